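#' Mark categories of paralog triplets
#'
#' Counts three-copy paralog sets (one gene per subgenome LF/MF1/MF2) by
#' how many copies carry the mark: all three, exactly two, exactly one, or
#' none. The four categories partition the complete sets.
#'
#' @param triplets data.frame from [read_triplets()] (columns `lf`, `mf1`,
#'   `mf2`; rows with missing or unresolved copies are excluded and their
#'   count reported).
#' @param marked character vector of marked gene IDs.
#' @return list: `counts` (named integer vector `c3`, `c2`, `c1`, `c0`),
#'   `total` complete sets, `n_excluded` incomplete rows.
#' @export
triplet_mark_categories <- function(triplets, marked) {
  ok <- if (!is.null(triplets$complete)) triplets$complete else
    stats::complete.cases(triplets[, c("lf", "mf1", "mf2")])
  if (!is.null(triplets$resolved)) ok <- ok & triplets$resolved
  tt <- triplets[ok, c("lf", "mf1", "mf2")]
  k <- (tt$lf %in% marked) + (tt$mf1 %in% marked) + (tt$mf2 %in% marked)
  counts <- vapply(3:0, function(j) sum(k == j), integer(1))
  list(counts = setNames(counts, c("c3", "c2", "c1", "c0")),
       total = nrow(tt),
       n_excluded = sum(!ok))
}

#' With- vs without-mark value contrasts between paralog copies
#'
#' For each ordered subgenome pair (e.g. LF vs MF1), collects triplets
#' whose first copy carries the mark and whose second does not, and
#' contrasts the values (FPKM, tau, ...) of the marked copies against the
#' unmarked copies with an unpaired two-sample t-test, plus a pooled
#' contrast over all discordant copies. Only discordant configurations
#' contribute; constant groups yield `NA` p-values and are flagged.
#'
#' @param triplets data.frame with `lf`, `mf1`, `mf2` (incomplete rows
#'   excluded).
#' @param marked character vector of marked gene IDs.
#' @param values per-gene numeric values named by gene ID.
#' @return data.frame: `comparison`, `n_pairs`, `mean_with`,
#'   `mean_without`, `t`, `p_value`, `direction`; empty (with a warning)
#'   when no triplet is discordant.
#' @export
paired_value_contrast <- function(triplets, marked, values) {
  ok <- if (!is.null(triplets$complete)) triplets$complete else
    stats::complete.cases(triplets[, c("lf", "mf1", "mf2")])
  tt <- triplets[ok, c("lf", "mf1", "mf2")]
  names(tt) <- c("LF", "MF1", "MF2")
  one <- function(w, wo, label) {
    w <- w[!is.na(values[w])]; wo <- wo[!is.na(values[wo])]
    if (length(w) < 2L || length(wo) < 2L) return(NULL)
    vw <- as.numeric(values[w]); vwo <- as.numeric(values[wo])
    if (sd(vw) == 0 && sd(vwo) == 0) {
      tstat <- NA_real_; p <- NA_real_
    } else {
      ht <- t.test(vw, vwo)
      tstat <- unname(ht$statistic); p <- unname(ht$p.value)
    }
    data.frame(comparison = label, n_pairs = min(length(w), length(wo)),
               mean_with = mean(vw), mean_without = mean(vwo),
               t = tstat, p_value = p,
               direction = if (mean(vw) > mean(vwo)) "higher" else "lower",
               stringsAsFactors = FALSE)
  }
  subs <- c("LF", "MF1", "MF2")
  rows <- list()
  for (A in subs) for (B in setdiff(subs, A)) {
    sel <- tt[[A]] %in% marked & !(tt[[B]] %in% marked)
    if (any(sel))
      rows[[paste0(A, "+/", B, "-")]] <-
        one(tt[[A]][sel], tt[[B]][sel], paste0(A, "+/", B, "-"))
  }
  # pooled: every discordant triplet's marked copies vs unmarked copies
  k <- (tt$LF %in% marked) + (tt$MF1 %in% marked) + (tt$MF2 %in% marked)
  disc <- tt[k > 0L & k < 3L, , drop = FALSE]
  if (nrow(disc) > 0L) {
    ids <- unlist(disc, use.names = FALSE)
    rows[["pooled"]] <- one(ids[ids %in% marked], ids[!ids %in% marked],
                            "pooled")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    warning("no discordant triplets; empty contrast")
    return(data.frame(comparison = character(), n_pairs = integer(),
                      mean_with = numeric(), mean_without = numeric(),
                      t = numeric(), p_value = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
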