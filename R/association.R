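#' Log2-transform an FPKM matrix with an expression floor
#'
#' Values below `min_fpkm` are excluded (set `NA`) so near-zero FPKM does
#' not dominate group summaries; retained values become `log2(FPKM)`.
#'
#' @param mat non-negative FPKM matrix (or vector).
#' @param min_fpkm exclusion floor (default 0.01).
#' @return matrix/vector of log2 values with sub-floor entries `NA`.
#' @export
log2_expression <- function(mat, min_fpkm = 0.01) {
  if (any(mat < 0, na.rm = TRUE)) stop("FPKM must be non-negative")
  out <- suppressWarnings(log2(mat))
  out[mat < min_fpkm] <- NA_real_
  out
}

#' Tissue-specificity index (tau / T-value)
#'
#' `T = sum_i(1 - x_i / max(x)) / (n - 1)` over `n >= 2` tissues: 0 for
#' uniform (housekeeping) expression, 1 for strict one-tissue expression.
#' By default expression is first mapped to `max(log2(FPKM + 1), 0)`, the
#' scale on which the index is conventionally defined; `transform =
#' "none"` scores the raw values, under which tau is exactly invariant to
#' positive rescaling. An all-zero vector is defined as tau = 0.
#'
#' @param x non-negative expression vector over `n >= 2` tissues.
#' @param transform `"log2"` (default) or `"none"`.
#' @return tau in `[0, 1]`.
#' @export
tau <- function(x, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  if (length(x) < 2L) stop("tau needs >= 2 tissues")
  if (any(x < 0)) stop("expression must be non-negative")
  if (transform == "log2") x <- pmax(log2(x + 1), 0)
  mx <- max(x)
  if (mx == 0) return(0)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' @rdname tau
#' @param mat FPKM matrix (genes x tissues).
#' @return for `tau_matrix`: data.frame with `gene_id`, `tau`, `n_tissues`.
#' @export
tau_matrix <- function(mat, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  data.frame(gene_id = rownames(mat),
             tau = apply(mat, 1L, tau, transform = transform),
             n_tissues = ncol(mat),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-group summaries and Tukey-style pairwise comparisons
#'
#' Summarises a per-gene value (log2 FPKM, tau, ...) within mark-state
#' groups and runs all pairwise comparisons via Tukey's HSD on a one-way
#' ANOVA at `alpha` (default 0.05). Groups with fewer than two finite
#' values are dropped with a warning; `NA` values are ignored.
#'
#' @param groups per-gene group labels: a character/factor vector named by
#'   gene ID, or a two-column data.frame (gene_id, group).
#' @param values per-gene numeric values named by gene ID.
#' @param alpha significance level for the pairwise flags.
#' @return list with `summary` (group, n, mean, median) and `pairwise`
#'   (comparison, diff, lwr, upr, p_adj, significant); `pairwise` is `NULL`
#'   when fewer than two groups remain.
#' @export
group_summary <- function(groups, values, alpha = 0.05) {
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups[[2L]]),
                       as.character(groups[[1L]]))
  ids <- intersect(names(groups), names(values))
  if (length(ids) == 0L) stop("no genes shared between groups and values")
  g <- as.character(groups[ids])
  v <- as.numeric(values[ids])
  ok <- is.finite(v)
  g <- g[ok]; v <- v[ok]
  n_by <- table(g)
  small <- names(n_by)[n_by < 2L]
  if (length(small) > 0L) {
    warning("dropping group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(g %in% small)
    g <- g[keep]; v <- v[keep]
  }
  summ <- do.call(rbind, lapply(split(v, g), function(z)
    data.frame(n = length(z), mean = mean(z), median = median(z))))
  summ <- data.frame(group = rownames(summ), summ,
                     row.names = NULL, stringsAsFactors = FALSE)
  pairwise <- NULL
  if (length(unique(g)) >= 2L) {
    fit <- aov(v ~ grp, data = data.frame(v = v, grp = factor(g)))
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$grp
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], lwr = tk[, "lwr"],
                           upr = tk[, "upr"], p_adj = tk[, "p adj"],
                           significant = tk[, "p adj"] < alpha,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  list(summary = summ, pairwise = pairwise)
}

#' Mark enrichment/depletion within a DEG set
#'
#' 2x2 contingency (DEG / non-DEG x marked / unmarked) over the gene
#' universe, tested with a 1-df chi-squared (continuity correction off by
#' default: cell counts are large in genome-scale use). The direction is
#' the sign of the marked proportion inside the DEG set relative to the
#' universe.
#'
#' @param deg,marked character vectors, subsets of `universe`.
#' @param universe character vector of all gene IDs.
#' @param correct apply Yates continuity correction.
#' @return one-row data.frame: counts `a` (DEG & marked), `b`, `c`, `d`,
#'   `observed_prop`, `reference_prop`, `statistic`, `p_value`,
#'   `direction` (`"higher"`/`"lower"`/`"equal"`).
#' @export
deg_mark_enrichment <- function(deg, marked, universe, correct = FALSE) {
  deg <- unique(deg); marked <- unique(marked)
  if (length(setdiff(deg, universe)) > 0L ||
      length(setdiff(marked, universe)) > 0L)
    stop("deg and marked must be subsets of the universe")
  N <- length(unique(universe))
  a <- length(intersect(deg, marked))
  b <- length(deg) - a
  c_ <- length(marked) - a
  d <- N - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a contingency margin is zero; test undefined")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  obs <- a / length(deg)
  ref <- length(marked) / N
  data.frame(a = a, b = b, c = c_, d = d,
             observed_prop = obs, reference_prop = ref,
             statistic = unname(ht$statistic),
             p_value = unname(ht$p.value),
             direction = if (obs > ref) "higher"
                         else if (obs < ref) "lower" else "equal",
             stringsAsFactors = FALSE)
}

#' SNP density (mutation rate) contrast between marked and unmarked genes
#'
#' Per-gene mutation rate = SNP count / gene length (bp); compares marked
#' vs unmarked genes with a Welch two-sample t-test (group sizes and
#' variances are unequal in practice).
#'
#' @param variants data.frame with columns `gene_id`, `snp_count`,
#'   `length_bp` (> 0).
#' @param marked character vector of marked gene IDs.
#' @return one-row data.frame: `n_marked`, `n_unmarked`, `mean_marked`,
#'   `mean_unmarked`, `ratio`, `p_value`.
#' @export
snp_density_contrast <- function(variants, marked) {
  if (any(variants$length_bp <= 0)) stop("gene length must be > 0")
  rate <- variants$snp_count / variants$length_bp
  grp <- variants$gene_id %in% marked
  if (!any(grp) || all(grp)) stop("both groups must be non-empty")
  rm_ <- rate[grp]; ru <- rate[!grp]
  if (sd(rate) == 0) {
    p <- 1  # all rates identical: no contrast by construction
  } else {
    p <- t.test(rm_, ru)$p.value
  }
  data.frame(n_marked = sum(grp), n_unmarked = sum(!grp),
             mean_marked = mean(rm_), mean_unmarked = mean(ru),
             ratio = mean(rm_) / mean(ru), p_value = p)
}
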