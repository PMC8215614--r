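#' Maximum single-peak overlap with flank-extended gene spans
#'
#' For each gene, extends its span by `flank_bp` on both sides (clamped at
#' the chromosome start), intersects every peak with the extended span, and
#' returns the largest single-peak intersection in bp (`mode = "single"`,
#' the default) or the sum of per-peak intersections (`mode = "summed"`).
#' The extension is strand-independent: the rule is symmetric around the
#' gene span.
#'
#' @param genes `GRanges` with `gene_id`.
#' @param peaks `GRanges` peak set (sorted; strand ignored).
#' @param flank_bp non-negative extension in bp (default 200).
#' @param mode overlap aggregation across multiple peaks hitting one gene.
#' @return integer vector of overlaps, named by `gene_id` (0 = no overlap).
#' @export
gene_peak_overlap <- function(genes, peaks, flank_bp = 200,
                              mode = c("single", "summed")) {
  mode <- match.arg(mode)
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  out <- setNames(integer(length(genes)), genes$gene_id)
  if (length(peaks) == 0L || length(genes) == 0L) return(out)
  ext_start <- pmax(1L, start(genes) - as.integer(flank_bp))
  ext_end <- end(genes) + as.integer(flank_bp)
  ext <- GenomicRanges::GRanges(seqnames(genes),
                                IRanges::IRanges(ext_start, ext_end))
  ov <- GenomicRanges::findOverlaps(ext, peaks, ignore.strand = TRUE)
  if (length(ov) == 0L) return(out)
  q <- queryHits(ov)
  s <- subjectHits(ov)
  w <- pmin(ext_end[q], end(peaks)[s]) - pmax(ext_start[q], start(peaks)[s]) + 1L
  agg <- if (mode == "single") tapply(w, q, max) else tapply(w, q, sum)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Call marked genes from a peak set
#'
#' A gene is "marked" when a single peak intersects its flank-extended span
#' by strictly more than `min_overlap_bp` (default: a more-than-200-bp peak
#' segment within the genic region extended by 200 bp up- and downstream).
#' Whether multiple sub-threshold peaks may be summed is controlled by
#' `overlap_mode`; the default `"single"` is the literal per-peak reading.
#'
#' @inheritParams gene_peak_overlap
#' @param min_overlap_bp overlap threshold in bp; strict inequality.
#' @param overlap_mode `"single"` (max one peak) or `"summed"`.
#' @param mark,sample labels recorded in the output (defaults taken from
#'   `metadata(peaks)` when present).
#' @return data.frame with columns `gene_id`, `mark`, `sample`,
#'   `max_overlap_bp`, `marked`; parameters recorded as attributes
#'   `flank_bp`, `min_overlap_bp`, `overlap_mode` for provenance.
#' @export
classify_marked_genes <- function(genes, peaks, flank_bp = 200,
                                  min_overlap_bp = 200,
                                  overlap_mode = c("single", "summed"),
                                  mark = NULL, sample = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  if (is.null(mark))
    mark <- if (!is.null(metadata(peaks)$mark)) metadata(peaks)$mark
            else NA_character_
  if (is.null(sample))
    sample <- if (!is.null(metadata(peaks)$sample)) metadata(peaks)$sample
              else NA_character_
  ov <- gene_peak_overlap(genes, peaks, flank_bp = flank_bp,
                          mode = overlap_mode)
  out <- data.frame(gene_id = genes$gene_id, mark = mark, sample = sample,
                    max_overlap_bp = unname(ov),
                    marked = unname(ov) > min_overlap_bp,
                    stringsAsFactors = FALSE)
  attr(out, "flank_bp") <- flank_bp
  attr(out, "min_overlap_bp") <- min_overlap_bp
  attr(out, "overlap_mode") <- overlap_mode
  out
}

#' Consensus marked genes across samples
#'
#' Genes marked in every provided sample (the two inbred lines act as
#' biological replicates; only genes marked in both are carried forward).
#'
#' @param status_list list of >= 2 status tables from
#'   [classify_marked_genes()], all over the identical gene universe.
#' @return character vector of consensus-marked gene IDs.
#' @export
consensus_marked <- function(status_list) {
  if (length(status_list) < 2L) stop("need >= 2 samples for a consensus")
  universes <- lapply(status_list, function(s) sort(s$gene_id))
  for (i in seq_along(universes)[-1L])
    if (!identical(universes[[1L]], universes[[i]]))
      stop("gene universes differ between samples")
  Reduce(intersect,
         lapply(status_list, function(s) s$gene_id[s$marked]))
}

#' Assemble a per-gene mark state table
#'
#' Central object of the pipeline: one row per gene of the universe, one
#' logical column per mark holding the consensus state.
#'
#' @param universe character vector of all gene IDs.
#' @param marked named list of character vectors, one consensus marked set
#'   per mark (e.g. `list(K4 = ..., K36 = ..., K27 = ...)`).
#' @return data.frame with `gene_id` plus one logical column per mark.
#' @export
mark_state_table <- function(universe, marked) {
  if (is.null(names(marked)) || any(!nzchar(names(marked))))
    stop("'marked' must be a named list (one element per mark)")
  out <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (m in names(marked)) {
    extra <- setdiff(marked[[m]], universe)
    if (length(extra) > 0L)
      stop("marked set '", m, "' contains IDs outside the universe")
    out[[m]] <- universe %in% marked[[m]]
  }
  out
}

#' Label each gene by its mark combination
#'
#' @param states mark state table from [mark_state_table()].
#' @return character vector (e.g. `"none"`, `"K4"`, `"K4+K36"`), in the
#'   same order as `states`.
#' @export
mark_state_label <- function(states) {
  marks <- setdiff(names(states), "gene_id")
  lab <- apply(as.matrix(states[marks]), 1L, function(z)
    if (!any(z)) "none" else paste(marks[z], collapse = "+"))
  unname(lab)
}
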