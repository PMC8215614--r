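#' Partition the gene universe by mark combination
#'
#' Counts genes in each of the `2^m` subsets of the mark set (for the three
#' marks: none, each single mark, each pair, the triple). The counts
#' partition the universe: they always sum to `N`.
#'
#' @param states mark state table from [mark_state_table()].
#' @return named integer vector over all mark subsets, with attribute `N`.
#' @export
mark_state_partition <- function(states) {
  marks <- setdiff(names(states), "gene_id")
  m <- length(marks)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  names(combos) <- marks
  combos <- combos[order(rowSums(combos)), , drop = FALSE]
  labels <- apply(as.matrix(combos), 1L, function(z)
    if (!any(z)) "none" else paste(marks[z], collapse = "+"))
  lab <- factor(mark_state_label(states), levels = labels)
  out <- table(lab)
  out <- setNames(as.integer(out), names(out))
  attr(out, "N") <- nrow(states)
  out
}

#' Percentage of a subset carrying a mark
#'
#' `100 * subset_marked / subset_size`, rounded half-up to one decimal
#' (the convention that reproduces printed percentages from printed
#' counts, e.g. 549 of 903 -> 60.8).
#'
#' @param subset_size size of the gene subset (> 0).
#' @param subset_marked number of marked genes within it.
#' @return percentage with one decimal.
#' @export
percent_with_mark <- function(subset_size, subset_marked) {
  if (any(subset_size <= 0)) stop("subset_size must be > 0")
  if (any(subset_marked < 0) || any(subset_marked > subset_size))
    stop("subset_marked must lie in [0, subset_size]")
  round_half_up(100 * subset_marked / subset_size, 1)
}

#' Expected co-occurrence under independence
#'
#' Expected number of genes carrying both of two marks if the marks were
#' assigned independently: `nA * nB / N` over the consensus universe,
#' with the observed/expected ratio and the hypergeometric standard
#' deviation of the overlap under random assignment of fixed marginals.
#'
#' @param nA,nB marginal marked-set sizes.
#' @param N universe size (> 0).
#' @param observed observed co-marked count.
#' @return list with `expected`, `ratio`, `sd_hypergeometric`.
#' @export
expected_cooccurrence <- function(nA, nB, N, observed) {
  if (N <= 0) stop("N must be > 0")
  if (nA > N || nB > N) stop("marginals cannot exceed N")
  nA <- as.numeric(nA); nB <- as.numeric(nB); N <- as.numeric(N)
  expected <- nA * nB / N
  v <- nA * nB * (N - nA) * (N - nB) / (N^2 * (N - 1))
  list(expected = expected,
       ratio = observed / expected,
       sd_hypergeometric = sqrt(v))
}

#' Fraction of co-marked genes whose peak pair overlaps beyond thresholds
#'
#' For every co-marked gene, clips both peak sets to the flank-extended
#' gene span and takes the largest single A-peak x B-peak intersection;
#' reports, for each threshold, the fraction of co-marked genes whose best
#' pairwise overlap strictly exceeds it. By construction the fraction at a
#' lower threshold is never below that at a higher one.
#'
#' @param peaks_a,peaks_b `GRanges` peak sets for the two marks.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param co_marked non-empty character vector of co-marked gene IDs.
#' @param thresholds overlap thresholds in bp (default 150 and 500).
#' @param flank_bp span extension, matching the marked-gene rule.
#' @return list with `fraction` (named by threshold) and `per_gene`
#'   (best pairwise overlap per co-marked gene, bp).
#' @export
peak_overlap_length_classes <- function(peaks_a, peaks_b, genes, co_marked,
                                        thresholds = c(150, 500),
                                        flank_bp = 200) {
  if (length(co_marked) == 0L) stop("co_marked set is empty")
  idx <- match(co_marked, genes$gene_id)
  if (anyNA(idx)) stop("co_marked contains IDs absent from the gene set")
  g <- genes[idx]
  ext_start <- pmax(1L, start(g) - as.integer(flank_bp))
  ext_end <- end(g) + as.integer(flank_bp)
  ext <- GenomicRanges::GRanges(seqnames(g),
                                IRanges::IRanges(ext_start, ext_end))
  ova <- GenomicRanges::findOverlaps(ext, peaks_a, ignore.strand = TRUE)
  ovb <- GenomicRanges::findOverlaps(ext, peaks_b, ignore.strand = TRUE)
  best <- setNames(numeric(length(g)), co_marked)
  a_by_gene <- split(subjectHits(ova), queryHits(ova))
  b_by_gene <- split(subjectHits(ovb), queryHits(ovb))
  for (k in intersect(names(a_by_gene), names(b_by_gene))) {
    i <- as.integer(k)
    ai <- a_by_gene[[k]]
    bi <- b_by_gene[[k]]
    # clip both peak lists to the extended span, then best pairwise overlap
    as_ <- pmax(start(peaks_a)[ai], ext_start[i])
    ae <- pmin(end(peaks_a)[ai], ext_end[i])
    bs <- pmax(start(peaks_b)[bi], ext_start[i])
    be <- pmin(end(peaks_b)[bi], ext_end[i])
    ov <- outer(ae, be, pmin) - outer(as_, bs, pmax) + 1
    best[i] <- max(0, ov)
  }
  frac <- vapply(thresholds, function(t) mean(best > t), numeric(1))
  list(fraction = setNames(frac, as.character(thresholds)),
       per_gene = best)
}

#' Cross-species conservation of a marked-gene set
#'
#' Percentage of species-1 marked genes with at least one marked ortholog
#' in species 2 under a many-to-many ortholog map.
#'
#' @param marked_species1 non-empty character vector of marked genes in
#'   species 1.
#' @param ortholog_map two-column data.frame (species-1 ID, species-2 ID);
#'   many-to-many relations permitted.
#' @param marked_species2 character vector of marked genes in species 2.
#' @return percentage in `[0, 100]` (full precision; round for display).
#' @export
ortholog_mark_conservation <- function(marked_species1, ortholog_map,
                                       marked_species2) {
  if (length(marked_species1) == 0L) stop("marked set in species 1 is empty")
  if (ncol(ortholog_map) < 2L) stop("ortholog_map needs 2 columns")
  conserved_s1 <- unique(ortholog_map[[1L]][ortholog_map[[2L]] %in%
                                              marked_species2])
  100 * mean(marked_species1 %in% conserved_s1)
}
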