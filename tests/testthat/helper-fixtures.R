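# in-code fixtures and brute-force oracles shared across test files
suppressPackageStartupMessages(library(GenomicRanges))

gr_genes <- function(start, end, strand = "+", chrom = "A01", id = NULL) {
  if (is.null(id)) id <- paste0("g", seq_along(start))
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  gr$gene_id <- id
  gr$subgenome <- "unknown"
  gr
}

gr_peaks <- function(start, end, chrom = "A01") {
  GRanges(chrom, IRanges(start, end))
}

# per-base bitmap oracle for the marked-gene rule: enumerate the bases of
# the flank-extended span and intersect with each peak's bases
oracle_max_overlap <- function(gene_start, gene_end, peak_start, peak_end,
                               flank) {
  span <- seq(max(1, gene_start - flank), gene_end + flank)
  best <- 0L
  for (i in seq_along(peak_start)) {
    ov <- length(intersect(span, seq(peak_start[i], peak_end[i])))
    best <- max(best, ov)
  }
  best
}

# random small classification instance on one chromosome
random_instance <- function(n_genes, n_peaks, size = 50000) {
  gs <- sort(sample.int(size, n_genes))
  gl <- sample(50:3000, n_genes, replace = TRUE)
  genes <- gr_genes(gs, gs + gl - 1L,
                    strand = sample(c("+", "-"), n_genes, TRUE))
  ps <- sample.int(size, n_peaks, replace = TRUE)
  pl <- sample(20:2000, n_peaks, replace = TRUE)
  list(genes = genes, peaks = gr_peaks(ps, ps + pl - 1L))
}

# triplet fixture with exact planted per-mark category counts
planted_triplets <- function(c3, c2, c1, c0, prefix = "t") {
  total <- c3 + c2 + c1 + c0
  lf <- paste0(prefix, "L", seq_len(total))
  mf1 <- paste0(prefix, "M", seq_len(total))
  mf2 <- paste0(prefix, "N", seq_len(total))
  marked <- c(lf[seq_len(c3 + c2 + c1)],
              mf1[seq_len(c3 + c2)],
              mf2[seq_len(c3)])
  list(triplets = data.frame(lf = lf, mf1 = mf1, mf2 = mf2,
                             complete = TRUE, resolved = TRUE,
                             stringsAsFactors = FALSE),
       marked = marked)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
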