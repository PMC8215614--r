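#' Metagene occupancy profile around scaled gene bodies
#'
#' Aggregates peak occupancy over genes in a flank/body/flank frame: fixed
#' `flank_bp` windows upstream and downstream split into `flank_bins` bins
#' each, and the gene body linearly rescaled onto `body_bins` bins
#' ("scale-regions" style). Minus-strand genes are reversed so bin 1 is
#' always the 5' (upstream) end. Occupancy per bin is the fraction of
#' genes whose bin midpoint falls inside a peak — a binary peak-presence
#' statistic, not read coverage; the package consumes peak intervals, and
#' profile shape comparisons (TSS-proximal enrichment, body decay) remain
#' valid under this proxy.
#'
#' @param peaks `GRanges` peak set.
#' @param genes stranded `GRanges` gene models.
#' @param flank_bp flank extent in bp (divisible by `flank_bins`).
#' @param flank_bins,body_bins bin counts.
#' @return data.frame with `bin` (1-based over the full frame), `segment`
#'   (`up`/`body`/`down`) and `occupancy`; attribute `n_genes` records how
#'   many genes contributed.
#' @export
metagene_profile <- function(peaks, genes, flank_bp = 1000,
                             flank_bins = 20, body_bins = 40) {
  if (flank_bp %% flank_bins != 0)
    stop("flank_bp must be divisible by flank_bins")
  short <- width(genes) < body_bins
  if (any(short)) {
    warning("skipping ", sum(short), " gene(s) shorter than body_bins bases")
    genes <- genes[!short]
  }
  if (length(genes) == 0L) stop("no usable genes")
  nb <- 2L * flank_bins + body_bins
  fw <- flank_bp / flank_bins
  # plus-strand bin-midpoint geometry; minus strand = the same positions
  # visited in reverse order, which makes strand flipping an exact mirror
  up_off <- -flank_bp + (seq_len(flank_bins) - 0.5) * fw
  dn_off <- (seq_len(flank_bins) - 0.5) * fw
  pos <- matrix(0, nrow = length(genes), ncol = nb)
  gs <- start(genes); ge <- end(genes); gw <- width(genes)
  for (i in seq_len(flank_bins)) {
    pos[, i] <- gs - 0.5 + up_off[i]
    pos[, flank_bins + body_bins + i] <- ge + 0.5 + dn_off[i]
  }
  for (j in seq_len(body_bins))
    pos[, flank_bins + j] <- gs - 0.5 + (j - 0.5) * gw / body_bins
  neg <- as.character(strand(genes)) == "-"
  pos[neg, ] <- pos[neg, rev(seq_len(nb)), drop = FALSE]
  ipos <- round(pos)
  valid <- ipos >= 1
  qry <- GenomicRanges::GRanges(
    rep(as.character(seqnames(genes)), nb),
    IRanges::IRanges(pmax(1, as.vector(ipos)), width = 1L))
  inpeak <- GenomicRanges::countOverlaps(qry, peaks,
                                         ignore.strand = TRUE) > 0
  hit <- matrix(inpeak, nrow = length(genes)) & valid
  out <- data.frame(
    bin = seq_len(nb),
    segment = rep(c("up", "body", "down"),
                  c(flank_bins, body_bins, flank_bins)),
    occupancy = colMeans(hit),
    stringsAsFactors = FALSE)
  attr(out, "n_genes") <- length(genes)
  out
}

#' Tile the genome and score per-window peak coverage
#'
#' Fixed-width windows tiling each chromosome; the value of a window is
#' the fraction of its bases covered by (reduced) peaks, in `[0, 1]`.
#'
#' @param peaks `GRanges`.
#' @param window_bp window width (> 0).
#' @param chrom_sizes named integer vector of chromosome lengths; when
#'   `NULL`, taken from `seqlengths(peaks)` or, failing that, the maximum
#'   peak end per chromosome.
#' @return `GRanges` of windows with metadata column `value`.
#' @export
windowed_track <- function(peaks, window_bp = 10000, chrom_sizes = NULL) {
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (is.null(chrom_sizes)) {
    sl <- seqlengths(peaks)
    if (length(sl) > 0L && !anyNA(sl)) {
      chrom_sizes <- sl
    } else {
      chrom_sizes <- vapply(split(end(peaks),
                                  as.character(seqnames(peaks))),
                            max, numeric(1))
    }
  }
  red <- GenomicRanges::reduce(GenomicRanges::granges(peaks),
                               ignore.strand = TRUE)
  windows <- GenomicRanges::tileGenome(chrom_sizes, tilewidth = window_bp,
                                       cut.last.tile.in.chrom = TRUE)
  ov <- GenomicRanges::findOverlaps(windows, red)
  covered <- numeric(length(windows))
  if (length(ov) > 0L) {
    q <- queryHits(ov); s <- subjectHits(ov)
    w <- pmin(end(windows)[q], end(red)[s]) -
      pmax(start(windows)[q], start(red)[s]) + 1
    agg <- tapply(w, q, sum)
    covered[as.integer(names(agg))] <- agg
  }
  mcols(windows)$value <- covered / width(windows)
  windows
}

#' Pearson correlation between two window tracks
#'
#' @param a,b window tracks from [windowed_track()] on the identical grid.
#' @return Pearson r.
#' @export
track_correlation <- function(a, b) {
  same <- length(a) == length(b) &&
    all(as.character(seqnames(a)) == as.character(seqnames(b))) &&
    all(start(a) == start(b)) && all(end(a) == end(b))
  if (!same) stop("window grids differ")
  x <- a$value; y <- b$value
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant track")
  cor(x, y)
}
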