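#' Read gene models from GFF3 or BED
#'
#' Parses gene models into a `GRanges` with `gene_id` and `subgenome`
#' metadata columns. Coordinates are held 1-based closed (the
#' GenomicRanges convention); BED input (0-based half-open) is shifted on
#' read so that interval lengths are preserved exactly.
#'
#' The "genic region" used throughout the package is the gene's full span;
#' exon/intron substructure is not needed by any downstream rule.
#'
#' @param path file path.
#' @param format `"gff3"` (1-based closed, converted) or `"bed"`
#'   (BED6+ with strand; 0-based half-open, converted).
#' @param feature_type GFF3 feature type to retain (default `"gene"`).
#' @param subgenome optional side table assigning subgenomes: a named
#'   character vector (names = gene IDs, values in `LF`, `MF1`, `MF2`) or a
#'   two-column data.frame (gene_id, subgenome). Overrides any `subgenome=`
#'   GFF3 attribute. Genes not covered are labelled `"unknown"`.
#' @return `GRanges` with metadata columns `gene_id`, `subgenome`.
#' @export
read_gene_models <- function(path, format = c("gff3", "bed"),
                             feature_type = "gene", subgenome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff3") {
    raw <- readLines(path)
    keep <- !grepl("^#", raw) & nzchar(trimws(raw))
    lineno <- which(keep)
    fields <- strsplit(raw[keep], "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 9L)
    if (length(bad) > 0L)
      stop("malformed GFF3 record (expected 9 tab-separated fields) at line ",
           lineno[bad[1L]], " of ", path)
    m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
    sel <- m[, 3L] == feature_type
    if (!any(sel)) stop("no '", feature_type, "' features in ", path)
    lsel <- lineno[sel]
    start <- suppressWarnings(as.integer(m[sel, 4L]))
    end <- suppressWarnings(as.integer(m[sel, 5L]))
    if (anyNA(start) || anyNA(end))
      stop("non-numeric coordinate at line ",
           lsel[which(is.na(start) | is.na(end))[1L]], " of ", path)
    if (any(end < start))
      stop("end < start at line ", lsel[which(end < start)[1L]], " of ", path)
    strand <- m[sel, 7L]
    strand[!strand %in% c("+", "-")] <- "*"
    attrs <- m[sel, 9L]
    gene_id <- gff3_attribute(attrs, "ID")
    if (anyNA(gene_id))
      stop("missing ID attribute at line ", lsel[which(is.na(gene_id))[1L]])
    sub <- gff3_attribute(attrs, "subgenome")
    sub[is.na(sub)] <- "unknown"
    gr <- GenomicRanges::GRanges(m[sel, 1L],
                                 IRanges::IRanges(start, end),
                                 strand = strand)
    mcols(gr)$gene_id <- gene_id
    mcols(gr)$subgenome <- sub
  } else {
    tab <- read_bedlike(path, min_cols = 6L, what = "BED gene model")
    if (nrow(tab) == 0L) stop("no gene records in ", path)
    strand <- tab[[6L]]
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GenomicRanges::GRanges(tab[[1L]],
                                 IRanges::IRanges(tab[[2L]] + 1L, tab[[3L]]),
                                 strand = strand)
    mcols(gr)$gene_id <- as.character(tab[[4L]])
    mcols(gr)$subgenome <- "unknown"
  }
  dup <- duplicated(gr$gene_id)
  if (any(dup)) stop("duplicate gene_id: ", gr$gene_id[which(dup)[1L]])
  if (!is.null(subgenome)) {
    if (is.data.frame(subgenome))
      subgenome <- setNames(as.character(subgenome[[2L]]),
                            as.character(subgenome[[1L]]))
    hit <- gr$gene_id %in% names(subgenome)
    mcols(gr)$subgenome[hit] <- unname(subgenome[gr$gene_id[hit]])
  }
  gr
}

# pull one key=value out of a GFF3 column-9 attribute string
gff3_attribute <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]+)")
  m <- regmatches(attrs, regexpr(pat, attrs, perl = TRUE))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]; round trips preserve coordinates,
#' strand, gene IDs and subgenome labels.
#'
#' @param genes `GRanges` with `gene_id` (and optionally `subgenome`).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  sub <- if (!is.null(genes$subgenome)) genes$subgenome else "unknown"
  attrs <- paste0("ID=", genes$gene_id, ";subgenome=", sub)
  lines <- paste(as.character(seqnames(genes)), "markstate", "gene",
                 start(genes), end(genes), ".",
                 as.character(strand(genes)), ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# shared reader for BED-like whitespace-free tab tables; validates column
# count, numeric coordinates and start<end, reporting 1-based line numbers
read_bedlike <- function(path, min_cols, exact_cols = NULL, what = "BED") {
  raw <- readLines(path)
  keep <- !grepl("^(#|track|browser)", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  if (length(lineno) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  n <- lengths(fields)
  if (!is.null(exact_cols)) {
    bad <- which(n != exact_cols)
    if (length(bad) > 0L)
      stop("malformed ", what, " (expected ", exact_cols,
           " fields) at line ", lineno[bad[1L]], " of ", path)
  } else {
    bad <- which(n < min_cols)
    if (length(bad) > 0L)
      stop("malformed ", what, " (expected >= ", min_cols,
           " fields) at line ", lineno[bad[1L]], " of ", path)
  }
  ncol <- min(n)
  m <- t(vapply(fields, function(f) f[seq_len(ncol)], character(ncol)))
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  out[[2L]] <- suppressWarnings(as.integer(out[[2L]]))
  out[[3L]] <- suppressWarnings(as.integer(out[[3L]]))
  if (anyNA(out[[2L]]) || anyNA(out[[3L]]))
    stop("non-numeric coordinate at line ",
         lineno[which(is.na(out[[2L]]) | is.na(out[[3L]]))[1L]], " of ", path)
  bad <- which(out[[3L]] <= out[[2L]])
  if (length(bad) > 0L)
    stop("chromEnd <= chromStart at line ", lineno[bad[1L]], " of ", path)
  out
}

#' Read a peak set (MACS2 narrowPeak or BED3+)
#'
#' Returns sorted intervals as a `GRanges`. Unsorted input is accepted and
#' sorted; overlapping peaks are retained as-is (merging is never implicit:
#' the co-occurrence overlap-length classes would be distorted by silent
#' merging). narrowPeak score/signal/summit columns are kept as metadata
#' columns but are unused downstream.
#'
#' @param path file path; an empty file yields an empty (valid) peak set.
#' @param format `"narrowPeak"` (BED6+4) or `"bed"` (3+ columns).
#' @param mark,sample labels stored in `metadata()` for provenance.
#' @return sorted `GRanges`; `metadata(x)$mark` / `$sample` carry labels.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed"),
                       mark = NA_character_, sample = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- if (format == "narrowPeak")
    read_bedlike(path, min_cols = 10L, exact_cols = 10L, what = "narrowPeak")
  else read_bedlike(path, min_cols = 3L, what = "BED")
  if (nrow(tab) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(tab[[1L]],
                                 IRanges::IRanges(tab[[2L]] + 1L, tab[[3L]]))
    if (ncol(tab) >= 5L)
      mcols(gr)$score <- suppressWarnings(as.numeric(tab[[5L]]))
    if (format == "narrowPeak") {
      mcols(gr)$signalValue <- suppressWarnings(as.numeric(tab[[7L]]))
      mcols(gr)$pValue <- suppressWarnings(as.numeric(tab[[8L]]))
      mcols(gr)$qValue <- suppressWarnings(as.numeric(tab[[9L]]))
      mcols(gr)$peak <- suppressWarnings(as.integer(tab[[10L]]))
    }
    gr <- sort(gr, ignore.strand = TRUE)
  }
  metadata(gr)$mark <- mark
  metadata(gr)$sample <- sample
  gr
}

#' Write a peak set as narrowPeak or BED3
#'
#' @param peaks `GRanges`.
#' @param path output path.
#' @param format output dialect; narrowPeak fills unavailable statistics
#'   columns with `-1` per the ENCODE convention.
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  chrom <- as.character(seqnames(peaks))
  start0 <- start(peaks) - 1L
  end0 <- end(peaks)
  if (length(peaks) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (format == "bed") {
    lines <- paste(chrom, start0, end0, sep = "\t")
  } else {
    score <- if (!is.null(peaks$score)) peaks$score else 0
    name <- paste0("peak_", seq_along(peaks))
    lines <- paste(chrom, start0, end0, name, score, ".",
                   -1, -1, -1, -1, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write an FPKM expression matrix
#'
#' TSV with a header; first column gene IDs, remaining columns one per
#' tissue or condition. Values must be non-negative.
#'
#' @param path file path.
#' @return numeric matrix, rownames = gene IDs.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs >= 2 columns (id + values)")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate gene_id in expression table")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("missing FPKM values are not permitted")
  if (any(mat < 0)) stop("negative FPKM values are not permitted")
  rownames(mat) <- ids
  mat
}

#' @rdname read_expression
#' @param mat numeric matrix with rownames.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a paralog triplet table
#'
#' TSV with header columns `lf`, `mf1`, `mf2` (one gene ID per subgenome
#' copy; empty cells mark missing copies). Rows with any missing copy are
#' flagged `complete = FALSE` and excluded from three-copy analyses.
#'
#' @param path file path.
#' @param genes optional `GRanges` from [read_gene_models()] or a character
#'   vector of known gene IDs; triplet IDs absent from it are flagged
#'   `resolved = FALSE` with a warning.
#' @return data.frame with columns `lf`, `mf1`, `mf2`, `complete`,
#'   `resolved`.
#' @export
read_triplets <- function(path, genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("", "NA"))
  if (ncol(df) < 3L) stop("triplet table needs 3 columns (lf, mf1, mf2)")
  nm <- tolower(names(df))
  idx <- match(c("lf", "mf1", "mf2"), nm)
  if (anyNA(idx)) idx <- 1:3
  out <- data.frame(lf = df[[idx[1L]]], mf1 = df[[idx[2L]]],
                    mf2 = df[[idx[3L]]], stringsAsFactors = FALSE)
  out$complete <- !is.na(out$lf) & !is.na(out$mf1) & !is.na(out$mf2)
  out$resolved <- TRUE
  if (!is.null(genes)) {
    ids <- if (inherits(genes, "GRanges")) genes$gene_id else genes
    known <- function(x) is.na(x) | x %in% ids
    out$resolved <- known(out$lf) & known(out$mf1) & known(out$mf2)
    if (any(!out$resolved))
      warning(sum(!out$resolved),
              " triplet row(s) contain gene IDs absent from the gene set")
  }
  out
}

#' @rdname read_triplets
#' @param triplets data.frame as returned by [read_triplets()].
#' @export
write_triplets <- function(triplets, path) {
  write.table(triplets[, c("lf", "mf1", "mf2")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write a qPCR Ct table
#'
#' TSV with header columns `target`, `antibody`, `template` (`IP` or
#' `input`), `replicate` (optional, default 1) and `ct` (cycle number,
#' positive).
#'
#' @param path file path.
#' @return data.frame with the five columns above.
#' @export
read_ct <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("target", "antibody", "template", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("Ct table missing column(s): ",
                              paste(miss, collapse = ", "))
  if (is.null(df$replicate)) df$replicate <- 1L
  df$template <- tolower(df$template)
  df$template[df$template == "ip"] <- "IP"
  if (!all(df$template %in% c("IP", "input")))
    stop("template must be 'IP' or 'input'")
  df$ct <- as.numeric(df$ct)
  if (anyNA(df$ct) || any(df$ct <= 0)) stop("Ct values must be positive")
  df[, c("target", "antibody", "template", "replicate", "ct")]
}

#' @rdname read_ct
#' @param ct data.frame as returned by [read_ct()].
#' @export
write_ct <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
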