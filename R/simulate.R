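#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' are the study conditions the pipeline targets: consensus marked-gene
#' frequencies 42.3% / 29.9% / 26.4% (K4 / K36 / K27 of annotated genes),
#' a K4-K36 co-occurrence at twice the independence expectation, K4-K27
#' at 0.84x and K36-K27 at 0.21x (ratios derived from the observed and
#' expected co-marked counts), two lines whose per-line marked sets exceed
#' the consensus by a small line-specific rate, gene lengths log-normal
#' with a 2 kb median, peak lengths gamma with a 1 kb mean and TSS-biased
#' placement, six-tissue expression with additive per-mark log2 effects,
#' state-dependent tissue-specificity targets, a DEG model with per-mark
#' odds multipliers (K36 depleted, K27 enriched), and qPCR Ct tables with
#' Gaussian cycle noise.
#'
#' @param seed integer master seed; every generator stage derives its RNG
#'   stream from it (stage offsets 0-6), so one seed fixes all outputs.
#' @param n_genes,n_chromosomes genome size.
#' @param gene_length_meanlog,gene_length_sdlog log-normal gene-length
#'   parameters (bp); lengths are floored at 300 bp.
#' @param gap_min,gap_mean intergenic gap model (bp): `gap_min` plus an
#'   exponential with mean `gap_mean - gap_min`. The minimum gap keeps a
#'   gene's peaks out of its neighbours' flank-extended spans.
#' @param mark_freq named marginal consensus mark frequencies.
#' @param cooccurrence_ratio named pairwise observed/expected ratios
#'   (`"K4:K36"`, `"K4:K27"`, `"K36:K27"`).
#' @param lines sample labels; `line_extra_rate` is the probability that a
#'   consensus-unmarked gene acquires a line-specific mark, so per-line
#'   marked sets are supersets of the consensus.
#' @param peak_length_shape,peak_length_mean gamma peak-length model (bp).
#' @param tissues tissue labels (>= 2).
#' @param expr_base,expr_effect,expr_sd log2-FPKM model: gene-level mean
#'   `expr_base + sum(expr_effect[marks carried])`, SD `expr_sd`.
#' @param tau_mean state-dependent tissue-specificity targets (precedence
#'   K36 > K4 > K27 > none); `tau_jitter_sd` spreads targets per gene and
#'   `tau_noise_sd` is the Gaussian noise SD on log2 tissue values.
#' @param deg_rate,deg_odds DEG model: baseline membership rate and
#'   per-mark odds multipliers.
#' @param n_triplets number of paralog three-copy sets (disjoint genes).
#' @param qpcr_enrichment named true fold enrichments; `qpcr_reference`
#'   the unmarked reference gene; `ct_noise_sd` Gaussian Ct noise;
#'   `qpcr_replicates` biological replicates.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed = 1,
                       n_genes = 5000,
                       n_chromosomes = 2,
                       gene_length_meanlog = log(2000),
                       gene_length_sdlog = 0.6,
                       gap_min = 1000,
                       gap_mean = 3000,
                       mark_freq = c(K4 = 0.423, K36 = 0.299, K27 = 0.264),
                       cooccurrence_ratio = c("K4:K36" = 2.0,
                                              "K4:K27" = 0.84,
                                              "K36:K27" = 0.21),
                       lines = c("T23", "T24"),
                       line_extra_rate = 0.07,
                       peak_length_shape = 2,
                       peak_length_mean = 1000,
                       tissues = c("leaf_14d", "root", "stem", "flower",
                                   "silique", "seedling"),
                       expr_base = 1.5,
                       expr_effect = c(K4 = 1.5, K36 = 2.5, K27 = -1.8),
                       expr_sd = 1.2,
                       tau_mean = c(K36 = 0.15, K4 = 0.25, K27 = 0.60,
                                    none = 0.35),
                       tau_jitter_sd = 0.05,
                       tau_noise_sd = 0.1,
                       deg_rate = 0.05,
                       deg_odds = c(K4 = 1.0, K36 = 0.3, K27 = 2.5),
                       n_triplets = 400,
                       qpcr_enrichment = c(BrTargetA = 0.5, BrTargetB = 1,
                                           BrTargetC = 2, BrTargetD = 8,
                                           BrTargetE = 16),
                       qpcr_reference = "Bra011336",
                       ct_noise_sd = 0.2,
                       qpcr_replicates = 3) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_chromosomes = n_chromosomes,
              gene_length_meanlog = gene_length_meanlog,
              gene_length_sdlog = gene_length_sdlog,
              gap_min = gap_min, gap_mean = gap_mean,
              mark_freq = mark_freq,
              cooccurrence_ratio = cooccurrence_ratio,
              lines = lines, line_extra_rate = line_extra_rate,
              peak_length_shape = peak_length_shape,
              peak_length_mean = peak_length_mean,
              tissues = tissues, expr_base = expr_base,
              expr_effect = expr_effect, expr_sd = expr_sd,
              tau_mean = tau_mean, tau_jitter_sd = tau_jitter_sd,
              tau_noise_sd = tau_noise_sd,
              deg_rate = deg_rate, deg_odds = deg_odds,
              n_triplets = n_triplets,
              qpcr_enrichment = qpcr_enrichment,
              qpcr_reference = qpcr_reference,
              ct_noise_sd = ct_noise_sd,
              qpcr_replicates = qpcr_replicates)
  if (any(mark_freq < 0 | mark_freq > 1)) stop("mark_freq must lie in [0,1]")
  if (any(tau_mean < 0 | tau_mean > 1)) stop("tau targets must lie in [0,1]")
  if (deg_rate <= 0 || deg_rate >= 1) stop("deg_rate must lie in (0,1)")
  if (length(tissues) < 2L) stop("need >= 2 tissues")
  if (line_extra_rate < 0 || line_extra_rate > 1)
    stop("line_extra_rate must lie in [0,1]")
  if (3 * n_triplets > n_genes)
    stop("n_triplets too large: needs 3*n_triplets <= n_genes")
  # fail on an infeasible joint before anything is sampled
  mark_joint_probs(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Joint mark-state distribution from marginals and pairwise ratios
#'
#' Builds the 8-cell joint distribution over \{K4, K36, K27\} states by
#' iterative proportional fitting (IPF): the three pairwise 2x2 margins
#' are fixed by `joint(A,B) = ratio_AB * p_A * p_B` (which also pins the
#' one-way marginals), and the three-way interaction defaults to
#' independence given the pairs (the IPF maximum-entropy solution).
#'
#' @param cfg a [sim_config()] (class check is not enforced so partial
#'   lists can be probed for feasibility).
#' @return numeric `2 x 2 x 2` array (`dimnames` FALSE/TRUE per mark)
#'   summing to 1.
#' @export
mark_joint_probs <- function(cfg) {
  p <- cfg$mark_freq[c("K4", "K36", "K27")]
  r <- cfg$cooccurrence_ratio
  pair_target <- function(a, b, ratio) {
    t22 <- ratio * p[a] * p[b]
    # rows index mark a, columns mark b (FALSE, TRUE)
    tab <- matrix(c(1 - p[a] - p[b] + t22, p[a] - t22,
                    p[b] - t22, t22), nrow = 2)
    if (any(tab < -1e-12))
      stop("infeasible joint: pair ", a, "-", b,
           " ratio incompatible with its marginals")
    pmax(tab, 0)
  }
  targets <- list(
    c(1L, 2L) , c(1L, 3L), c(2L, 3L))
  marks <- c("K4", "K36", "K27")
  keys <- c("K4:K36", "K4:K27", "K36:K27")
  tabs <- list(pair_target("K4", "K36", r[["K4:K36"]]),
               pair_target("K4", "K27", r[["K4:K27"]]),
               pair_target("K36", "K27", r[["K36:K27"]]))
  joint <- array(1 / 8, dim = c(2, 2, 2),
                 dimnames = list(K4 = c("FALSE", "TRUE"),
                                 K36 = c("FALSE", "TRUE"),
                                 K27 = c("FALSE", "TRUE")))
  for (iter in seq_len(5000)) {
    before <- joint
    for (t in seq_along(targets)) {
      dims <- targets[[t]]
      cur <- apply(joint, dims, sum)
      scale <- tabs[[t]] / cur
      scale[!is.finite(scale)] <- 0
      joint <- sweep_pair(joint, dims, scale)
    }
    if (max(abs(joint - before)) < 1e-12) break
  }
  for (t in seq_along(targets)) {
    if (max(abs(apply(joint, targets[[t]], sum) - tabs[[t]])) > 1e-6)
      stop("infeasible joint: IPF did not converge for pair ", keys[t])
  }
  joint / sum(joint)
}

# multiply each cell of a 2x2x2 array by a factor indexed by two of its dims
sweep_pair <- function(a, dims, fac) {
  idx <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  f <- fac[cbind(idx[, dims[1L]], idx[, dims[2L]])]
  array(a[idx] * f, dim = dim(a), dimnames = dimnames(a))
}

#' Simulate a gene annotation
#'
#' Genes laid end-to-end per chromosome with log-normal lengths and
#' exponential-plus-minimum intergenic gaps; random strands; subgenome
#' labels unset (assigned when triplets are drawn). Chromosome lengths are
#' recorded in `seqlengths`.
#'
#' @param cfg a [sim_config()].
#' @return `GRanges` gene set with `gene_id`, `subgenome`.
#' @export
simulate_genome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  len <- pmax(300L, as.integer(round(rlnorm(n, cfg$gene_length_meanlog,
                                            cfg$gene_length_sdlog))))
  gap <- cfg$gap_min +
    as.integer(round(rexp(n, 1 / max(1, cfg$gap_mean - cfg$gap_min))))
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  start <- integer(n)
  for (cx in seq_len(cfg$n_chromosomes)) {
    i <- which(chrom_of == cx)
    start[i] <- cumsum(gap[i]) + c(0L, cumsum(len[i][-length(i)]))
  }
  chrom <- paste0("A", sprintf("%02d", chrom_of))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L,
                                                width = len),
                               strand = sample(c("+", "-"), n, TRUE))
  mcols(gr)$gene_id <- sprintf("BraS%05d", seq_len(n))
  mcols(gr)$subgenome <- "unknown"
  sl <- vapply(split(end(gr), chrom), max, numeric(1)) + 5000
  seqlengths(gr) <- sl[seqlevels(gr)]
  gr
}

#' Simulate consensus and per-line mark states
#'
#' Consensus states are drawn per gene from the joint distribution of
#' [mark_joint_probs()]; each line then marks every consensus-marked gene
#' plus, independently per line and mark, consensus-unmarked genes at
#' `line_extra_rate`, so per-line marked sets exceed the consensus and the
#' across-line intersection recovers it.
#'
#' @param cfg a [sim_config()].
#' @param genes `GRanges` from [simulate_genome()].
#' @return list: `consensus` (mark state table) and `per_line` (named list
#'   of mark state tables, one per line).
#' @export
simulate_mark_states <- function(cfg, genes) {
  set.seed(cfg$seed + 1L)
  joint <- mark_joint_probs(cfg)
  cells <- as.matrix(expand.grid(K4 = c(FALSE, TRUE), K36 = c(FALSE, TRUE),
                                 K27 = c(FALSE, TRUE)))
  draw <- sample.int(8L, cfg$n_genes, replace = TRUE, prob = as.vector(joint))
  consensus <- data.frame(gene_id = genes$gene_id,
                          K4 = cells[draw, 1L], K36 = cells[draw, 2L],
                          K27 = cells[draw, 3L], stringsAsFactors = FALSE)
  per_line <- lapply(cfg$lines, function(l) {
    st <- consensus
    for (m in c("K4", "K36", "K27"))
      st[[m]] <- st[[m]] |
        (!consensus[[m]] & runif(cfg$n_genes) < cfg$line_extra_rate)
    st
  })
  names(per_line) <- cfg$lines
  list(consensus = consensus, per_line = per_line)
}

#' Simulate peak sets for every mark and line
#'
#' One peak per marked gene, anchored at the TSS (starting up to 150 bp
#' upstream of it) and extending into the body by a gamma-distributed
#' length, truncated 150 bp beyond the far gene end. Placement guarantees
#' a single-peak overlap with the flank-extended span of more than 400 bp
#' — comfortably beyond the 200 bp marked-gene threshold — while the
#' minimum intergenic gap keeps peaks out of neighbouring genes' extended
#' spans, so classification recovers the planted states.
#'
#' @param cfg a [sim_config()].
#' @param genes `GRanges` from [simulate_genome()].
#' @param line_states `per_line` element of [simulate_mark_states()].
#' @return nested list `peaks[[mark]][[line]]`, each a sorted `GRanges`
#'   with `metadata()$mark` / `$sample`.
#' @export
simulate_peaks <- function(cfg, genes, line_states) {
  set.seed(cfg$seed + 2L)
  gs <- start(genes); ge <- end(genes)
  tss_plus <- as.character(strand(genes)) == "+"
  out <- list()
  for (m in c("K4", "K36", "K27")) {
    out[[m]] <- list()
    for (l in names(line_states)) {
      idx <- which(line_states[[l]][[m]])
      n <- length(idx)
      if (n == 0L) {
        pk <- GenomicRanges::GRanges()
      } else {
        len <- pmax(420L, as.integer(round(
          rgamma(n, shape = cfg$peak_length_shape,
                 rate = cfg$peak_length_shape / cfg$peak_length_mean))))
        u <- as.integer(round(runif(n, 0, 150)))
        plus <- tss_plus[idx]
        ps <- pe <- integer(n)
        # anchor at the TSS and run into the gene body
        ps[plus] <- pmax(1L, gs[idx][plus] - u[plus])
        pe[plus] <- pmin(ge[idx][plus] + 150L, ps[plus] + len[plus] - 1L)
        pe[!plus] <- ge[idx][!plus] + u[!plus]
        ps[!plus] <- pmax(gs[idx][!plus] - 150L, pe[!plus] - len[!plus] + 1L)
        pk <- GenomicRanges::GRanges(seqnames(genes)[idx],
                                     IRanges::IRanges(ps, pe))
        mcols(pk)$score <- as.integer(round(runif(n, 20, 1000)))
        pk <- sort(pk, ignore.strand = TRUE)
      }
      metadata(pk)$mark <- m
      metadata(pk)$sample <- l
      out[[m]][[l]] <- pk
    }
  }
  out
}

# state-dependent tissue-specificity target (precedence K36 > K4 > K27)
tau_target_of_state <- function(cfg, states) {
  tm <- cfg$tau_mean
  ifelse(states$K36, tm[["K36"]],
         ifelse(states$K4, tm[["K4"]],
                ifelse(states$K27, tm[["K27"]], tm[["none"]])))
}

#' Build one expression profile with a planted tissue-specificity target
#'
#' One tissue (chosen at random) is expressed at `level` on the
#' `log2(FPKM + 1)` scale and the remaining tissues at
#' `level * (1 - target)`, so the tissue-specificity index of the
#' noiseless profile equals `target` exactly; Gaussian noise of SD
#' `noise_sd` is then added on the log scale and values floored at 0
#' before mapping back to FPKM.
#'
#' @param target tau target in `[0, 1]`.
#' @param level log2 expression of the maximal tissue (> 0).
#' @param n_tissues number of tissues.
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @return non-negative FPKM vector of length `n_tissues`.
#' @export
simulate_tau_profile <- function(target, level, n_tissues, noise_sd = 0) {
  if (target < 0 || target > 1) stop("tau target must lie in [0,1]")
  peak_tissue <- sample.int(n_tissues, 1L)
  lg <- rep(level * (1 - target), n_tissues)
  lg[peak_tissue] <- level
  lg <- pmax(lg + rnorm(n_tissues, 0, noise_sd), 0)
  2^lg - 1
}

#' Simulate a six-tissue FPKM matrix from mark states
#'
#' Gene-level expression `level ~ N(expr_base + sum(effects), expr_sd)` on
#' the log2 scale (floored at 0.1), spread over tissues by
#' [simulate_tau_profile()] with a state-dependent tau target.
#'
#' @param cfg a [sim_config()].
#' @param states consensus mark state table.
#' @return list: `fpkm` (genes x tissues matrix) and `truth` (data.frame
#'   `gene_id`, `level`, `tau_target`).
#' @export
simulate_expression <- function(cfg, states) {
  set.seed(cfg$seed + 3L)
  n <- nrow(states)
  eff <- cfg$expr_effect
  mu <- cfg$expr_base + eff[["K4"]] * states$K4 +
    eff[["K36"]] * states$K36 + eff[["K27"]] * states$K27
  level <- pmax(rnorm(n, mu, cfg$expr_sd), 0.1)
  tgt <- pmin(pmax(rnorm(n, tau_target_of_state(cfg, states),
                         cfg$tau_jitter_sd), 0.02), 0.95)
  fpkm <- t(vapply(seq_len(n), function(i)
    simulate_tau_profile(tgt[i], level[i], length(cfg$tissues),
                         cfg$tau_noise_sd),
    numeric(length(cfg$tissues))))
  dimnames(fpkm) <- list(states$gene_id, cfg$tissues)
  list(fpkm = fpkm,
       truth = data.frame(gene_id = states$gene_id, level = level,
                          tau_target = tgt, stringsAsFactors = FALSE))
}

#' Simulate a DEG set with mark-dependent membership odds
#'
#' Baseline odds `deg_rate / (1 - deg_rate)` multiplied by `deg_odds[m]`
#' for each mark carried (defaults deplete K36-marked and enrich
#' K27-marked genes among the DEGs).
#'
#' @param cfg a [sim_config()].
#' @param states consensus mark state table.
#' @return character vector of DEG gene IDs.
#' @export
simulate_degs <- function(cfg, states) {
  set.seed(cfg$seed + 4L)
  odds0 <- cfg$deg_rate / (1 - cfg$deg_rate)
  odds <- odds0 * cfg$deg_odds[["K4"]]^states$K4 *
    cfg$deg_odds[["K36"]]^states$K36 * cfg$deg_odds[["K27"]]^states$K27
  p <- odds / (1 + odds)
  states$gene_id[runif(nrow(states)) < p]
}

#' Simulate a paralog triplet table
#'
#' Draws `n_triplets` disjoint gene triples and labels the copies LF, MF1,
#' MF2 (every gene appears in at most one triplet).
#'
#' @param cfg a [sim_config()].
#' @param genes `GRanges` from [simulate_genome()].
#' @return data.frame `lf`, `mf1`, `mf2`, `complete`, `resolved`.
#' @export
simulate_triplets <- function(cfg, genes) {
  set.seed(cfg$seed + 5L)
  need <- 3L * cfg$n_triplets
  if (need > length(genes)) stop("not enough genes for n_triplets")
  ids <- sample(genes$gene_id, need)
  data.frame(lf = ids[seq(1L, need, 3L)],
             mf1 = ids[seq(2L, need, 3L)],
             mf2 = ids[seq(3L, need, 3L)],
             complete = TRUE, resolved = TRUE, stringsAsFactors = FALSE)
}

#' Simulate a ChIP-qPCR Ct table with planted enrichments
#'
#' Each target's true fold enrichment `E` enters as `-log2(E)` cycles on
#' its IP Ct relative to the reference gene; per-gene primer offsets are
#' shared between IP and input templates (and thus cancel in the
#' input-corrected ddCt), and every Ct receives Gaussian noise of SD
#' `ct_noise_sd`.
#'
#' @param cfg a [sim_config()].
#' @return Ct data.frame in [read_ct()] layout.
#' @export
simulate_ct <- function(cfg) {
  set.seed(cfg$seed + 6L)
  targets <- names(cfg$qpcr_enrichment)
  all_genes <- c(targets, cfg$qpcr_reference)
  primer <- setNames(runif(length(all_genes), -1, 1), all_genes)
  pulldown <- 5  # cycles between input and reference IP
  rows <- list()
  for (r in seq_len(cfg$qpcr_replicates)) {
    for (g in all_genes) {
      shift <- if (g == cfg$qpcr_reference) 0
               else -log2(cfg$qpcr_enrichment[[g]])
      rows[[length(rows) + 1L]] <- data.frame(
        target = g, antibody = "reChIP_K4K27",
        template = c("IP", "input"), replicate = r,
        ct = c(24 + primer[[g]] + pulldown + shift +
                 rnorm(1, 0, cfg$ct_noise_sd),
               24 + primer[[g]] + rnorm(1, 0, cfg$ct_noise_sd)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate the complete synthetic data set
#'
#' Runs every generator stage under seeds derived from `cfg$seed` and
#' optionally writes all external-format files (GFF3 gene models, one
#' narrowPeak per mark and line, FPKM TSV, DEG list, triplet TSV, Ct TSV,
#' the planted consensus states and a `truth.json` of planted parameters).
#' Identical configuration implies byte-identical outputs.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional directory to write files into (created if
#'   needed).
#' @return list: `config`, `genes`, `states` (consensus), `line_states`,
#'   `peaks` (`[[mark]][[line]]`), `fpkm`, `expression_truth`, `degs`,
#'   `triplets`, `ct`, and `files` (named paths when `outdir` given).
#' @export
simulate_dataset <- function(cfg, outdir = NULL) {
  genes <- simulate_genome(cfg)
  st <- simulate_mark_states(cfg, genes)
  peaks <- simulate_peaks(cfg, genes, st$per_line)
  expr <- simulate_expression(cfg, st$consensus)
  degs <- simulate_degs(cfg, st$consensus)
  triplets <- simulate_triplets(cfg, genes)
  ct <- simulate_ct(cfg)
  sub <- rep(c("LF", "MF1", "MF2"), nrow(triplets))
  ids <- as.vector(t(as.matrix(triplets[, c("lf", "mf1", "mf2")])))
  mcols(genes)$subgenome[match(ids, genes$gene_id)] <- sub
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(outdir, x)
    files <- c(genes = fp("genes.gff3"), fpkm = fp("fpkm.tsv"),
               degs = fp("degs.txt"), triplets = fp("triplets.tsv"),
               ct = fp("ct.tsv"), states = fp("mark_states.tsv"),
               truth = fp("truth.json"))
    write_gene_models(genes, files[["genes"]])
    write_expression(expr$fpkm, files[["fpkm"]])
    writeLines(degs, files[["degs"]])
    write_triplets(triplets, files[["triplets"]])
    write_ct(ct, files[["ct"]])
    write.table(st$consensus, files[["states"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (m in names(peaks)) for (l in names(peaks[[m]])) {
      f <- fp(paste0(m, "_", l, ".narrowPeak"))
      write_peaks(peaks[[m]][[l]], f)
      files[paste0("peaks_", m, "_", l)] <- f
    }
    truth <- list(seed = cfg$seed, n_genes = cfg$n_genes,
                  mark_freq = as.list(cfg$mark_freq),
                  cooccurrence_ratio = as.list(cfg$cooccurrence_ratio),
                  line_extra_rate = cfg$line_extra_rate,
                  expr_effect = as.list(cfg$expr_effect),
                  tau_mean = as.list(cfg$tau_mean),
                  deg_rate = cfg$deg_rate,
                  deg_odds = as.list(cfg$deg_odds),
                  qpcr_enrichment = as.list(cfg$qpcr_enrichment))
    jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE,
                         digits = NA)
  }
  list(config = cfg, genes = genes, states = st$consensus,
       line_states = st$per_line, peaks = peaks, fpkm = expr$fpkm,
       expression_truth = expr$truth, degs = degs, triplets = triplets,
       ct = ct, files = files)
}
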