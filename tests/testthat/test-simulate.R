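small_cfg <- function(seed = 7, n_genes = 1000, ...)
  sim_config(seed = seed, n_genes = n_genes,
             n_triplets = floor(n_genes / 10), ...)

test_that("the IPF joint reproduces marginals and pairwise ratios", {
  cfg <- small_cfg()
  joint <- mark_joint_probs(cfg)
  expect_equal(sum(joint), 1)
  pk4 <- sum(joint["TRUE", , ])
  pk36 <- sum(joint[, "TRUE", ])
  pk27 <- sum(joint[, , "TRUE"])
  expect_equal(pk4, 0.423, tolerance = 1e-8)
  expect_equal(pk36, 0.299, tolerance = 1e-8)
  expect_equal(pk27, 0.264, tolerance = 1e-8)
  expect_equal(sum(joint["TRUE", "TRUE", ]) / (pk4 * pk36), 2.0,
               tolerance = 1e-6)
  expect_equal(sum(joint["TRUE", , "TRUE"]) / (pk4 * pk27), 0.84,
               tolerance = 1e-6)
  expect_equal(sum(joint[, "TRUE", "TRUE"]) / (pk36 * pk27), 0.21,
               tolerance = 1e-6)
  expect_true(all(joint >= 0))
})

test_that("an infeasible joint is rejected before sampling", {
  expect_error(sim_config(cooccurrence_ratio = c("K4:K36" = 5,
                                                 "K4:K27" = 0.84,
                                                 "K36:K27" = 0.21)),
               "infeasible")
  expect_error(sim_config(mark_freq = c(K4 = 1.2, K36 = 0.3, K27 = 0.2)),
               "\\[0,1\\]")
})

test_that("generation is deterministic under one seed and varies across", {
  cfg <- small_cfg(n_genes = 300)
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  simulate_dataset(small_cfg(seed = 8, n_genes = 300), outdir = d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "genes.gff3")),
                         readLines(file.path(d3, "genes.gff3"))))
})

test_that("every emitted file parses and passes the type invariants", {
  cfg <- small_cfg(n_genes = 300)
  d <- tempfile()
  sim <- simulate_dataset(cfg, outdir = d)
  g <- read_gene_models(file.path(d, "genes.gff3"))
  expect_equal(length(g), 300L)
  expect_identical(ranges(g), ranges(sim$genes))
  expect_true(all(width(g) >= 300))
  pk <- read_peaks(file.path(d, "K4_T23.narrowPeak"))
  expect_identical(ranges(pk), ranges(sim$peaks$K4$T23))
  expect_true(all(width(pk) > 0))
  em <- read_expression(file.path(d, "fpkm.tsv"))
  expect_equal(em, sim$fpkm)
  expect_true(all(em >= 0))
  tr <- read_triplets(file.path(d, "triplets.tsv"), g)
  expect_true(all(tr$complete) && all(tr$resolved))
  expect_false(anyDuplicated(unlist(tr[, 1:3])) > 0)
  ct <- read_ct(file.path(d, "ct.tsv"))
  expect_true(all(ct$ct > 0))
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$mark_freq$K4, 0.423)
})

test_that("a zero mark frequency yields no peaks for that mark", {
  cfg <- small_cfg(n_genes = 200,
                   mark_freq = c(K4 = 0, K36 = 0.3, K27 = 0.25),
                   cooccurrence_ratio = c("K4:K36" = 1, "K4:K27" = 1,
                                          "K36:K27" = 0.21),
                   line_extra_rate = 0)
  sim <- simulate_dataset(cfg)
  expect_equal(length(sim$peaks$K4$T23), 0L)
  expect_equal(length(sim$peaks$K4$T24), 0L)
  expect_gt(length(sim$peaks$K36$T23), 0L)
})

test_that("classification of simulated peaks recovers the planted states", {
  cfg <- small_cfg(seed = 13)
  sim <- simulate_dataset(cfg)
  for (m in c("K4", "K36", "K27")) {
    status <- lapply(cfg$lines, function(l)
      classify_marked_genes(sim$genes, sim$peaks[[m]][[l]]))
    called <- sim$states$gene_id %in% consensus_marked(status)
    expect_gte(mean(called == sim$states[[m]]), 0.99)
  }
})

test_that("planted marginal frequencies land within binomial error", {
  cfg <- small_cfg(seed = 17)
  genes <- simulate_genome(cfg)
  st <- simulate_mark_states(cfg, genes)
  for (m in c("K4", "K36", "K27")) {
    p <- cfg$mark_freq[[m]]
    se <- sqrt(p * (1 - p) / cfg$n_genes)
    expect_lt(abs(mean(st$consensus[[m]]) - p), 3 * se)
    # per-line sets are supersets of the consensus
    for (l in cfg$lines)
      expect_true(all(st$per_line[[l]][[m]][st$consensus[[m]]]))
  }
})

test_that("noiseless tau profiles realise their target exactly", {
  set.seed(3)
  for (tgt in c(0, 0.25, 0.5, 0.8, 1)) {
    f <- simulate_tau_profile(tgt, 5, 6, noise_sd = 0)
    expect_equal(tau(f), tgt, tolerance = 1e-12)
  }
  expect_error(simulate_tau_profile(1.2, 5, 6), "\\[0,1\\]")
})

test_that("expression effects order the planted state means", {
  cfg <- small_cfg(seed = 23, n_genes = 2000)
  genes <- simulate_genome(cfg)
  st <- simulate_mark_states(cfg, genes)
  ex <- simulate_expression(cfg, st$consensus)
  lvl <- ex$truth$level
  s <- st$consensus
  m_both <- mean(lvl[s$K4 & s$K36 & !s$K27])
  m_k4 <- mean(lvl[s$K4 & !s$K36 & !s$K27])
  m_none <- mean(lvl[!s$K4 & !s$K36 & !s$K27])
  m_k27 <- mean(lvl[!s$K4 & !s$K36 & s$K27])
  expect_true(m_both > m_k4 && m_k4 > m_none && m_none > m_k27)
})
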