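test_that("mark state partition covers all eight cells and sums to N", {
  uni <- paste0("g", 1:100)
  st <- mark_state_table(uni, list(K4 = character(), K36 = character(),
                                   K27 = character()))
  part <- mark_state_partition(st)
  expect_equal(unname(part["none"]), 100L)
  expect_equal(sum(part), 100L)

  st2 <- mark_state_table(uni, list(K4 = paste0("g", 1:40),
                                    K36 = paste0("g", 21:50),
                                    K27 = paste0("g", 46:60)))
  part2 <- mark_state_partition(st2)
  expect_equal(sum(part2), 100L)
  expect_equal(unname(part2["K4+K36"]), 20L)       # g21..g40
  expect_equal(unname(part2["K36+K27"]), 5L)       # g46..g50
  expect_equal(unname(part2["K4"]), 20L)           # g1..g20
  expect_equal(unname(part2["none"]), 40L)         # g61..g100
})

test_that("planted partitions are recovered exactly", {
  set.seed(11)
  uni <- paste0("g", 1:500)
  marked <- list(K4 = sample(uni, 200), K36 = sample(uni, 150),
                 K27 = sample(uni, 120))
  st <- mark_state_table(uni, marked)
  part <- mark_state_partition(st)
  expect_equal(sum(part), 500L)
  k4_total <- sum(part[grepl("K4", names(part))])
  expect_equal(k4_total, 200L)
})

test_that("percentages round half-up to one decimal and complement", {
  expect_equal(percent_with_mark(1000, 0), 0.0)
  expect_equal(percent_with_mark(8, 1), 12.5)
  expect_error(percent_with_mark(0, 0), "> 0")
  expect_error(percent_with_mark(10, 11), "subset_marked")
  set.seed(5)
  for (i in 1:50) {
    a <- sample(50:5000, 1)
    b <- sample.int(a, 1)
    expect_lte(abs(percent_with_mark(a, b) + percent_with_mark(a, a - b)
                   - 100), 0.1)
  }
})

test_that("expected co-occurrence is the independence product", {
  r <- expected_cooccurrence(100, 100, 100, 80)
  expect_equal(r$expected, 100)
  expect_equal(r$ratio, 0.8)
  expect_error(expected_cooccurrence(10, 10, 0, 5), "N must be > 0")
  expect_error(expected_cooccurrence(20, 5, 10, 2), "exceed N")
})

test_that("independence expectation matches a label-permutation null", {
  set.seed(303)
  N <- 800; nA <- 330; nB <- 240
  a <- logical(N); a[seq_len(nA)] <- TRUE
  b <- logical(N); b[seq_len(nB)] <- TRUE
  perm <- replicate(2000, sum(a & sample(b)))
  analytic <- expected_cooccurrence(nA, nB, N, 0)
  se <- sd(perm) / sqrt(length(perm))
  expect_lt(abs(mean(perm) - analytic$expected), 3 * se)
  # the hypergeometric SD describes the same null
  expect_lt(abs(sd(perm) - analytic$sd_hypergeometric),
            0.1 * analytic$sd_hypergeometric)
})

test_that("overlap-length classes use the best peak pair within the span", {
  g <- gr_genes(1001, 3000)
  # A-peak and B-peak overlapping 600 bp inside the gene
  res <- peak_overlap_length_classes(gr_peaks(1001, 2000),
                                     gr_peaks(1401, 2600), g, "g1")
  expect_equal(unname(res$per_gene), 600)
  expect_equal(unname(res$fraction), c(1, 1))
  # disjoint peaks score zero
  res2 <- peak_overlap_length_classes(gr_peaks(1001, 1400),
                                      gr_peaks(2001, 2600), g, "g1")
  expect_equal(unname(res2$per_gene), 0)
  expect_equal(unname(res2$fraction), c(0, 0))
  expect_error(peak_overlap_length_classes(gr_peaks(1, 2), gr_peaks(1, 2),
                                           g, character()), "empty")
})

test_that("overlap-length fractions are monotone in the threshold", {
  set.seed(404)
  inst <- random_instance(30, 60)
  instB <- random_instance(30, 60)
  res <- peak_overlap_length_classes(inst$peaks, instB$peaks, inst$genes,
                                     inst$genes$gene_id)
  expect_gte(res$fraction[["150"]], res$fraction[["500"]])
  expect_true(all(res$per_gene >= 0))
})

test_that("ortholog conservation percentage behaves at the bounds", {
  ids <- paste0("at", 1:40)
  map <- data.frame(s1 = ids, s2 = paste0("br", 1:40))
  expect_equal(ortholog_mark_conservation(ids, map, paste0("br", 1:40)), 100)
  expect_equal(ortholog_mark_conservation(ids, map, character()), 0)
  expect_error(ortholog_mark_conservation(character(), map, "br1"), "empty")
})

test_that("a planted conservation rate is recovered within binomial error", {
  set.seed(505)
  p <- 0.6; n <- 400
  s1 <- paste0("at", 1:n)
  conserved <- runif(n) < p
  map <- data.frame(s1 = s1, s2 = paste0("br", 1:n))
  got <- ortholog_mark_conservation(s1, map, paste0("br", which(conserved)))
  expect_lt(abs(got / 100 - p), 3 * sqrt(p * (1 - p) / n))
})
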