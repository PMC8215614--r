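test_that("log2 transform floors out near-zero FPKM", {
  x <- c(8, 1, 0.005, 2)
  lx <- log2_expression(x)
  expect_equal(lx[1], 3.0)
  expect_equal(lx[2], 0.0)
  expect_true(is.na(lx[3]))
  expect_error(log2_expression(c(1, -1)), "non-negative")
})

test_that("tau hits its boundary cases", {
  expect_equal(tau(rep(5, 6)), 0)
  expect_equal(tau(c(8, 0, 0, 0, 0, 0)), 1)
  expect_equal(tau(rep(0, 6)), 0)                    # all-zero defined as 0
  expect_equal(tau(c(4, 2, 2, 2, 2, 2), transform = "none"), 0.5)
  expect_error(tau(5), ">= 2 tissues")
  expect_error(tau(c(-1, 2)), "non-negative")
})

test_that("tau is bounded and raw-mode scale invariant on random vectors", {
  set.seed(21)
  for (i in 1:200) {
    x <- runif(sample(2:10, 1), 0, 100)
    t1 <- tau(x, transform = "none")
    expect_gte(t1, 0); expect_lte(t1, 1)
    k <- runif(1, 0.1, 50)
    expect_equal(tau(k * x, transform = "none"), t1)
    tl <- tau(x)
    expect_gte(tl, 0); expect_lte(tl, 1)
  }
})

test_that("tau_matrix maps rows of an FPKM matrix", {
  m <- rbind(g1 = rep(5, 6), g2 = c(8, 0, 0, 0, 0, 0))
  tv <- tau_matrix(m)
  expect_equal(tv$tau, c(0, 1))
  expect_equal(tv$n_tissues, c(6L, 6L))
})

test_that("group summaries detect planted effects and not null ones", {
  set.seed(31)
  v0 <- setNames(rnorm(200), paste0("g", 1:200))
  g0 <- setNames(rep(c("a", "b"), each = 100), names(v0))
  null_res <- group_summary(g0, v0)
  expect_false(any(null_res$pairwise$significant))
  # planted +2 shift on the marked group
  v1 <- v0; v1[101:200] <- v1[101:200] + 2
  eff <- group_summary(g0, v1)
  expect_true(all(eff$pairwise$significant))
  expect_gt(eff$summary$mean[eff$summary$group == "b"],
            eff$summary$mean[eff$summary$group == "a"])
  # single group: summary only
  solo <- group_summary(setNames(rep("a", 200), names(v0)), v0)
  expect_null(solo$pairwise)
  expect_warning(group_summary(setNames(c(rep("a", 199), "tiny"),
                                        names(v0)), v0), "n < 2")
})

test_that("DEG mark enrichment matches the closed-form 2x2 chi-squared", {
  uni <- paste0("g", 1:1000)
  # identical marked fraction inside and outside the DEG set
  deg <- uni[1:200]
  marked <- uni[c(1:60, 201:440)]                    # 30% both sides
  r <- deg_mark_enrichment(deg, marked, uni)
  expect_lt(r$statistic, 1e-10)
  expect_equal(r$direction, "equal")
  # closed form N(ad-bc)^2 / row/col products on random fixtures
  set.seed(41)
  for (i in 1:20) {
    d <- sample(uni, 150); m <- sample(uni, 300)
    r <- deg_mark_enrichment(d, m, uni)
    a <- as.numeric(r$a); b <- as.numeric(r$b)
    cc <- as.numeric(r$c); dd <- as.numeric(r$d)
    N <- a + b + cc + dd
    closed <- N * (a * dd - b * cc)^2 /
      ((a + b) * (cc + dd) * (a + cc) * (b + dd))
    expect_equal(r$statistic, closed)
    # symmetry of the 2x2
    expect_equal(deg_mark_enrichment(m, d, uni)$statistic, r$statistic)
  }
  expect_error(deg_mark_enrichment(uni, uni[1:10], uni), "margin")
})

test_that("a planted mark depletion among DEGs is strongly detected", {
  # marked rate 0.10 inside 250 DEGs vs 0.30 outside, N = 40000
  N <- 40000; n_deg <- 250
  uni <- paste0("g", seq_len(N))
  deg <- uni[seq_len(n_deg)]
  marked <- c(uni[seq_len(25)],                         # 10% of DEGs
              uni[n_deg + seq_len(round(0.30 * (N - n_deg)))])
  r <- deg_mark_enrichment(deg, marked, uni)
  expect_equal(r$direction, "lower")
  expect_lt(r$p_value, 1e-5)
})

test_that("SNP density contrasts recover planted rate ratios", {
  vr <- data.frame(gene_id = paste0("g", 1:100),
                   snp_count = rep(10, 100), length_bp = rep(1000, 100))
  same <- snp_density_contrast(vr, paste0("g", 1:50))
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  set.seed(51)
  vr2 <- data.frame(gene_id = paste0("g", 1:400),
                    snp_count = c(rpois(200, 15), rpois(200, 10)),
                    length_bp = 1000)
  r <- snp_density_contrast(vr2, paste0("g", 1:200))
  expect_gt(r$ratio, 1.2)
  expect_lt(r$p_value, 0.01)
  vr2$length_bp[1] <- 0
  expect_error(snp_density_contrast(vr2, paste0("g", 1:200)), "length")
})
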