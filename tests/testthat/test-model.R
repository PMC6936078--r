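test_that("log_evidence matches closed-form and quadrature values", {
  # empty data: B(a,b)/B(a,b) = 1
  expect_identical(log_evidence(0, 0, 1, 30), 0)
  expect_identical(log_evidence(0, 0, 2, 2), 0)
  # single alternate read under the WW prior: 1/31
  expect_equal(log_evidence(0, 1, 1, 30), log(1 / 31), tolerance = 1e-12)
  # single reference read under the WW prior: 30/31
  expect_equal(log_evidence(1, 0, 1, 30), log(30 / 31), tolerance = 1e-12)
  # quadrature oracle on a small grid (full grid in the acceptance suite)
  for (ab in list(c(1, 30), c(2, 2), c(30, 1))) {
    for (m in c(0, 3, 50)) for (n in c(1, 7)) {
      expect_equal(log_evidence(m, n, ab[1], ab[2]),
                   quad_log_evidence(m, n, ab[1], ab[2]),
                   tolerance = 1e-8)
    }
  }
  expect_error(log_evidence(-1, 0, 1, 30), "non-negative")
})

test_that("log_evidence is numerically stable at million-read depth", {
  v <- log_evidence(1e6, 5e5, 1, 30)
  expect_true(is.finite(v))
  # closed-form via log-gamma identity, computed independently
  direct <- (lgamma(1 + 5e5) + lgamma(30 + 1e6) - lgamma(31 + 1.5e6)) -
    (lgamma(1) + lgamma(30) - lgamma(31))
  expect_equal(v, direct, tolerance = 1e-12)
})

test_that("genotype-pair matrices carry Hardy-Weinberg structure", {
  expect_equal(diag(same_individual_matrix(0.5)), c(WW = 0.25, WA = 0.5,
                                                    AA = 0.25))
  expect_equal(diag(same_individual_matrix(0.2)), c(WW = 0.64, WA = 0.32,
                                                    AA = 0.04))
  expect_equal(different_individuals_matrix(0.5)[1, 1], 0.0625)
  set.seed(3)
  for (q in runif(200, 1e-6, 1 - 1e-6)) {
    I_mat <- same_individual_matrix(q)
    D_mat <- different_individuals_matrix(q)
    expect_equal(sum(I_mat), 1, tolerance = 1e-12)
    expect_equal(sum(D_mat), 1, tolerance = 1e-12)
    expect_equal(D_mat, outer(diag(I_mat), diag(I_mat)), tolerance = 1e-15)
  }
  expect_error(same_individual_matrix(0), "strictly inside")
  expect_error(different_individuals_matrix(1), "strictly inside")
})

test_that("fingerprint stores per-genotype evidence and coverage flags", {
  panel <- tiny_panel(c(0.2, 0.5, 0.7))
  fp0 <- counts_fp(c(0, 0, 0), c(0, 0, 0), panel)
  expect_equal(unname(fp0$logq), matrix(0, 3, 3))
  expect_false(any(fp0$covered))

  fp <- counts_fp(c(0, 4, 2), c(1, 0, 3), panel)
  for (i in 1:3) for (g in 1:3) {
    ab <- list(c(1, 30), c(2, 2), c(30, 1))[[g]]
    expect_equal(unname(fp$logq[i, g]),
                 quad_log_evidence(fp$m[i], fp$n[i], ab[1], ab[2]),
                 tolerance = 1e-8)
  }
  expect_equal(fp$covered, c(TRUE, TRUE, TRUE))
  # pure function: bit-identical on repeat
  expect_identical(fp, counts_fp(c(0, 4, 2), c(1, 0, 3), panel))
  expect_error(counts_fp(c(0, 1), c(0, 0), panel), "match panel size")
})

test_that("posterior reduces to the prior with zero evidence and NOTESTs otherwise", {
  panel <- tiny_panel(c(0.3, 0.6))
  fa <- counts_fp(c(0, 0), c(0, 0), panel, sample_id = "a")
  fb <- counts_fp(c(0, 0), c(0, 0), panel, sample_id = "b")
  r <- posterior_same(fa, fb, panel)
  expect_true(r$notest)
  expect_true(is.na(r$posterior))
  # bypassing the gate: every per-SNP factor is 1, posterior == prior exactly
  r2 <- posterior_same(fa, fb, panel, allow_notest = FALSE)
  expect_identical(r2$posterior, 0.01)
  expect_identical(r2$log10_bf, 0)
})

test_that("discordant homozygotes at high depth depress the posterior below the prior", {
  panel <- tiny_panel(0.5)
  fa <- counts_fp(50, 0, panel, sample_id = "a")
  fb <- counts_fp(0, 50, panel, sample_id = "b")
  r <- posterior_same(fa, fb, panel)
  expect_lt(r$posterior, 0.01)
  oracle <- brute_posterior(50, 0, 0, 50, 0.5)
  expect_equal(r$log_odds, oracle$log_odds, tolerance = 1e-10)
})

test_that("posterior agrees with the literal matrix-product oracle on random counts", {
  set.seed(21)
  for (rep in 1:25) {
    n_snps <- sample(c(1, 5, 50), 1)
    q <- runif(n_snps, 0.1, 0.9)
    ma <- rpois(n_snps, 4); na <- rpois(n_snps, 2)
    mb <- rpois(n_snps, 3); nb <- rpois(n_snps, 3)
    panel <- tiny_panel(q)
    fa <- counts_fp(ma, na, panel, sample_id = "a")
    fb <- counts_fp(mb, nb, panel, sample_id = "b")
    r <- posterior_same(fa, fb, panel)
    keep <- fa$covered & fb$covered
    if (!any(keep)) next
    oracle <- brute_posterior(ma[keep], na[keep], mb[keep], nb[keep], q[keep])
    expect_lte(rel_diff(r$log_odds, oracle$log_odds), 1e-10)
  }
})

test_that("posterior is symmetric, order-invariant and binomial-factor-invariant", {
  set.seed(33)
  n_snps <- 40
  q <- runif(n_snps, 0.1, 0.9)
  ma <- rpois(n_snps, 4); na <- rpois(n_snps, 2)
  mb <- rpois(n_snps, 3); nb <- rpois(n_snps, 3)
  panel <- tiny_panel(q)
  fa <- counts_fp(ma, na, panel, sample_id = "a")
  fb <- counts_fp(mb, nb, panel, sample_id = "b")
  r_ab <- posterior_same(fa, fb, panel)
  r_ba <- posterior_same(fb, fa, panel)
  expect_identical(r_ab$posterior, r_ba$posterior)
  expect_identical(r_ab$log_odds, r_ba$log_odds)

  # permuting panel order leaves the posterior unchanged
  perm <- sample.int(n_snps)
  panel_p <- tiny_panel(q[perm])
  fa_p <- counts_fp(ma[perm], na[perm], panel_p, sample_id = "a")
  fb_p <- counts_fp(mb[perm], nb[perm], panel_p, sample_id = "b")
  r_p <- posterior_same(fa_p, fb_p, panel_p)
  expect_lte(rel_diff(r_p$log_odds, r_ab$log_odds), 1e-12)

  # the binomial coefficient is common to both hypotheses and cancels
  params_c <- model_params(keep_binomial = TRUE)
  fa_c <- counts_fp(ma, na, panel, params_c, sample_id = "a")
  fb_c <- counts_fp(mb, nb, panel, params_c, sample_id = "b")
  r_c <- posterior_same(fa_c, fb_c, panel, params_c)
  expect_lte(rel_diff(r_c$log_odds, r_ab$log_odds), 1e-12)
})

test_that("SNPs covered in only one sample contribute equally to both hypotheses", {
  set.seed(44)
  n_snps <- 30
  q <- runif(n_snps, 0.1, 0.9)
  ma <- rpois(n_snps, 4); na <- rpois(n_snps, 2)
  mb <- rpois(n_snps, 3); nb <- rpois(n_snps, 3)
  # knock sample b's coverage out at a third of the SNPs
  zero <- sample.int(n_snps, 10)
  mb[zero] <- 0L; nb[zero] <- 0L
  panel <- tiny_panel(q)
  fa <- counts_fp(ma, na, panel, sample_id = "a")
  fb <- counts_fp(mb, nb, panel, sample_id = "b")
  r_skip <- posterior_same(fa, fb, panel)
  expect_equal(r_skip$n_co_covered, n_snps - 10L)
  # computing over all SNPs (uncovered evidence triple is (1,1,1)) must give
  # the same log odds: Tr(Q I) = sum_h Q(h) v_h = Tr(Q D) there
  keep_all <- rep(TRUE, n_snps)
  lv <- snpmatchr:::log_hw_matrix(q)
  a <- snpmatchr:::precompute_pair_terms(fa, lv)
  b <- snpmatchr:::precompute_pair_terms(fb, lv)
  lr_all <- snpmatchr:::pair_log_lr(a, b, lv, keep_all)
  lr_skip <- snpmatchr:::pair_log_lr(a, b, lv, fa$covered & fb$covered)
  expect_lte(rel_diff(lr_all, lr_skip), 1e-12)
})

test_that("trace over the joint-genotype matrix factorizes under independence", {
  set.seed(55)
  for (r in 1:20) {
    q <- runif(1, 0.05, 0.95)
    Qa <- runif(3); Qb <- runif(3)
    Qhat <- outer(Qa, Qb)
    D_mat <- different_individuals_matrix(q)
    v <- diag(same_individual_matrix(q))
    expect_equal(sum(diag(Qhat %*% D_mat)), sum(Qa * v) * sum(Qb * v),
                 tolerance = 1e-12)
  }
})

test_that("concordant depth raises and discordant depth lowers the posterior monotonically", {
  panel <- tiny_panel(0.5)
  depths <- c(1, 2, 5, 10, 20, 50)
  conc <- vapply(depths, function(d) {
    posterior_same(counts_fp(d, 0, panel, sample_id = "a"),
                   counts_fp(d, 0, panel, sample_id = "b"),
                   panel)$log_odds
  }, numeric(1))
  disc <- vapply(depths, function(d) {
    posterior_same(counts_fp(d, 0, panel, sample_id = "a"),
                   counts_fp(0, d, panel, sample_id = "b"),
                   panel)$log_odds
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
  expect_true(all(diff(disc) < 0))
})

test_that("fingerprints from different panels refuse to be compared", {
  panel1 <- tiny_panel(c(0.3, 0.5))
  panel2 <- tiny_panel(c(0.3, 0.6))
  fa <- counts_fp(c(1, 1), c(0, 0), panel1, sample_id = "a")
  fb <- counts_fp(c(1, 1), c(0, 0), panel2, sample_id = "b")
  expect_error(posterior_same(fa, fb, panel1), "hash")
})

test_that("fingerprints round-trip through JSON exactly", {
  panel <- tiny_panel(c(0.25, 0.5, 0.75))
  fp <- counts_fp(c(3, 0, 7), c(1, 0, 2), panel, sample_id = "s1")
  f <- withr::local_tempfile(fileext = ".json")
  write_fingerprint(fp, f)
  fp2 <- read_fingerprint(f)
  expect_identical(fp2$sample_id, fp$sample_id)
  expect_identical(fp2$panel_hash, fp$panel_hash)
  expect_identical(fp2$m, fp$m)
  expect_identical(fp2$n, fp$n)
  expect_identical(fp2$covered, fp$covered)
  expect_equal(fp2$logq, fp$logq, tolerance = 0, ignore_attr = FALSE)
})
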