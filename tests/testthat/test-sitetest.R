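test_that("identical groups give a null result", {
  r <- fit_site_glm(rbind(c(5, 5)), rbind(c(5, 5)))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_equal(r$delta, 0)
  expect_equal(r$direction, 0)
})

test_that("fully separated groups match the hand-computed deviance", {
  # 3 samples of (10, 0) vs 3 of (0, 10): G = 2 * 60 * ln 2
  r <- fit_site_glm(matrix(c(10, 10, 10, 0, 0, 0), ncol = 2),
                    matrix(c(0, 0, 0, 10, 10, 10), ncol = 2))
  expect_equal(r$statistic, 2 * 60 * log(2), tolerance = 1e-12)
  expect_lt(r$p, 1e-15)
  expect_equal(r$pi_a, 1)
  expect_equal(r$pi_b, 0)
})

test_that("label swap preserves p and negates delta", {
  set.seed(21)
  for (i in 1:20) {
    a <- cbind(rbinom(3, 30, 0.6), rbinom(3, 30, 0.4))
    b <- cbind(rbinom(6, 30, 0.4), rbinom(6, 30, 0.6))
    r1 <- fit_site_glm(a, b)
    r2 <- fit_site_glm(b, a)
    expect_equal(r1$p, r2$p, tolerance = 1e-12)
    expect_equal(r1$delta, -r2$delta, tolerance = 1e-12)
  }
})

test_that("closed-form LRT agrees with a glm() binomial fit", {
  set.seed(31)
  for (i in 1:30) {
    na <- sample(2:4, 1); nb <- sample(2:6, 1)
    cov <- sample(5:40, na + nb, replace = TRUE)
    p_true <- runif(2, 0.05, 0.95)
    meth <- rbinom(na + nb, cov, rep(p_true, c(na, nb)))
    grp <- factor(rep(c("A", "B"), c(na, nb)))
    fit1 <- stats::glm(cbind(meth, cov - meth) ~ grp, family = binomial)
    fit0 <- stats::glm(cbind(meth, cov - meth) ~ 1, family = binomial)
    g_glm <- fit0$deviance - fit1$deviance
    r <- fit_site_glm(cbind(meth, cov - meth)[grp == "A", , drop = FALSE],
                      cbind(meth, cov - meth)[grp == "B", , drop = FALSE])
    expect_equal(r$statistic, g_glm, tolerance = 1e-8)
    expect_equal(r$p, pchisq(g_glm, 1, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("GLM p-values track Fisher's exact ordering on 2x2 tables", {
  # moderate margins: below ~20 reads the exact test's discreteness (heavy
  # ties) caps any rank agreement with a continuous statistic
  set.seed(41)
  p_glm <- p_fish <- numeric(200)
  for (i in 1:200) {
    ca <- sample(20:60, 1); cb <- sample(20:60, 1)
    ma <- rbinom(1, ca, runif(1, 0.1, 0.9))
    mb <- rbinom(1, cb, runif(1, 0.1, 0.9))
    p_glm[i] <- fit_site_glm(cbind(ma, ca - ma), cbind(mb, cb - mb))$p
    p_fish[i] <- stats::fisher.test(rbind(c(ma, ca - ma),
                                          c(mb, cb - mb)))$p.value
  }
  expect_gt(cor(p_glm, p_fish, method = "spearman"), 0.99)
})

test_that("zero-coverage groups are rejected at single sites and skipped in cohorts", {
  expect_error(fit_site_glm(rbind(c(0, 0)), rbind(c(5, 5))), "zero total coverage")

  # one CpG (pos 500) covered only in group A: absent from results, logged
  samples <- one_site_cohort(c(10, 12), c(20, 20), c(5, 6), c(20, 20))
  extra <- cpg_sites("chr1", c(100L, 500L), c(10L, 8L), c(10L, 2L))
  samples[[1L]] <- methylome_sample("A1", "A", extra)
  samples[[2L]]$sites <- cpg_sites("chr1", c(100L, 500L), c(12L, 9L), c(8L, 1L))
  res <- test_all_sites(samples, min_cov = 5)
  expect_equal(res$pos, 100L)
  skipped <- attr(res, "skipped")
  expect_equal(skipped$pos, 500L)
  expect_match(skipped$reason, "group B")
})

test_that("cohort-level results respect the output contract", {
  coh <- simulate_cohort(build_layout(), sim_config(seed = 6))
  res <- test_all_sites(coh$samples)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$delta >= -1 & res$delta <= 1))
  expect_identical(res$direction, sign(res$delta))
  for (chr in unique(res$chrom)) {
    expect_true(all(diff(res$pos[res$chrom == chr]) > 0))
  }
  expect_error(test_all_sites(coh$samples[1:3]), "two groups")
})

test_that("dispersion estimate calibrates at rho = 0 and detects rho > 0", {
  lay <- null_layout(chrom_length = 150000L)  # 1500 CpGs
  c0 <- simulate_cohort(lay, sim_config(background_pi = 0.8, rho = 0,
                                        seed = 13))
  expect_lt(abs(estimate_dispersion(c0$samples, "B") - 1), 0.2)
  c1 <- simulate_cohort(lay, sim_config(background_pi = 0.8, rho = 0.1,
                                        seed = 13))
  expect_gt(estimate_dispersion(c1$samples, "B"), 1.2)
  # single-sample group: not estimable
  expect_true(is.na(estimate_dispersion(c0$samples[1L], "A")))
})

test_that("power grows with effect size and with coverage", {
  lay <- null_layout(chrom_length = 30000L)  # 300 CpGs
  power_at <- function(delta, coverage) {
    dmrs <- data.frame(start = 0L, end = 30000L, pi_a = 0.5 + delta,
                       pi_b = 0.5)
    l2 <- build_layout(chrom_length = 30000L,
                       islands = data.frame(start = integer(), end = integer()),
                       dmrs = dmrs,
                       lmrs = data.frame(start = integer(), end = integer()))
    coh <- simulate_cohort(l2, sim_config(mean_coverage = coverage, rho = 0,
                                          seed = 17))
    mean(test_all_sites(coh$samples)$p < 0.05)
  }
  by_delta <- vapply(c(0.05, 0.15, 0.35), power_at, 0, coverage = 20)
  expect_true(all(diff(by_delta) > 0))
  by_cov <- vapply(c(8, 25, 80), function(cv) power_at(0.1, cv), 0)
  expect_true(all(diff(by_cov) > 0))
})
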