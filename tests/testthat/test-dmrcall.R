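test_that("uniform product CDF matches its closed forms and domain", {
  expect_equal(uniform_product_cdf(0.05, 1), 0.05)
  expect_equal(uniform_product_cdf(1, 7), 1)
  # k = 3, x = 0.01: x * (1 + (-ln x) + (-ln x)^2 / 2)
  expect_equal(uniform_product_cdf(0.01, 3),
               0.01 * (1 + 4.60517 + 10.6038), tolerance = 1e-4)
  expect_error(uniform_product_cdf(0, 3), "in \\(0, 1\\]")
  expect_error(uniform_product_cdf(1.5, 3), "in \\(0, 1\\]")
  expect_error(uniform_product_cdf(0.5, 0), "k must")
  # log-space entry handles products far below double underflow
  expect_gt(uniform_product_cdf(-600, 10, log_x = TRUE), 0)
})

test_that("uniform product CDF agrees with the chi-square survival form", {
  x <- exp(seq(log(1e-12), log(1), length.out = 60))
  for (k in c(1, 2, 3, 5, 10, 25, 50)) {
    expect_equal(uniform_product_cdf(x, k),
                 pchisq(-2 * log(x), df = 2 * k, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("uniform product CDF is monotone in x and in k", {
  x <- exp(seq(log(1e-8), log(1), length.out = 40))
  for (k in c(1, 4, 12)) expect_true(all(diff(uniform_product_cdf(x, k)) >= 0))
  # a product of more uniforms is stochastically smaller, so at fixed x < 1
  # the CDF grows with k
  at_k <- vapply(1:15, function(k) uniform_product_cdf(0.3, k), 0)
  expect_true(all(diff(at_k) >= 0))
})

test_that("segmentation finds same-direction runs within the gap limit", {
  res <- fake_results(pos = c(100, 150, 200, 250, 300), p = rep(0.001, 5))
  cand <- segment_candidates(res, alpha_site = 0.01, max_gap = 500,
                             min_sites = 3)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$n_sig, 5L)
  expect_equal(cand$start, 100L)
  expect_equal(cand$end, 301L)

  # alternating directions never form a run
  alt <- fake_results(pos = seq(100, 600, by = 100), p = rep(0.001, 6),
                      delta = rep(c(0.5, -0.5), 3))
  expect_equal(nrow(segment_candidates(alt)), 0L)

  # a 10-kb gap splits two clusters
  two <- fake_results(pos = c(100, 200, 300, 10400, 10500, 10600),
                      p = rep(0.001, 6))
  expect_equal(nrow(segment_candidates(two)), 2L)

  # interior non-significant sites are recorded as span members
  mix <- fake_results(pos = c(100, 200, 300, 400, 500),
                      p = c(0.001, 0.001, 0.8, 0.001, 0.001))
  cand <- segment_candidates(mix, min_sites = 3)
  expect_equal(cand$n_sig, 4L)
  expect_equal(lengths(cand$span_members), 5L)
})

test_that("DMR calls combine member p-values via the exact product null", {
  res <- fake_results(pos = c(100, 150, 200, 250, 300), p = rep(0.001, 5))
  d <- call_dmrs(res, combine_scope = "significant_only")
  expect_equal(nrow(d), 1L)
  expect_equal(d$k, 5L)
  # product 1e-15 over k = 5 uniforms; cross-check vs chi-square form
  expect_equal(d$combined_p, 6.6794e-11, tolerance = 1e-4)
  expect_equal(d$combined_p, pchisq(-2 * log(1e-15), 10, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(d$direction, "hyper")

  # all p = 1: nothing is called
  flat <- fake_results(pos = seq(100, 1000, by = 100), p = rep(1, 10))
  expect_equal(nrow(call_dmrs(flat)), 0L)
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # q is monotone non-decreasing in p-rank
  set.seed(8)
  p <- runif(50)
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("called DMRs on a planted cohort are sorted, disjoint and near truth", {
  coh <- simulate_cohort(build_layout(), sim_config(seed = 23))
  d <- call_dmrs(test_all_sites(coh$samples))
  expect_gt(nrow(d), 0L)
  expect_true(all(diff(d$start) > 0))
  if (nrow(d) > 1L) expect_true(all(d$start[-1L] >= d$end[-nrow(d)]))
  truth <- coh$truth[grepl("^dmr", coh$truth$name), ]
  near <- vapply(seq_len(nrow(d)), function(j) {
    any(d$start[j] < truth$end + 1000 & truth$start - 1000 < d$end[j])
  }, TRUE)
  expect_true(all(near))
  expect_true(all(d$n_sig >= 3L))
})

test_that("null genomes yield no DMR calls across seeds", {
  lay <- null_layout(chrom_length = 200000L)  # 2000 CpGs, nothing planted
  total <- 0L
  for (seed in 1:5) {
    coh <- simulate_cohort(lay, sim_config(background_pi = 0.8, rho = 0,
                                           seed = seed))
    total <- total + nrow(call_dmrs(test_all_sites(coh$samples)))
  }
  expect_lte(total, 1L)
})
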