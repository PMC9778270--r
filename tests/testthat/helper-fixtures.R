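# shared fixture builders; all randomness is seeded by the caller

random_sites <- function(n, chrom = "chr1", max_cov = 60L) {
  pos <- sort(sample.int(10 * n, n))
  cov <- sample.int(max_cov, n, replace = TRUE)
  meth <- rbinom(n, cov, runif(n))
  cpg_sites(chrom, pos, meth, as.integer(cov - meth))
}

# layout with a flat background and nothing planted (null genome)
null_layout <- function(chrom_length = 100000L, spacing = 100L) {
  build_layout(chrom_length = chrom_length,
               islands = data.frame(start = integer(), end = integer()),
               dmrs = data.frame(start = integer(), end = integer()),
               lmrs = data.frame(start = integer(), end = integer()),
               background_spacing = spacing)
}

# cohort of per-sample binomial counts at a single CpG, as methylome samples
one_site_cohort <- function(meth_a, cov_a, meth_b, cov_b, pos = 100L) {
  mk <- function(m, cv, g, i) {
    methylome_sample(sprintf("%s%d", g, i), g,
                     cpg_sites("chr1", pos, m, as.integer(cv - m)))
  }
  c(lapply(seq_along(meth_a), function(i) mk(meth_a[i], cov_a[i], "A", i)),
    lapply(seq_along(meth_b), function(i) mk(meth_b[i], cov_b[i], "B", i)))
}

# synthetic site-test result table with chosen p-values/directions
fake_results <- function(pos, p, direction = 1L, delta = NULL,
                         chrom = "chr1") {
  if (is.null(delta)) delta <- 0.5 * direction
  structure(data.frame(chrom = chrom, pos = as.integer(pos),
                       pi_a = 0.5 + delta / 2, pi_b = 0.5 - delta / 2,
                       delta = delta, direction = sign(delta),
                       statistic = qchisq(p, 1, lower.tail = FALSE),
                       p = p, n_samples_used = 9L,
                       stringsAsFactors = FALSE),
            class = c("site_test_results", "data.frame"),
            groups = c("A", "B"))
}
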