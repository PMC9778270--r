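# binomial log-likelihood of pooled counts at rate p (kernel only; the
# binomial coefficients cancel in every deviance difference we form)
binom_ll <- function(m, u, p) {
  ll <- numeric(length(m))
  nz <- m > 0
  ll[nz] <- ll[nz] + m[nz] * log(p[nz])
  nz <- u > 0
  ll[nz] <- ll[nz] + u[nz] * log(1 - p[nz])
  ll
}

# vectorised two-group binomial-logit likelihood-ratio test.  With a single
# two-level factor the GLM maximum-likelihood fit is the group-pooled
# fraction, so the deviance difference has a closed form:
#   G = 2 * [ ll(MA, CA, pA) + ll(MB, CB, pB) - ll(MA+MB, CA+CB, p0) ]
# identical to the glm(cbind(meth, unmeth) ~ group) anova deviance.
site_lrt <- function(MA, CA, MB, CB) {
  pA <- ifelse(CA > 0, MA / CA, NA_real_)
  pB <- ifelse(CB > 0, MB / CB, NA_real_)
  p0 <- (MA + MB) / (CA + CB)
  stat <- 2 * (binom_ll(MA, CA - MA, pA) + binom_ll(MB, CB - MB, pB) -
                 binom_ll(MA + MB, CA + CB - MA - MB, p0))
  stat[stat < 0] <- 0  # guard tiny negative rounding
  list(stat = stat, pi_a = pA, pi_b = pB)
}

#' Two-group binomial GLM likelihood-ratio test at one CpG
#'
#' Fits the binomial-logit model `logit(pi) = b0 + b1 * [group == A]` to
#' per-sample (methylated, unmethylated) counts and tests `b1 = 0` by the
#' likelihood-ratio (deviance difference, 1 df, chi-square reference,
#' two-sided).  The methylation difference `delta` is estimated from
#' group-pooled fractions with Haldane-Anscombe 0.5 pseudo-counts; the test
#' statistic itself uses raw counts only (boundary fits are handled by the
#' `0 * log(0) = 0` continuity convention, never by pseudo-counts).
#'
#' @param counts_a,counts_b two-column matrices (or data.frames) of
#'   `(meth, unmeth)` per sample, one row per sample.
#' @param dispersion scale applied to the LRT statistic (quasi-binomial
#'   scaling; 1 = pure binomial).
#' @return A one-row `data.frame`: `pi_a`, `pi_b` (pooled fractions),
#'   `delta`, `direction`, `statistic` (unscaled deviance difference), `p`,
#'   `n_samples_used`.
#' @examples
#' fit_site_glm(rbind(c(10, 0), c(9, 1)), rbind(c(1, 9), c(0, 10)))
#' @export
fit_site_glm <- function(counts_a, counts_b, dispersion = 1) {
  counts_a <- matrix(as.numeric(as.matrix(counts_a)), ncol = 2L)
  counts_b <- matrix(as.numeric(as.matrix(counts_b)), ncol = 2L)
  MA <- sum(counts_a[, 1L]); CA <- sum(counts_a)
  MB <- sum(counts_b[, 1L]); CB <- sum(counts_b)
  if (CA <= 0 || CB <= 0) {
    stop("fit_site_glm: a group has zero total coverage at this site")
  }
  r <- site_lrt(MA, CA, MB, CB)
  delta <- (MA + 0.5) / (CA + 1) - (MB + 0.5) / (CB + 1)
  data.frame(pi_a = r$pi_a, pi_b = r$pi_b, delta = delta,
             direction = sign(delta), statistic = r$stat,
             p = stats::pchisq(r$stat / dispersion, df = 1, lower.tail = FALSE),
             n_samples_used = nrow(counts_a) + nrow(counts_b))
}

# assemble aligned per-sample count matrices over the union of sites
cohort_matrices <- function(samples) {
  keys <- lapply(samples, function(s) paste(s$sites$chrom, s$sites$pos))
  all_key <- unique(unlist(keys))
  first <- !duplicated(unlist(keys))
  chrom <- unlist(lapply(samples, function(s) s$sites$chrom))[first]
  pos <- unlist(lapply(samples, function(s) s$sites$pos))[first]
  o <- order(chrom, pos)
  all_key <- all_key[o]; chrom <- chrom[o]; pos <- pos[o]
  n <- length(all_key); k <- length(samples)
  M <- matrix(0, n, k); C <- matrix(0, n, k)
  for (j in seq_len(k)) {
    idx <- match(keys[[j]], all_key)
    M[idx, j] <- samples[[j]]$sites$meth
    C[idx, j] <- samples[[j]]$sites$meth + samples[[j]]$sites$unmeth
  }
  list(chrom = chrom, pos = pos, M = M, C = C,
       groups = vapply(samples, `[[`, "", "group"),
       ids = vapply(samples, `[[`, "", "sample_id"))
}

#' Within-group overdispersion scale from replicate fits
#'
#' Estimates the quasi-binomial dispersion scale for one group as the pooled
#' Pearson chi-square per degree of freedom of within-group single-rate site
#' fits: at each CpG covered in `>= 2` replicates with a pooled fraction in
#' `(0, 1)`, `X2 = sum_i (m_i - c_i p)^2 / (c_i p (1 - p))` on `n_i - 1` df;
#' the estimate is `sum(X2) / sum(df)`.  Approximately 1 under pure binomial
#' sampling, `> 1` under beta-binomial replicate variation.
#'
#' @param samples list of [methylome_sample]; only members of `group` are
#'   used.
#' @param group group label.
#' @param min_cov per-sample coverage floor for a site to contribute.
#' @param min_sites minimum number of contributing CpGs; below it the
#'   dispersion is declared not estimable.
#' @return The dispersion scale, or `NA_real_` when not estimable (fewer
#'   than 2 replicates or fewer than `min_sites` usable CpGs).
#' @export
estimate_dispersion <- function(samples, group, min_cov = 5L, min_sites = 50L) {
  members <- Filter(function(s) s$group == group, samples)
  if (length(members) < 2L) return(NA_real_)
  cm <- cohort_matrices(members)
  disp_from_matrices(cm$M, cm$C, min_cov, min_sites)
}

disp_from_matrices <- function(M, C, min_cov, min_sites = 50L) {
  use <- C >= max(1L, min_cov)
  Mu <- M * use; Cu <- C * use
  nrep <- rowSums(use)
  Ctot <- rowSums(Cu)
  p <- ifelse(Ctot > 0, rowSums(Mu) / Ctot, NA_real_)
  ok <- nrep >= 2L & !is.na(p) & p > 0 & p < 1
  if (sum(ok) < min_sites) return(NA_real_)
  E <- Cu * p
  V <- Cu * p * (1 - p)
  X2 <- rowSums(ifelse(use & V > 0, (Mu - E)^2 / ifelse(V > 0, V, 1), 0))
  sum(X2[ok]) / sum(nrep[ok] - 1L)
}

#' Per-CpG differential methylation tests across a cohort
#'
#' Runs the two-group binomial-logit likelihood-ratio test (see
#' [fit_site_glm]) at every CpG that passes the coverage and representation
#' filters: a sample contributes to a site only if its coverage there is at
#' least `min_cov`, and a site is tested only if both groups retain at least
#' `min_samples_per_group` contributing samples (each with non-zero pooled
#' coverage).  With `dispersion_mode = "auto"` (default), quasi-binomial
#' scaling of the LRT statistic is applied when both groups have at least two
#' replicates and a dispersion estimate is available; `"binomial"` forces
#' scale 1; `"quasi"` forces scaling (error if not estimable).  The fitted
#' scale is never allowed below 1.
#'
#' @param samples list of [methylome_sample] carrying exactly two distinct
#'   group labels.
#' @param min_cov per-sample, per-site coverage floor (default 5).
#' @param min_samples_per_group representation floor per group (default 1).
#' @param dispersion_mode `"auto"`, `"binomial"` or `"quasi"`.
#' @return A `data.frame` of class `site_test_results`, sorted by
#'   `(chrom, pos)`, with columns `chrom`, `pos`, `pi_a`, `pi_b`, `delta`,
#'   `direction`, `statistic`, `p`, `n_samples_used`.  Attributes: `groups`
#'   (A label first), `dispersion` (scale used), `skipped` (data.frame of
#'   filtered sites with reasons), `params`.
#' @export
test_all_sites <- function(samples, min_cov = 5L, min_samples_per_group = 1L,
                           dispersion_mode = c("auto", "binomial", "quasi")) {
  dispersion_mode <- match.arg(dispersion_mode)
  groups <- vapply(samples, `[[`, "", "group")
  glev <- unique(groups)
  if (length(glev) != 2L) {
    stop(sprintf("test_all_sites: need exactly two groups, found %d (%s)",
                 length(glev), paste(glev, collapse = ", ")))
  }
  cm <- cohort_matrices(samples)
  a <- cm$groups == glev[1L]
  use <- cm$C >= max(1L, min_cov)
  nA <- rowSums(use[, a, drop = FALSE]); nB <- rowSums(use[, !a, drop = FALSE])
  Mu <- cm$M * use; Cu <- cm$C * use
  MA <- rowSums(Mu[, a, drop = FALSE]); CA <- rowSums(Cu[, a, drop = FALSE])
  MB <- rowSums(Mu[, !a, drop = FALSE]); CB <- rowSums(Cu[, !a, drop = FALSE])

  keep <- nA >= min_samples_per_group & nB >= min_samples_per_group &
    CA > 0 & CB > 0
  reason <- rep(NA_character_, length(keep))
  reason[nA < min_samples_per_group | CA == 0] <-
    sprintf("fewer than %d covered samples in group %s", min_samples_per_group,
            glev[1L])
  reason[nB < min_samples_per_group | CB == 0] <-
    sprintf("fewer than %d covered samples in group %s", min_samples_per_group,
            glev[2L])
  skipped <- data.frame(chrom = cm$chrom[!keep], pos = cm$pos[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)

  phi <- 1
  if (dispersion_mode != "binomial") {
    both_replicated <- sum(a) >= 2L && sum(!a) >= 2L
    if (both_replicated) {
      # pooled across the two groups' within-group fits
      phiA <- disp_from_matrices(cm$M[, a, drop = FALSE],
                                 cm$C[, a, drop = FALSE], min_cov)
      phiB <- disp_from_matrices(cm$M[, !a, drop = FALSE],
                                 cm$C[, !a, drop = FALSE], min_cov)
      est <- mean(c(phiA, phiB), na.rm = TRUE)
      if (!is.nan(est)) phi <- max(1, est)
    }
    if (dispersion_mode == "quasi" && phi == 1 &&
        (!both_replicated)) {
      stop("test_all_sites: quasi dispersion requested but not estimable")
    }
  }

  r <- site_lrt(MA[keep], CA[keep], MB[keep], CB[keep])
  delta <- (MA[keep] + 0.5) / (CA[keep] + 1) - (MB[keep] + 0.5) / (CB[keep] + 1)
  out <- data.frame(chrom = cm$chrom[keep], pos = cm$pos[keep],
                    pi_a = r$pi_a, pi_b = r$pi_b, delta = delta,
                    direction = sign(delta), statistic = r$stat,
                    p = stats::pchisq(r$stat / phi, df = 1, lower.tail = FALSE),
                    n_samples_used = nA[keep] + nB[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("site_test_results", "data.frame"),
            groups = glev, dispersion = phi, skipped = skipped,
            params = list(min_cov = min_cov,
                          min_samples_per_group = min_samples_per_group,
                          dispersion_mode = dispersion_mode,
                          model = "binomial-logit group LRT, chi-square(1)"))
}
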