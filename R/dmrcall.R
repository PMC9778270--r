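#' CDF of a product of independent Uniform(0, 1) variables
#'
#' The Uniform Product distribution is the exact null distribution of the
#' product of `k` independent uniform p-values.  Its CDF is
#' `F(x, k) = x * sum_{j=0}^{k-1} (-ln x)^j / j!`, equivalently the
#' chi-square survival probability `P(chi2_{2k} >= -2 ln x)` (Fisher's
#' method).  The series is accumulated in log space so that very small
#' products (pass `log_x = TRUE` and supply `ln x` directly to avoid
#' underflow) and large `k` are handled stably.
#'
#' @param x product value in `(0, 1]`, or its natural log when
#'   `log_x = TRUE` (then any value in `[-Inf, 0]`).  Vectorised.
#' @param k number of uniforms in the product (integer `>= 1`).
#' @param log_x interpret `x` as `ln x`.
#' @return `P(prod U_i <= x)`, same length as `x`.
#' @examples
#' uniform_product_cdf(0.05, 1)            # 0.05
#' uniform_product_cdf(0.01, 3)            # ~0.162
#' uniform_product_cdf(-60, 5, log_x = TRUE)
#' @export
uniform_product_cdf <- function(x, k, log_x = FALSE) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != floor(k)) {
    stop("uniform_product_cdf: k must be a single integer >= 1")
  }
  L <- if (log_x) as.numeric(x) else {
    if (any(x <= 0 | x > 1, na.rm = TRUE)) {
      stop("uniform_product_cdf: x must lie in (0, 1]")
    }
    log(x)
  }
  if (any(L > 0, na.rm = TRUE)) {
    stop("uniform_product_cdf: log-product must be <= 0")
  }
  out <- numeric(length(L))
  out[L == 0] <- 1
  idx <- which(is.finite(L) & L < 0)
  if (length(idx) > 0L) {
    l <- L[idx]
    j <- seq_len(k) - 1           # series terms j = 0 .. k-1
    # log term_j = L + j * log(-L) - lgamma(j + 1); log-sum-exp over j
    logterm <- outer(l, j, function(li, ji) li + ji * log(-li) - lgamma(ji + 1))
    mx <- apply(logterm, 1L, max)
    out[idx] <- exp(mx) * rowSums(exp(logterm - mx))
  }
  out[is.na(L)] <- NA_real_
  pmin(out, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; a thin, validated surface over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
adjust_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("adjust_fdr: p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Segment phase-1-significant sites into candidate regions
#'
#' Scans the sorted site results for maximal runs of significant
#' (`p < alpha_site`), same-direction sites in which consecutive significant
#' members are at most `max_gap` bp apart on the same chromosome.  Runs with
#' at least `min_sites` significant members become candidates; tested but
#' non-significant sites lying inside a candidate's span are recorded as
#' interior members.
#'
#' @param results a [test_all_sites] table (sorted by chrom, pos).
#' @param alpha_site phase-1 per-site significance level.
#' @param max_gap maximum bp between consecutive significant members.
#' @param min_sites minimum significant members per candidate.
#' @return A `data.frame` with one row per candidate (`chrom`, `start`,
#'   `end`, `n_sig`, `direction`) and list-columns of row indices into
#'   `results`: `sig_members` and `span_members` (every tested site in the
#'   span, interior non-significant ones included).
#' @export
segment_candidates <- function(results, alpha_site = 0.01, max_gap = 500L,
                               min_sites = 3L) {
  res <- as.data.frame(results)
  sig <- which(res$p < alpha_site & res$direction != 0)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sig = integer(), direction = integer())
  empty$sig_members <- list(); empty$span_members <- list()
  if (length(sig) == 0L) return(empty)
  schrom <- res$chrom[sig]; spos <- res$pos[sig]; sdir <- res$direction[sig]
  new_run <- c(TRUE, schrom[-1L] != schrom[-length(sig)] |
                 sdir[-1L] != sdir[-length(sig)] |
                 (spos[-1L] - spos[-length(sig)]) > max_gap)
  run_id <- cumsum(new_run)
  keep_runs <- which(tabulate(run_id) >= min_sites)
  if (length(keep_runs) == 0L) return(empty)
  rows <- lapply(keep_runs, function(r) sig[run_id == r])
  out <- data.frame(
    chrom = vapply(rows, function(i) res$chrom[i[1L]], ""),
    start = vapply(rows, function(i) res$pos[i[1L]], 0L),
    end = vapply(rows, function(i) res$pos[i[length(i)]] + 1L, 0L),
    n_sig = lengths(rows),
    direction = vapply(rows, function(i) as.integer(res$direction[i[1L]]), 0L),
    stringsAsFactors = FALSE)
  out$sig_members <- rows
  out$span_members <- lapply(seq_len(nrow(out)), function(i) {
    which(res$chrom == out$chrom[i] & res$pos >= out$start[i] &
            res$pos < out$end[i])
  })
  out
}

#' Call differentially methylated regions (phase 2)
#'
#' Aggregates candidate regions from [segment_candidates] into DMRs: each
#' candidate's member p-values are combined by the Uniform Product
#' distribution (product of `k` member p-values referred to its exact null
#' CDF, computed in log space), Benjamini-Hochberg adjustment is applied
#' across all candidates genome-wide, and regions with `q < q_threshold` are
#' reported, sorted and mutually non-overlapping.
#'
#' `combine_scope` selects the membership of the product: `"all_in_span"`
#' (default) combines every tested CpG inside the candidate span, which
#' tempers the selection bias of combining only phase-1 winners;
#' `"significant_only"` combines just the significant members.  The
#' Uniform-Product null assumes independent p-values; spatially correlated
#' methylation makes it optimistic, and `effective_k` (in `(0, 1]`) deflates
#' both the combined log-product and the member count by that factor as a
#' crude correlation correction (1 = off).
#'
#' @param results a [test_all_sites] table.
#' @param alpha_site,max_gap,min_sites phase-1/segmentation parameters
#'   (see [segment_candidates]).
#' @param q_threshold report DMRs with BH q below this.
#' @param combine_scope `"all_in_span"` or `"significant_only"`.
#' @param effective_k correlation deflation factor in `(0, 1]`.
#' @return A `data.frame` of class `dmr_calls`: `chrom`, `start`, `end`,
#'   `name`, `k`, `n_sig`, `mean_delta`, `direction` (`"hyper"` = group A
#'   more methylated), `log10_product_p`, `combined_p`, `q`.  Attribute
#'   `candidates` carries the pre-FDR candidate count.
#' @export
call_dmrs <- function(results, alpha_site = 0.01, max_gap = 500L,
                      min_sites = 3L, q_threshold = 0.05,
                      combine_scope = c("all_in_span", "significant_only"),
                      effective_k = 1) {
  combine_scope <- match.arg(combine_scope)
  stopifnot(effective_k > 0, effective_k <= 1)
  res <- as.data.frame(results)
  cand <- segment_candidates(results, alpha_site, max_gap, min_sites)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), k = integer(), n_sig = integer(),
                      mean_delta = numeric(), direction = character(),
                      log10_product_p = numeric(), combined_p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE)
  if (nrow(cand) == 0L) {
    return(structure(empty, class = c("dmr_calls", "data.frame"),
                     candidates = 0L))
  }
  members <- if (combine_scope == "all_in_span") cand$span_members else
    cand$sig_members
  tiny <- .Machine$double.xmin
  logprod <- vapply(members, function(i) sum(log(pmax(res$p[i], tiny))), 0)
  kk <- lengths(members)
  k_eff <- pmax(1L, as.integer(ceiling(kk * effective_k)))
  lp_eff <- logprod * effective_k
  combined <- vapply(seq_along(kk), function(i) {
    uniform_product_cdf(lp_eff[i], k_eff[i], log_x = TRUE)
  }, 0)
  q <- adjust_fdr(combined)
  mean_delta <- vapply(members, function(i) mean(res$delta[i]), 0)
  out <- data.frame(chrom = cand$chrom, start = cand$start, end = cand$end,
                    name = "", k = kk, n_sig = cand$n_sig,
                    mean_delta = mean_delta,
                    direction = ifelse(cand$direction > 0, "hyper", "hypo"),
                    log10_product_p = logprod / log(10),
                    combined_p = combined, q = q, stringsAsFactors = FALSE)
  out <- out[out$q < q_threshold, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (nrow(out) > 0L) {
    out$name <- sprintf("DMR_%04d_%s", seq_len(nrow(out)), out$direction)
  }
  rownames(out) <- NULL
  structure(out, class = c("dmr_calls", "data.frame"),
            candidates = nrow(cand))
}
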