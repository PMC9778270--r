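#' Genome-wide background methylation of one sample
#'
#' Coverage-weighted pooled fraction: total methylated reads over total reads
#' across every covered CpG (matching the pooled-count binomial testing of
#' [call_lmrs], as opposed to an unweighted per-site average).
#'
#' @param sample a [methylome_sample].
#' @param chrom optionally restrict to one chromosome (useful for
#'   single-locus fixtures).
#' @return Pooled methylated fraction in `[0, 1]`.
#' @export
genome_background <- function(sample, chrom = NULL) {
  s <- sample$sites
  if (!is.null(chrom)) s <- s[s$chrom == chrom, , drop = FALSE]
  total <- sum(s$meth) + sum(s$unmeth)
  if (total <= 0) stop("genome_background: sample has zero total coverage")
  sum(s$meth) / total
}

#' Call low-methylated regions (LMRs) within one sample
#'
#' Detects regions with significantly lower methylation than the rest of the
#' same genome.  A window of `window_cpgs` consecutive covered CpGs slides in
#' steps of one CpG; windows whose pooled methylated fraction falls below
#' `max_meth_frac` times the sample background are flagged; overlapping
#' flagged windows are merged into maximal regions; each merged region's
#' one-sided binomial p-value (pooled methylated count at the background
#' rate, lower tail) is recomputed on its pooled counts; Benjamini-Hochberg
#' adjustment is applied across merged regions and regions with
#' `q < q_threshold` are reported.
#'
#' @param sample a [methylome_sample].
#' @param window_cpgs window size in CpGs (>= 3).
#' @param max_meth_frac flagging threshold relative to background, in
#'   `(0, 1]`.
#' @param q_threshold report LMRs with BH q below this.
#' @param min_cov per-site coverage floor (default 1: any covered CpG).
#' @param background override the [genome_background] value (e.g. a
#'   chromosome-restricted background for single-locus fixtures).
#' @return A `data.frame` of class `lmr_calls`: `chrom`, `start`, `end`,
#'   `name`, `n_cpgs`, `mean_meth`, `background`, `p`, `q`.
#' @export
call_lmrs <- function(sample, window_cpgs = 10L, max_meth_frac = 0.5,
                      q_threshold = 0.05, min_cov = 1L, background = NULL) {
  stopifnot(window_cpgs >= 3L, max_meth_frac > 0, max_meth_frac <= 1)
  if (is.null(background)) background <- genome_background(sample)
  stopifnot(background >= 0, background <= 1)
  s <- sample$sites[sample$sites$meth + sample$sites$unmeth >= max(1L, min_cov), ,
                    drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), n_cpgs = integer(),
                      mean_meth = numeric(), background = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
  regions <- NULL
  for (chr in unique(s$chrom)) {
    sc <- s[s$chrom == chr, , drop = FALSE]
    n <- nrow(sc)
    if (n < window_cpgs) next
    cm <- cumsum(c(0, sc$meth))
    cc <- cumsum(c(0, sc$meth + sc$unmeth))
    i <- seq_len(n - window_cpgs + 1L)   # window = CpGs i .. i+w-1
    wm <- cm[i + window_cpgs] - cm[i]
    wc <- cc[i + window_cpgs] - cc[i]
    flagged <- which(wm / wc < max_meth_frac * background)
    if (length(flagged) == 0L) next
    # windows sharing CpGs merge: starts within window_cpgs of the previous
    brk <- c(TRUE, diff(flagged) >= window_cpgs)
    gid <- cumsum(brk)
    for (g in unique(gid)) {
      w <- flagged[gid == g]
      a <- min(w); b <- max(w) + window_cpgs - 1L
      regions <- rbind(regions, data.frame(
        chrom = chr, start = sc$pos[a], end = sc$pos[b] + 1L,
        n_cpgs = b - a + 1L,
        m = cm[b + 1L] - cm[a], cov = cc[b + 1L] - cc[a],
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(regions)) {
    if (nrow(s) < window_cpgs) {
      warning("call_lmrs: sample smaller than one window; no LMRs callable")
    }
    return(structure(empty, class = c("lmr_calls", "data.frame")))
  }
  regions$mean_meth <- regions$m / regions$cov
  regions$p <- stats::pbinom(regions$m, regions$cov, background)
  regions$q <- adjust_fdr(regions$p)
  out <- regions[regions$q < q_threshold & regions$mean_meth < background, ,
                 drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  res <- data.frame(chrom = out$chrom, start = out$start, end = out$end,
                    name = if (nrow(out) > 0L) {
                      sprintf("LMR_%04d", seq_len(nrow(out)))
                    } else character(),
                    n_cpgs = out$n_cpgs, mean_meth = out$mean_meth,
                    background = rep(background, nrow(out)),
                    p = out$p, q = out$q, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("lmr_calls", "data.frame"))
}
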