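#' TSS anchor: transcription start site plus its promoter core interval
#'
#' @param chrom chromosome name.
#' @param tss 0-based TSS position (bp).
#' @param strand `"+"` or `"-"`; on the minus strand upstream offsets run
#'   toward higher genomic coordinates.
#' @param promoter_start,promoter_end 0-based half-open interval of the
#'   (constitutively unmethylated) promoter core; must contain or abut the
#'   TSS.
#' @return A list of class `tss_anchor`.
#' @export
tss_anchor <- function(chrom, tss, strand, promoter_start, promoter_end) {
  stopifnot(strand %in% c("+", "-"), promoter_start < promoter_end)
  tss <- as.integer(tss)
  promoter_start <- as.integer(promoter_start)
  promoter_end <- as.integer(promoter_end)
  if (tss < promoter_start - 1L || tss > promoter_end) {
    stop("tss_anchor: promoter interval must contain or abut the TSS")
  }
  structure(list(chrom = as.character(chrom), tss = tss, strand = strand,
                 promoter = c(start = promoter_start, end = promoter_end)),
            class = "tss_anchor")
}

#' Signed TSS-relative offset of a genomic position
#'
#' Upstream is negative regardless of strand: for `"+"` the offset is
#' `pos - tss`, for `"-"` it is `tss - pos`.  This matches the convention of
#' naming promoter-flanking regions by kb offsets such as -0.7/-2.5.
#'
#' @param anchor a [tss_anchor].
#' @param genomic_pos position(s) in bp (0-based).
#' @param chrom if supplied, checked against the anchor's chromosome.
#' @return Integer offset(s) in bp.
#' @export
tss_relative <- function(anchor, genomic_pos, chrom = NULL) {
  stopifnot(inherits(anchor, "tss_anchor"))
  if (!is.null(chrom) && any(chrom != anchor$chrom)) {
    stop(sprintf("tss_relative: position on %s but anchor on %s",
                 chrom[chrom != anchor$chrom][1L], anchor$chrom))
  }
  genomic_pos <- as.integer(genomic_pos)
  if (anchor$strand == "+") genomic_pos - anchor$tss else
    anchor$tss - genomic_pos
}

# inverse of tss_relative
tss_genomic <- function(anchor, offset) {
  if (anchor$strand == "+") anchor$tss + as.integer(offset) else
    anchor$tss - as.integer(offset)
}

#' Classify a DMR's position relative to a promoter
#'
#' A DMR intersecting the promoter interval is `promoter_overlapping`;
#' otherwise, if its nearest edge lies within `border_window` bp of the
#' promoter it is `upstream_border` or `downstream_border` according to the
#' TSS-relative side it falls on; otherwise `distal`.  Intervals are 0-based
#' half-open; classification depends only on the occupied base range, not on
#' the start/end encoding.
#'
#' @param dmr a data.frame of intervals (`chrom`, `start`, `end`; e.g. a
#'   [call_dmrs] result), or a single interval as `c(start, end)`.
#' @param anchor a [tss_anchor].
#' @param border_window bp within which a flanking DMR counts as a border
#'   (default 5000, wide enough to take in promoter-border DMRs out to
#'   ~-5 kb).
#' @return Character vector of labels, one per interval: one of
#'   `"promoter_overlapping"`, `"upstream_border"`, `"downstream_border"`,
#'   `"distal"` (or `"other_chromosome"`).
#' @export
classify_dmr_position <- function(dmr, anchor, border_window = 5000L) {
  stopifnot(inherits(anchor, "tss_anchor"), border_window >= 0)
  if (!is.data.frame(dmr)) {
    dmr <- data.frame(chrom = anchor$chrom, start = dmr[1L], end = dmr[2L])
  }
  pstart <- anchor$promoter[["start"]]; pend <- anchor$promoter[["end"]]
  prel <- sort(tss_relative(anchor, c(pstart, pend - 1L)))
  vapply(seq_len(nrow(dmr)), function(i) {
    if (!is.null(dmr$chrom) && dmr$chrom[i] != anchor$chrom) {
      return("other_chromosome")
    }
    s <- dmr$start[i]; e <- dmr$end[i]
    if (s < pend && pstart < e) return("promoter_overlapping")
    drel <- sort(tss_relative(anchor, c(s, e - 1L)))
    if (drel[2L] < prel[1L]) {
      gap <- prel[1L] - drel[2L]
      if (gap <= border_window) "upstream_border" else "distal"
    } else {
      gap <- drel[1L] - prel[2L]
      if (gap <= border_window) "downstream_border" else "distal"
    }
  }, "")
}

# two-sided Fisher exact p for the 2x2 table rbind(c(a, b), c(c, d)):
# enumerate the hypergeometric support and sum probabilities not exceeding
# the observed one (relative tolerance as in standard practice)
fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Compare pooled regional methylation between two sample sides
#'
#' Pools (methylated, unmethylated) counts over covered CpGs inside the
#' interval, across the samples of each side, and tests the 2x2 table of
#' pooled counts.  `method = "auto"` uses Fisher's exact test when the total
#' count is at most 10,000 and a chi-square test with continuity correction
#' above that; `"glm"` instead fits the binomial-logit group model to the
#' per-sample regional totals (likelihood-ratio test), which respects the
#' sample as the unit.
#'
#' @param interval `c(start, end)` (0-based half-open) or a one-row
#'   data.frame with `chrom`, `start`, `end`.
#' @param samples_a,samples_b lists of [methylome_sample] (a single sample
#'   may be passed bare).
#' @param min_cov per-sample, per-site coverage floor (default 5).
#' @param method `"auto"`, `"fisher"`, `"chisq"`, or `"glm"`.
#' @param chrom chromosome of the interval when given as a bare vector;
#'   default: the single chromosome present in the data.
#' @return A list of class `region_comparison`: `interval`, `pooled_a`,
#'   `pooled_b` (named count vectors), `frac_a`, `frac_b`, `percent_a`,
#'   `percent_b`, `p`, `method`, `n_sites_a`, `n_sites_b`.
#' @export
compare_region <- function(interval, samples_a, samples_b, min_cov = 5L,
                           method = c("auto", "fisher", "chisq", "glm"),
                           chrom = NULL) {
  method <- match.arg(method)
  if (inherits(samples_a, "methylome_sample")) samples_a <- list(samples_a)
  if (inherits(samples_b, "methylome_sample")) samples_b <- list(samples_b)
  if (is.data.frame(interval)) {
    chrom <- interval$chrom[1L]
    interval <- c(interval$start[1L], interval$end[1L])
  }
  pool_side <- function(samples) {
    per_sample <- lapply(samples, function(s) {
      x <- s$sites
      keep <- x$pos >= interval[1L] & x$pos < interval[2L] &
        (x$meth + x$unmeth) >= max(1L, min_cov)
      if (!is.null(chrom)) keep <- keep & x$chrom == chrom
      c(meth = sum(x$meth[keep]), unmeth = sum(x$unmeth[keep]),
        n_sites = sum(keep))
    })
    Reduce(`+`, per_sample)
  }
  pa <- pool_side(samples_a); pb <- pool_side(samples_b)
  if (pa[["meth"]] + pa[["unmeth"]] == 0) {
    stop("compare_region: no covered CpGs in the interval on side A")
  }
  if (pb[["meth"]] + pb[["unmeth"]] == 0) {
    stop("compare_region: no covered CpGs in the interval on side B")
  }
  total <- sum(pa[c("meth", "unmeth")]) + sum(pb[c("meth", "unmeth")])
  if (method == "auto") method <- if (total <= 10000) "fisher" else "chisq"
  p <- switch(method,
    fisher = fisher_2x2(pa[["meth"]], pa[["unmeth"]],
                        pb[["meth"]], pb[["unmeth"]]),
    chisq = suppressWarnings(stats::chisq.test(
      rbind(pa[c("meth", "unmeth")], pb[c("meth", "unmeth")]),
      correct = TRUE)$p.value),
    glm = {
      side_counts <- function(samples) {
        t(vapply(samples, function(s) {
          x <- s$sites
          keep <- x$pos >= interval[1L] & x$pos < interval[2L] &
            (x$meth + x$unmeth) >= max(1L, min_cov)
          if (!is.null(chrom)) keep <- keep & x$chrom == chrom
          c(sum(x$meth[keep]), sum(x$unmeth[keep]))
        }, numeric(2L)))
      }
      fit_site_glm(side_counts(samples_a), side_counts(samples_b))$p
    })
  fa <- pa[["meth"]] / (pa[["meth"]] + pa[["unmeth"]])
  fb <- pb[["meth"]] / (pb[["meth"]] + pb[["unmeth"]])
  structure(list(interval = interval, chrom = chrom,
                 pooled_a = pa[c("meth", "unmeth")],
                 pooled_b = pb[c("meth", "unmeth")],
                 frac_a = fa, frac_b = fb,
                 percent_a = 100 * fa, percent_b = 100 * fb,
                 p = p, method = method,
                 n_sites_a = pa[["n_sites"]], n_sites_b = pb[["n_sites"]]),
            class = "region_comparison")
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("region [%s%d, %d): %.1f%% vs %.1f%% methylation (pooled), p = %.3g (%s)\n",
              if (is.null(x$chrom)) "" else paste0(x$chrom, ":"),
              x$interval[1L], x$interval[2L], x$percent_a, x$percent_b,
              x$p, x$method))
  invisible(x)
}
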