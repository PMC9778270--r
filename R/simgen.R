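#' Simulation configuration for synthetic methylome cohorts
#'
#' Houses every noise and design parameter of the cohort simulator.  Defaults
#' reproduce the package's reference study design: 3 samples in group A
#' (e.g. myoblast cultures) against 6 in group B (heterologous cultures),
#' mean coverage 30 reads per CpG, a strongly bimodal background (0.85
#' outside CpG islands, 0.05 inside), planted DMRs at 0.90 (group A) versus
#' 0.15 (group B), and mild beta-binomial overdispersion.
#'
#' @param n_group_a,n_group_b sample counts per group (>= 0; at least one
#'   group non-empty).
#' @param mean_coverage expected reads per CpG (Poisson mean, > 0).
#' @param background_pi methylation level outside islands, in `[0, 1]`.
#' @param island_pi level inside islands / the unmethylated promoter core.
#' @param dmr_pi_a,dmr_pi_b group target levels inside planted DMRs.
#' @param rho beta-binomial intra-site dispersion, `0 <= rho < 1`; `rho = 0`
#'   gives exact binomial counts.
#' @param seed master RNG seed; per-sample streams are derived from it so
#'   cohorts are reproducible regardless of sample order.
#' @param group_labels character vector of length 2 naming the groups.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_group_a = 3L, n_group_b = 6L, mean_coverage = 30,
                       background_pi = 0.85, island_pi = 0.05,
                       dmr_pi_a = 0.90, dmr_pi_b = 0.15, rho = 0.05,
                       seed = 1L, group_labels = c("A", "B")) {
  pis <- c(background_pi, island_pi, dmr_pi_a, dmr_pi_b)
  if (any(pis < 0 | pis > 1)) stop("sim_config: methylation levels must lie in [0, 1]")
  if (mean_coverage <= 0) stop("sim_config: mean_coverage must be > 0")
  if (rho < 0 || rho >= 1) stop("sim_config: rho must satisfy 0 <= rho < 1")
  if (n_group_a < 0 || n_group_b < 0 || n_group_a + n_group_b < 1) {
    stop("sim_config: need at least one sample")
  }
  stopifnot(length(group_labels) == 2L, !anyDuplicated(group_labels))
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 mean_coverage = mean_coverage,
                 background_pi = background_pi, island_pi = island_pi,
                 dmr_pi_a = dmr_pi_a, dmr_pi_b = dmr_pi_b, rho = rho,
                 seed = as.integer(seed), group_labels = group_labels),
            class = "sim_config")
}

#' Build a locus layout with planted DMR/LMR architecture
#'
#' Lays out CpG positions on one synthetic chromosome at regular spacing —
#' dense inside islands (default every 10 bp), sparse outside (every 100 bp)
#' — and records the planted truth: island intervals with low baseline
#' methylation, group-specific DMR intervals, and within-sample low
#' methylation (LMR) intervals.
#'
#' With all interval arguments `NULL`, the default layout emulates the
#' promoter-border architecture of a TBX15-like locus: a constitutively
#' unmethylated promoter core island around the TSS (relative -700..+600 bp),
#' flanked by two group-A-hypermethylated DMRs that do not touch the core
#' (upstream -2600..-1500, downstream +2600..+4600), on a 100-kb chromosome
#' with the TSS at 50 kb on the plus strand.  The core island doubles as the
#' planted LMR.
#'
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param islands,dmrs,lmrs `NULL` for the default layout, or data.frames
#'   with `start`/`end` (0-based half-open); `dmrs` may carry `pi_a`/`pi_b`
#'   columns (target levels per group), `lmrs` a `pi` column.  Pass a
#'   zero-row data.frame to request none.
#' @param tss TSS position (bp); `NULL` places it at `chrom_length / 2` for
#'   the default layout.
#' @param tss_strand `"+"` or `"-"`.
#' @param island_spacing,background_spacing CpG spacing in bp inside/outside
#'   islands.
#' @param dmr_pi_a,dmr_pi_b,island_pi default planted levels used to fill
#'   missing columns (overridden per interval by the data.frame columns).
#' @return A list of class `locus_layout` with elements `chrom`,
#'   `chrom_length`, `cpg_pos`, `islands`, `dmrs`, `lmrs`, `tss`,
#'   `tss_strand`, `promoter`.
#' @export
build_layout <- function(chrom_length = 100000L, chrom = "chrSim",
                         islands = NULL, dmrs = NULL, lmrs = NULL,
                         tss = NULL, tss_strand = "+",
                         island_spacing = 10L, background_spacing = 100L,
                         dmr_pi_a = 0.90, dmr_pi_b = 0.15, island_pi = 0.05) {
  chrom_length <- as.integer(chrom_length)
  stopifnot(chrom_length > 0L, island_spacing >= 2L, background_spacing >= 2L,
            tss_strand %in% c("+", "-"))
  if (is.null(tss)) tss <- chrom_length %/% 2L
  tss <- as.integer(tss)

  default_layout <- is.null(islands) && is.null(dmrs)
  if (default_layout) {
    # promoter-border geometry, TSS-relative: core -700..+600,
    # flanking hypermethylated DMRs -2600..-1500 and +2600..+4600
    rel <- function(a, b) {
      if (tss_strand == "+") c(tss + a, tss + b) else c(tss - b, tss - a)
    }
    core <- rel(-700L, 600L)
    up <- rel(-2600L, -1500L)
    down <- rel(2600L, 4600L)
    islands <- data.frame(start = core[1L], end = core[2L])
    dmrs <- data.frame(start = c(min(up), min(down)),
                       end = c(max(up), max(down)))
    # order by genomic coordinate
    dmrs <- dmrs[order(dmrs$start), , drop = FALSE]
    if (is.null(lmrs)) lmrs <- data.frame(start = core[1L], end = core[2L])
  }
  if (is.null(islands)) islands <- data.frame(start = integer(), end = integer())
  if (is.null(dmrs)) dmrs <- data.frame(start = integer(), end = integer())
  if (is.null(lmrs)) lmrs <- data.frame(start = integer(), end = integer())

  check_intervals <- function(df, what) {
    if (nrow(df) == 0L) return(df)
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (any(df$start < 0L) || any(df$end > chrom_length)) {
      stop(sprintf("build_layout: %s interval outside [0, chrom_length)", what))
    }
    if (any(df$start >= df$end)) {
      stop(sprintf("build_layout: degenerate %s interval (start >= end)", what))
    }
    df[order(df$start), , drop = FALSE]
  }
  islands <- check_intervals(islands, "island")
  dmrs <- check_intervals(dmrs, "DMR")
  lmrs <- check_intervals(lmrs, "LMR")
  if (nrow(islands) > 0L && any(islands$end - islands$start < island_spacing)) {
    stop("build_layout: island shorter than the island CpG spacing")
  }
  if (is.null(dmrs$pi_a)) dmrs$pi_a <- rep(dmr_pi_a, nrow(dmrs))
  if (is.null(dmrs$pi_b)) dmrs$pi_b <- rep(dmr_pi_b, nrow(dmrs))
  if (is.null(lmrs$pi)) lmrs$pi <- rep(island_pi, nrow(lmrs))

  # regular CpG spacing: walk the chromosome, stepping by the local density
  in_any <- function(p, df) {
    if (nrow(df) == 0L) return(rep(FALSE, length(p)))
    hit <- rep(FALSE, length(p))
    for (i in seq_len(nrow(df))) hit <- hit | (p >= df$start[i] & p < df$end[i])
    hit
  }
  pos <- integer(0)
  p <- background_spacing %/% 2L
  while (p < chrom_length - 1L) {
    pos <- c(pos, p)
    p <- p + if (in_any(p, islands)) island_spacing else background_spacing
  }
  pos <- as.integer(pos)

  for (nm in list(list(dmrs, "DMR"), list(lmrs, "LMR"), list(islands, "island"))) {
    df <- nm[[1L]]
    if (nrow(df) > 0L && any(!vapply(seq_len(nrow(df)), function(i) {
      any(pos >= df$start[i] & pos < df$end[i])
    }, TRUE))) {
      stop(sprintf("build_layout: planted %s interval contains no CpG", nm[[2L]]))
    }
  }

  promoter <- if (nrow(islands) > 0L) {
    islands[1L, c("start", "end"), drop = FALSE]
  } else NULL
  structure(list(chrom = chrom, chrom_length = chrom_length, cpg_pos = pos,
                 islands = islands, dmrs = dmrs, lmrs = lmrs, tss = tss,
                 tss_strand = tss_strand, promoter = promoter),
            class = "locus_layout")
}

# per-CpG target methylation level for one group
layout_pi <- function(layout, config, group) {
  pos <- layout$cpg_pos
  pi <- rep(config$background_pi, length(pos))
  isl <- layout$islands
  for (i in seq_len(nrow(isl))) {
    pi[pos >= isl$start[i] & pos < isl$end[i]] <- config$island_pi
  }
  lm <- layout$lmrs
  for (i in seq_len(nrow(lm))) {
    pi[pos >= lm$start[i] & pos < lm$end[i]] <- lm$pi[i]
  }
  dm <- layout$dmrs
  a_side <- group == config$group_labels[1L]
  for (i in seq_len(nrow(dm))) {
    pi[pos >= dm$start[i] & pos < dm$end[i]] <-
      if (a_side) dm$pi_a[i] else dm$pi_b[i]
  }
  pi
}

#' Simulate one methylome sample from a layout
#'
#' Per CpG: coverage is Poisson(`mean_coverage`); the site-level methylation
#' probability is drawn from a Beta distribution with mean equal to the
#' layout's target level and dispersion `rho` (`rho = 0` uses the target
#' level exactly, giving binomial counts); the methylated count is Binomial
#' in that probability.  CpGs receiving zero reads are dropped, as in real
#' coverage files.
#'
#' @param layout a [build_layout] result.
#' @param config a [sim_config].
#' @param group group label (must be one of `config$group_labels`).
#' @param sample_id sample identifier.
#' @param seed RNG seed for this sample's stream.
#' @return A [methylome_sample].
#' @export
simulate_sample <- function(layout, config, group, sample_id, seed) {
  stopifnot(inherits(layout, "locus_layout"), inherits(config, "sim_config"),
            group %in% config$group_labels)
  pi <- layout_pi(layout, config, group)
  n <- length(pi)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cov <- stats::rpois(n, config$mean_coverage)
  p <- pi
  if (config$rho > 0) {
    s <- (1 - config$rho) / config$rho  # Beta(a, b) with a + b = s, mean = pi
    inner <- pi > 0 & pi < 1
    p[inner] <- stats::rbeta(sum(inner), pi[inner] * s, (1 - pi[inner]) * s)
  }
  meth <- stats::rbinom(n, cov, p)
  keep <- cov > 0L
  methylome_sample(sample_id, group,
                   cpg_sites(layout$chrom, layout$cpg_pos[keep], meth[keep],
                             as.integer(cov[keep] - meth[keep])))
}

#' Simulate a two-group cohort plus its planted truth table
#'
#' Generates `n_group_a + n_group_b` samples sharing one layout, with
#' independent noise streams derived deterministically from the master seed
#' (sample `i` always receives the same stream whatever the generation
#' order).
#'
#' @param layout a [build_layout] result.
#' @param config a [sim_config].
#' @return A list of class `sim_cohort`: `samples` (list of
#'   [methylome_sample]) and `truth`, a [genomic_intervals] table of planted
#'   DMRs (`dmr_1`, `dmr_2`, ...) and LMRs (`lmr_1`, ...).
#' @export
simulate_cohort <- function(layout, config) {
  stopifnot(inherits(layout, "locus_layout"), inherits(config, "sim_config"))
  n <- config$n_group_a + config$n_group_b
  groups <- rep(config$group_labels, c(config$n_group_a, config$n_group_b))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(config$seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    samples[[i]] <- simulate_sample(layout, config, groups[i],
                                    sprintf("sim_%s_%02d", groups[i], i),
                                    stream_seeds[i])
  }
  truth <- rbind(
    if (nrow(layout$dmrs) > 0L) {
      data.frame(chrom = layout$chrom, start = layout$dmrs$start,
                 end = layout$dmrs$end,
                 name = sprintf("dmr_%d", seq_len(nrow(layout$dmrs))))
    },
    if (nrow(layout$lmrs) > 0L) {
      data.frame(chrom = layout$chrom, start = layout$lmrs$start,
                 end = layout$lmrs$end,
                 name = sprintf("lmr_%d", seq_len(nrow(layout$lmrs))))
    })
  truth <- if (is.null(truth)) genomic_intervals() else {
    genomic_intervals(truth$chrom, truth$start, truth$end, truth$name)
  }
  structure(list(samples = samples, truth = truth, layout = layout,
                 config = config),
            class = "sim_cohort")
}
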