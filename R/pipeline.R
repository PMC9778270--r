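#' Run the two-phase DMR analysis end to end
#'
#' Orchestrates the full analysis on a cohort: coverage filtering, per-CpG
#' GLM tests (phase 1), Uniform-Product DMR aggregation with region-level
#' FDR (phase 2), per-sample LMR calling, pooled regional comparison of each
#' DMR between the groups, and — when a TSS anchor is supplied — positional
#' classification of each DMR against the promoter core.  All outputs are
#' deterministic functions of the inputs and parameters; the run log echoes
#' the full parameter set and per-stage counts.
#'
#' @param samples list of [methylome_sample] (exactly two groups), or `NULL`
#'   when `manifest` is given.
#' @param manifest path to a tab-delimited sample manifest with columns
#'   `path`, `sample_id`, `group` (header required); files are read with
#'   [read_coverage].
#' @param out_dir output directory (created if missing); `NULL` skips file
#'   output and only returns results.
#' @param min_cov,min_samples_per_group,dispersion_mode phase-1 parameters
#'   (see [test_all_sites]).
#' @param alpha_site,max_gap,min_sites,q_threshold,combine_scope,effective_k
#'   phase-2 parameters (see [call_dmrs]).
#' @param lmr_window,lmr_max_frac,lmr_q LMR parameters (see [call_lmrs]).
#' @param anchor optional [tss_anchor] for DMR classification.
#' @param border_window bp window for border classification.
#' @param dialect coverage-file dialect for manifest input.
#' @return Invisibly, a list of class `dmr_run`: `sites`, `dmrs`, `lmrs`
#'   (named per sample), `region_report`, `classification`, `params`, `log`
#'   (character vector).  When `out_dir` is given, writes `sites.tsv`,
#'   `dmrs.tsv`, `dmrs.bed`, `lmrs_<sample>.tsv`, `region_report.tsv`,
#'   `classification.tsv` (if anchored) and `run_log.txt`.
#' @export
run_dmr_pipeline <- function(samples = NULL, manifest = NULL, out_dir = NULL,
                             min_cov = 5L, min_samples_per_group = 1L,
                             dispersion_mode = "auto",
                             alpha_site = 0.01, max_gap = 500L,
                             min_sites = 3L, q_threshold = 0.05,
                             combine_scope = "all_in_span", effective_k = 1,
                             lmr_window = 10L, lmr_max_frac = 0.5,
                             lmr_q = 0.05,
                             anchor = NULL, border_window = 5000L,
                             dialect = "bismark") {
  if (is.null(samples)) {
    if (is.null(manifest)) stop("run_dmr_pipeline: supply samples or a manifest")
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    need <- c("path", "sample_id", "group")
    if (!all(need %in% names(man))) {
      stop("run_dmr_pipeline: manifest needs columns path, sample_id, group")
    }
    missing_files <- man$path[!file.exists(man$path)]
    if (length(missing_files) > 0L) {
      stop(sprintf("run_dmr_pipeline: input file not found: %s",
                   missing_files[1L]))
    }
    samples <- lapply(seq_len(nrow(man)), function(i) {
      read_coverage(man$path[i], man$sample_id[i], man$group[i], dialect)
    })
  }
  groups <- vapply(samples, `[[`, "", "group")
  if (length(unique(groups)) != 2L) {
    stop(sprintf("run_dmr_pipeline: manifest must define exactly two groups, found %d (%s)",
                 length(unique(groups)), paste(unique(groups), collapse = ", ")))
  }

  params <- list(min_cov = min_cov,
                 min_samples_per_group = min_samples_per_group,
                 dispersion_mode = dispersion_mode, alpha_site = alpha_site,
                 max_gap = max_gap, min_sites = min_sites,
                 q_threshold = q_threshold, combine_scope = combine_scope,
                 effective_k = effective_k, lmr_window = lmr_window,
                 lmr_max_frac = lmr_max_frac, lmr_q = lmr_q,
                 border_window = border_window)
  log <- c(sprintf("methborder %s",
                   as.character(utils::packageVersion("methborder"))),
           sprintf("samples: %d (%s)", length(samples),
                   paste(sprintf("%s=%d", names(table(groups)),
                                 as.integer(table(groups))), collapse = ", ")),
           sprintf("param %s = %s", names(params),
                   vapply(params, function(p) paste(format(p), collapse = ","), "")))

  filtered <- lapply(samples, filter_coverage, min_cov = min_cov)
  sites <- test_all_sites(filtered, min_cov = min_cov,
                          min_samples_per_group = min_samples_per_group,
                          dispersion_mode = dispersion_mode)
  skipped <- attr(sites, "skipped")
  log <- c(log,
           sprintf("phase 1: %d sites tested, %d skipped by filters",
                   nrow(sites), nrow(skipped)),
           sprintf("phase 1: dispersion scale %.4f (%s)",
                   attr(sites, "dispersion"), dispersion_mode),
           sprintf("phase 1: %d sites significant at alpha_site = %g",
                   sum(sites$p < alpha_site), alpha_site))

  dmrs <- call_dmrs(sites, alpha_site = alpha_site, max_gap = max_gap,
                    min_sites = min_sites, q_threshold = q_threshold,
                    combine_scope = combine_scope, effective_k = effective_k)
  log <- c(log, sprintf("phase 2: %d candidates, %d DMRs at q < %g",
                        attr(dmrs, "candidates"), nrow(dmrs), q_threshold))

  lmrs <- lapply(filtered, function(s) {
    call_lmrs(s, window_cpgs = lmr_window, max_meth_frac = lmr_max_frac,
              q_threshold = lmr_q)
  })
  names(lmrs) <- vapply(filtered, `[[`, "", "sample_id")
  log <- c(log, sprintf("LMRs: %s",
                        paste(sprintf("%s=%d", names(lmrs),
                                      vapply(lmrs, nrow, 0L)), collapse = ", ")))

  glev <- attr(sites, "groups")
  region_report <- NULL
  if (nrow(dmrs) > 0L) {
    sa <- filtered[groups == glev[1L]]
    sb <- filtered[groups == glev[2L]]
    region_report <- do.call(rbind, lapply(seq_len(nrow(dmrs)), function(i) {
      rc <- compare_region(dmrs[i, c("chrom", "start", "end")], sa, sb,
                           min_cov = min_cov)
      data.frame(name = dmrs$name[i], chrom = dmrs$chrom[i],
                 start = dmrs$start[i], end = dmrs$end[i],
                 percent_a = rc$percent_a, percent_b = rc$percent_b,
                 p = rc$p, method = rc$method, stringsAsFactors = FALSE)
    }))
  }

  classification <- NULL
  if (!is.null(anchor) && nrow(dmrs) > 0L) {
    classification <- data.frame(
      name = dmrs$name, chrom = dmrs$chrom, start = dmrs$start,
      end = dmrs$end, direction = dmrs$direction,
      tss_rel_start = NA_integer_, tss_rel_end = NA_integer_,
      position_class = classify_dmr_position(dmrs, anchor, border_window),
      stringsAsFactors = FALSE)
    same <- classification$chrom == anchor$chrom
    rel <- lapply(which(same), function(i) {
      sort(tss_relative(anchor, c(dmrs$start[i], dmrs$end[i] - 1L)))
    })
    classification$tss_rel_start[same] <- vapply(rel, `[`, 0L, 1L)
    classification$tss_rel_end[same] <- vapply(rel, `[`, 0L, 2L)
    log <- c(log, sprintf("classification: %s",
                          paste(sprintf("%s=%s", classification$name,
                                        classification$position_class),
                                collapse = ", ")))
  }

  result <- structure(list(sites = sites, dmrs = dmrs, lmrs = lmrs,
                           region_report = region_report,
                           classification = classification,
                           params = params, log = log),
                      class = "dmr_run")
  if (!is.null(out_dir)) write_run(result, out_dir)
  invisible(result)
}

# write all pipeline artifacts; deterministic (no wall-clock content)
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_sites_tsv(result$sites, file.path(out_dir, "sites.tsv"))
  utils::write.table(as.data.frame(result$dmrs),
                     file.path(out_dir, "dmrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(result$dmrs) > 0L) {
    write_bed(genomic_intervals(result$dmrs$chrom, result$dmrs$start,
                                result$dmrs$end, result$dmrs$name),
              file.path(out_dir, "dmrs.bed"))
  } else {
    writeLines(character(), file.path(out_dir, "dmrs.bed"))
  }
  for (id in names(result$lmrs)) {
    utils::write.table(as.data.frame(result$lmrs[[id]]),
                       file.path(out_dir, sprintf("lmrs_%s.tsv", id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$region_report)) {
    utils::write.table(result$region_report,
                       file.path(out_dir, "region_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$classification)) {
    utils::write.table(result$classification,
                       file.path(out_dir, "classification.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.dmr_run <- function(x, ...) {
  cat(paste(x$log, collapse = "\n"), "\n")
  invisible(x)
}
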