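#' CpG site table
#'
#' Builds the canonical per-CpG count table used throughout the package:
#' one row per CpG with the chromosome, the 0-based position of the C of the
#' CpG on the plus strand, and methylated/unmethylated read counts.  Rows are
#' sorted by `(chrom, pos)`; duplicate positions on a chromosome have their
#' counts summed with a warning (per-strand callers commonly emit two records
#' per CpG).
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector, 0-based position of the plus-strand C.
#' @param meth,unmeth non-negative integer read counts.
#' @return A `data.frame` of class `cpg_sites` with columns
#'   `chrom`, `pos`, `meth`, `unmeth`.
#' @examples
#' cpg_sites("chr1", c(100L, 150L), meth = c(9L, 0L), unmeth = c(1L, 10L))
#' @export
cpg_sites <- function(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer()) {
  n <- length(pos)
  stopifnot(length(chrom) %in% c(1L, n) || n == 0L,
            length(meth) == n, length(unmeth) == n)
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  meth <- as.integer(meth)
  unmeth <- as.integer(unmeth)
  if (anyNA(pos) || anyNA(meth) || anyNA(unmeth) || anyNA(chrom)) {
    stop("cpg_sites: NA values are not permitted")
  }
  if (any(pos < 0L)) stop("cpg_sites: positions must be >= 0")
  if (any(meth < 0L) || any(unmeth < 0L)) {
    stop("cpg_sites: read counts must be non-negative")
  }
  df <- data.frame(chrom = chrom, pos = pos, meth = meth, unmeth = unmeth,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) {
    warning("cpg_sites: duplicate positions found; counts were summed")
    df <- aggregate_counts(df)
  }
  rownames(df) <- NULL
  class(df) <- c("cpg_sites", "data.frame")
  df
}

# sum meth/unmeth over duplicate (chrom, pos) keys; input must be sorted
aggregate_counts <- function(df) {
  key <- paste(df$chrom, df$pos)
  meth <- rowsum(df$meth, key, reorder = FALSE)
  unmeth <- rowsum(df$unmeth, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(chrom = df$chrom[first], pos = df$pos[first],
                    meth = as.integer(meth[, 1L]),
                    unmeth = as.integer(unmeth[, 1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' A sample's methylome: CpG count track plus group label
#'
#' @param sample_id sample identifier.
#' @param group group label (one of exactly two per contrast downstream).
#' @param sites a [cpg_sites] table (or a data.frame coercible to one).
#' @return An object of class `methylome_sample`: a list with elements
#'   `sample_id`, `group`, `sites`.
#' @export
methylome_sample <- function(sample_id, group, sites) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            is.character(group), length(group) == 1L)
  if (!inherits(sites, "cpg_sites")) {
    sites <- cpg_sites(sites$chrom, sites$pos, sites$meth, sites$unmeth)
  }
  structure(list(sample_id = sample_id, group = group, sites = sites),
            class = "methylome_sample")
}

#' @export
print.methylome_sample <- function(x, ...) {
  cov <- x$sites$meth + x$sites$unmeth
  cat(sprintf("methylome_sample '%s' (group %s): %d CpGs", x$sample_id,
              x$group, nrow(x$sites)))
  if (nrow(x$sites) > 0L) {
    cat(sprintf(", mean coverage %.1f, pooled methylation %.3f",
                mean(cov), sum(x$sites$meth) / max(1, sum(cov))))
  }
  cat("\n")
  invisible(x)
}

#' Genomic interval table (BED-like, 0-based half-open)
#'
#' @param chrom character vector.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name,score,strand optional BED columns; strand one of `"+"`, `"-"`,
#'   `"."`.
#' @return A `data.frame` of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), name = NULL, score = NULL,
                              strand = NULL) {
  n <- length(start)
  if (n > 0L && length(chrom) == 1L) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n, length(end) == n)
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("genomic_intervals: start must be >= 0")
  if (any(start >= end)) stop("genomic_intervals: require start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = if (is.null(name)) rep(".", n) else as.character(name),
                   score = if (is.null(score)) rep(".", n) else as.character(score),
                   strand = if (is.null(strand)) rep(".", n) else as.character(strand),
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("genomic_intervals: strand must be one of '+', '-', '.'")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Read a CpG coverage file into a methylome sample
#'
#' Reads Bismark-style coverage output (tab-delimited:
#' chrom, start, end, percent methylation, methylated count, unmethylated
#' count).  The percent column is ignored and recomputed from counts.  In the
#' `"bismark"` dialect positions are 1-based inclusive and are shifted to the
#' package's internal 0-based convention; in the `"bedgraph"` dialect the
#' start column is already 0-based.
#'
#' @param path file path.
#' @param sample_id,group labels for the resulting [methylome_sample].
#' @param dialect `"bismark"` (1-based, default) or `"bedgraph"` (0-based).
#' @return A [methylome_sample]; sites sorted, duplicates summed (warning).
#' @export
read_coverage <- function(path, sample_id, group,
                          dialect = c("bismark", "bedgraph")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(methylome_sample(sample_id, group, cpg_sites()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("read_coverage: malformed line %d in '%s' (%d fields, need >= 6)",
                 which(nf < 6L)[1L], path, nf[which(nf < 6L)[1L]]))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  meth <- suppressWarnings(as.integer(m[, 5L]))
  unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(start) | is.na(meth) | is.na(unmeth))
  if (length(bad) > 0L) {
    stop(sprintf("read_coverage: malformed line %d in '%s' (non-numeric field)",
                 bad[1L], path))
  }
  neg <- which(meth < 0L | unmeth < 0L)
  if (length(neg) > 0L) {
    stop(sprintf("read_coverage: negative count on line %d in '%s'",
                 neg[1L], path))
  }
  pos <- if (dialect == "bismark") start - 1L else start
  if (any(pos < 0L)) {
    stop(sprintf("read_coverage: position < %d on line %d in '%s'",
                 if (dialect == "bismark") 1L else 0L, which(pos < 0L)[1L], path))
  }
  methylome_sample(sample_id, group, cpg_sites(m[, 1L], pos, meth, unmeth))
}

#' Write a methylome sample as a Bismark-style coverage file
#'
#' Inverse of [read_coverage] (dialect `"bismark"`): 1-based inclusive
#' coordinates, percent methylation recomputed from counts (0 for uncovered
#' sites).
#'
#' @param sample a [methylome_sample].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_coverage <- function(sample, path) {
  s <- sample$sites
  cov <- s$meth + s$unmeth
  pct <- ifelse(cov > 0L, 100 * s$meth / cov, 0)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", s$chrom, s$pos + 1L, s$pos + 1L,
                   format(pct, trim = TRUE, digits = 10), s$meth, s$unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Merge plus- and minus-strand CpG records onto the plus-strand C
#'
#' Bisulfite callers run per strand emit two records per CpG: the plus-strand
#' C at position `p` and its minus-strand mate at `p + 1`.  Counts of mate
#' pairs are summed onto the plus-strand position; unpaired records are
#' retained as-is.  A minus-strand record at a position already occupied by a
#' plus-strand record is not a mate and raises an error.
#'
#' @param plus,minus [cpg_sites] tables for the two strands.
#' @return A [cpg_sites] table on plus-strand coordinates.
#' @export
merge_strands <- function(plus, minus) {
  stopifnot(inherits(plus, "cpg_sites"), inherits(minus, "cpg_sites"))
  if (nrow(minus) == 0L) return(plus)
  pk <- paste(plus$chrom, plus$pos)
  clash <- paste(minus$chrom, minus$pos) %in% pk
  if (any(clash)) {
    stop(sprintf("merge_strands: minus-strand record at %s:%d overlaps a non-mate plus-strand position",
                 minus$chrom[clash][1L], minus$pos[clash][1L]))
  }
  mate_key <- paste(minus$chrom, minus$pos - 1L)
  paired <- mate_key %in% pk
  shifted <- minus
  shifted$pos[paired] <- shifted$pos[paired] - 1L
  all_rows <- rbind(as.data.frame(plus), as.data.frame(shifted))
  suppressWarnings(cpg_sites(all_rows$chrom, all_rows$pos,
                             all_rows$meth, all_rows$unmeth))
}

#' Drop CpGs below a minimum read coverage
#'
#' The default threshold of 5 reads per CpG per sample is the conventional
#' display/analysis floor for WGBS-class data.
#'
#' @param sample a [methylome_sample].
#' @param min_cov minimum `meth + unmeth` to retain (default 5).
#' @return A [methylome_sample] with the filtered site table.
#' @export
filter_coverage <- function(sample, min_cov = 5L) {
  stopifnot(min_cov >= 0)
  keep <- (sample$sites$meth + sample$sites$unmeth) >= min_cov
  out <- sample
  out$sites <- sample$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  class(out$sites) <- c("cpg_sites", "data.frame")
  out
}

#' Write intervals as BED6
#'
#' Output is 0-based half-open, sorted by `(chrom, start)`.
#'
#' @param intervals a [genomic_intervals] table (or coercible data.frame with
#'   `chrom`, `start`, `end` columns).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  if (!inherits(intervals, "genomic_intervals")) {
    intervals <- genomic_intervals(intervals$chrom, intervals$start,
                                   intervals$end, intervals$name,
                                   intervals$score, intervals$strand)
  }
  iv <- intervals[order(intervals$chrom, intervals$start, intervals$end), ,
                  drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", iv$chrom, iv$start, iv$end,
                   iv$name, iv$score, iv$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file (3 to 6 columns) as genomic intervals
#'
#' @param path BED file path.
#' @return A [genomic_intervals] table.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(genomic_intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("read_bed: malformed line %d in '%s'", which(nf < 3L)[1L], path))
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, "")
  }
  genomic_intervals(chrom = get(1L, "."),
                    start = as.integer(get(2L, NA)),
                    end = as.integer(get(3L, NA)),
                    name = get(4L, "."), score = get(5L, "."),
                    strand = get(6L, "."))
}

#' Write per-site test results as a plain TSV
#'
#' @param results a site test result table (see [test_all_sites]).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sites_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
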