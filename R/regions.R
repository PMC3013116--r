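#' Region-detection parameters
#'
#' Hyper-mutated regions are flagged where depressed coverage (window mean
#' more than `sd_factor` standard deviations below the genome-wide mean)
#' coincides with a cluster of called differences (`min_cluster` or more per
#' window). Windows slide by half their width and qualifying windows are
#' merged.
#'
#' @param sd_factor how many standard deviations below the mean coverage
#'   counts as an extreme change.
#' @param window sliding window width in bases (step is `window / 2`).
#' @param min_cluster minimum called differences per window.
#' @param min_uncovered_len minimum length of a reported zero-coverage run.
#' @return An object of class `region_params`.
#' @export
region_params <- function(sd_factor = 1.0, window = 500L, min_cluster = 5L,
                          min_uncovered_len = 1L) {
  stopifnot(window > 0L, min_cluster >= 1L)
  structure(list(sd_factor = sd_factor, window = as.integer(window),
                 min_cluster = as.integer(min_cluster),
                 min_uncovered_len = as.integer(min_uncovered_len)),
            class = "region_params")
}

#' Per-position coverage track
#'
#' Depth is the number of aligned read bases (match or mismatch columns) at
#' each reference position, zero where nothing aligns. Mean and standard
#' deviation are computed over all genome positions, zeros included, unless
#' `exclude_zeros`.
#'
#' @param pileup a [build_pileup()] result.
#' @param exclude_zeros drop zero-depth positions from the mean/SD summary.
#' @return An object of class `coverage_track`: list with `depth`, `mean`,
#'   `sd`, `fraction_uncovered`, `genome_name`.
#' @export
coverage_profile <- function(pileup, exclude_zeros = FALSE) {
  stopifnot(inherits(pileup, "pileup"))
  depth <- as.integer(colSums(pileup$base_counts))
  d <- if (exclude_zeros) depth[depth > 0L] else depth
  structure(list(depth = depth,
                 mean = if (length(d)) mean(d) else 0,
                 sd = if (length(d) > 1L) sd(d) else 0,
                 fraction_uncovered = mean(depth == 0L),
                 genome_name = pileup$genome_name),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: mean depth %.1f (sd %.1f), %.2f%% uncovered\n",
              x$genome_name, x$mean, x$sd, 100 * x$fraction_uncovered))
  invisible(x)
}

#' Find zero-coverage runs (candidate large deletions)
#'
#' Maximal runs of zero depth, at least `min_uncovered_len` bases long.
#'
#' @param track a [coverage_profile()] result, or a bare integer depth
#'   vector.
#' @param min_uncovered_len minimum run length in bases.
#' @return A region data.frame (`start`, `end`, `length`, `label` =
#'   `"uncovered"`), with attributes `total_uncovered` (bases at zero depth,
#'   regardless of run length) and `percent_uncovered` (of the genome).
#' @export
find_uncovered_runs <- function(track, min_uncovered_len = 1L) {
  depth <- if (inherits(track, "coverage_track")) track$depth else track
  r <- rle(depth == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_uncovered_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep],
                    label = rep("uncovered", sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "total_uncovered") <- sum(depth == 0L)
  attr(out, "percent_uncovered") <- 100 * mean(depth == 0L)
  out
}

#' Flag hyper-mutated regions
#'
#' Regions so diverged from the mediator that short reads align poorly show
#' two coupled signatures: depressed coverage and a cluster of called
#' differences. Sliding windows (step = half the window) qualify when the
#' window's mean depth is below `mean - sd_factor * sd` of the track AND the
#' window holds at least `min_cluster` strict-pass calls; overlapping
#' qualifying windows are merged.
#'
#' @param track a [coverage_profile()] result.
#' @param diff_table strict-pass [difference_table()].
#' @param params a [region_params()].
#' @return A region data.frame (`start`, `end`, `length`, `label` =
#'   `"hypermutated"`).
#' @export
find_hypermutated <- function(track, diff_table, params = region_params()) {
  stopifnot(inherits(track, "coverage_track"))
  glen <- length(track$depth)
  w <- params$window
  step <- max(1L, w %/% 2L)
  starts <- seq.int(1L, max(1L, glen - w + 1L), by = step)
  cum <- c(0, cumsum(as.numeric(track$depth)))
  thresh <- track$mean - params$sd_factor * track$sd
  pos <- diff_table$pos
  hits <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(glen, s + w - 1L)
    wmean <- (cum[e + 1L] - cum[s]) / (e - s + 1L)
    if (wmean >= thresh) next
    if (sum(pos >= s & pos <= e) < params$min_cluster) next
    hits[i] <- TRUE
  }
  if (!any(hits))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), label = character(0),
                      stringsAsFactors = FALSE))
  qs <- starts[hits]
  qe <- pmin(glen, qs + w - 1L)
  m <- IRanges::reduce(IRanges::IRanges(qs, qe))
  data.frame(start = BiocGenerics::start(m), end = BiocGenerics::end(m),
             length = BiocGenerics::width(m),
             label = rep("hypermutated", length(m)),
             stringsAsFactors = FALSE)
}

#' Upper bound on total inserted sequence absent from the mediator
#'
#' Reads originating inside insertions have nothing to align to, so the sum
#' of the unaligned reads' lengths divided by the mean depth bounds the
#' total inserted sequence (rounded down).
#'
#' @param unaligned_reads [read_set()] of the unaligned reads (or an integer
#'   vector of their lengths).
#' @param track a [coverage_profile()] with positive mean depth.
#' @return Upper bound in bases (integer).
#' @export
estimate_max_insertion <- function(unaligned_reads, track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$mean <= 0) stop("mean depth is zero; bound undefined")
  lens <- if (inherits(unaligned_reads, "read_set"))
    nchar(unaligned_reads$sequence) else as.integer(unaligned_reads)
  as.integer(floor(sum(as.numeric(lens)) / track$mean))
}

#' Write regions as BED
#'
#' BED uses 0-based half-open intervals; the conversion from the package's
#' 1-based inclusive regions happens here.
#'
#' @param regions a region data.frame (`start`, `end`, `label`).
#' @param path output file.
#' @param seqname sequence name for column 1.
#' @export
write_bed <- function(regions, path, seqname = "genome") {
  lines <- sprintf("%s\t%d\t%d\t%s", seqname, regions$start - 1L,
                   regions$end, regions$label)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of regions
#' @param path BED file (0-based half-open); converted to 1-based inclusive.
#' @return A region data.frame (`start`, `end`, `length`, `label`).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(start = df[[2]] + 1L, end = df[[3]],
             length = df[[3]] - df[[2]],
             label = if (ncol(df) >= 4L) df[[4]] else "region",
             stringsAsFactors = FALSE)
}
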