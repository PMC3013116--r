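#' Matching key of a variant call
#'
#' Two calls denote the same mutation iff their (position, type, alt allele)
#' agree; coverage, alt fraction and pass mode are ignored, so a variant
#' called strictly in one isolate and relaxed in the other still matches.
#' Requiring the identical alt allele (not just the position) keeps two
#' isolates that mutated independently at one site from cancelling out.
#'
#' @param calls a [difference_table()] or compatible data.frame.
#' @return Character vector of keys, one per call.
#' @export
match_key <- function(calls) {
  paste(calls$pos, calls$type, calls$alt_allele, sep = "|")
}

#' Subtract the wild-type difference table from the mutant's
#'
#' Partitions the union of the two tables into mutations common to both
#' isolates (the evolutionary distance to the mediator, discarded from
#' further analysis), mutations unique to the mutant (the candidate
#' causative set), and mutations unique to the wild type.
#'
#' @param mutant,wt [difference_table()]s against the same mediator genome.
#' @return An object of class `subtraction`: list of three
#'   [difference_table()]s (`common`, `unique_to_mutant`, `unique_to_wt`)
#'   plus the cardinality summary. The partition identities
#'   `|mutant| = |common| + |unique_to_mutant|` and
#'   `|wt| = |common| + |unique_to_wt|` are asserted on every run.
#' @export
subtract <- function(mutant, wt) {
  stopifnot(inherits(mutant, "difference_table"),
            inherits(wt, "difference_table"))
  if (attr(mutant, "genome_name") != attr(wt, "genome_name"))
    stop("difference tables refer to different genomes ('",
         attr(mutant, "genome_name"), "' vs '", attr(wt, "genome_name"), "')")
  mk <- match_key(mutant)
  wk <- match_key(wt)
  gname <- attr(mutant, "genome_name")
  dt <- function(df, label) difference_table(df, label, gname)
  common <- dt(as.data.frame(mutant)[mk %in% wk, , drop = FALSE], "common")
  um <- dt(as.data.frame(mutant)[!(mk %in% wk), , drop = FALSE],
           attr(mutant, "isolate"))
  uw <- dt(as.data.frame(wt)[!(wk %in% mk), , drop = FALSE],
           attr(wt, "isolate"))
  stopifnot(nrow(mutant) == nrow(common) + nrow(um),
            nrow(wt) == nrow(common) + nrow(uw))
  structure(list(common = common, unique_to_mutant = um, unique_to_wt = uw,
                 n_mutant = nrow(mutant), n_wt = nrow(wt),
                 n_common = nrow(common)),
            class = "subtraction")
}

#' @export
print.subtraction <- function(x, ...) {
  cat(sprintf(paste0("<subtraction> mutant calls: %s | WT calls: %s | ",
                     "common: %s (%.1f%% of WT)\n",
                     "  unique to mutant: %d | unique to WT: %d\n"),
              format(x$n_mutant, big.mark = ","),
              format(x$n_wt, big.mark = ","),
              format(x$n_common, big.mark = ","),
              if (x$n_wt) 100 * x$n_common / x$n_wt else 0,
              nrow(x$unique_to_mutant), nrow(x$unique_to_wt)))
  invisible(x)
}

#' Regions uncovered in the mutant but covered in the wild type
#'
#' Maximal sub-intervals of the mutant's uncovered regions that no wild-type
#' uncovered region overlaps, filtered to a minimum length: candidate large
#' deletions unique to the mutant. Uncovered regions shared by both isolates
#' reflect divergence from (or deletions relative to) the mediator and drop
#' out.
#'
#' @param mutant_regions,wt_regions region data.frames (`start`, `end`,
#'   1-based inclusive) from [find_uncovered_runs()] on the same genome.
#' @param min_len minimum reported length in bases.
#' @return A region data.frame (`start`, `end`, `length`, `label`).
#' @export
compare_uncovered <- function(mutant_regions, wt_regions, min_len = 50L) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(mutant_regions) || nrow(mutant_regions) == 0L) return(empty)
  m <- IRanges::IRanges(mutant_regions$start, mutant_regions$end)
  w <- if (is.null(wt_regions) || nrow(wt_regions) == 0L)
    IRanges::IRanges() else IRanges::IRanges(wt_regions$start, wt_regions$end)
  d <- IRanges::setdiff(m, w)
  keep <- BiocGenerics::width(d) >= min_len
  d <- d[keep]
  data.frame(start = BiocGenerics::start(d), end = BiocGenerics::end(d),
             length = BiocGenerics::width(d),
             label = rep("mutant_only_uncovered", length(d)),
             stringsAsFactors = FALSE)
}
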