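#' Build a per-position pileup from alignments
#'
#' Projects alignment columns onto the mediator genome. At each reference
#' position the pileup records the read-base tallies over non-gap columns,
#' the number of reads showing a gap (deletion), insertion events keyed by
#' the inserted sequence and anchored to the reference position preceding the
#' inserted bases, and the overlap coverage (reads whose alignment interval
#' spans the position, deletions included). Minus-strand alignments
#' contribute reference-strand bases.
#'
#' @param alignments an `alignment_set` from [align_readset()] (or a
#'   compatible alignment data.frame).
#' @param ref the [reference_genome()] the alignments refer to.
#' @return An object of class `pileup`: list with `coverage`, `del_count`
#'   (integer vectors over the genome), `base_counts` (4 x genome-length
#'   matrix, rows A/C/G/T), `ins` (data.frame `pos`, `seq`, `count`),
#'   `genome_name`, `genome_length` and `ref_sequence`.
#' @export
build_pileup <- function(alignments, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  a <- if (inherits(alignments, "alignment_set")) alignments$alignments
       else alignments
  if (inherits(alignments, "alignment_set") &&
      alignments$genome_name != ref$name)
    stop("alignments were made against genome '", alignments$genome_name, "'")
  if (nrow(a) > 0L &&
      (any(a$ref_start < 1L) || any(a$ref_end > ref$length)))
    stop("alignment interval outside genome bounds")
  res <- cpp_build_pileup(ref$length, a$ref_start, a$ref_aln, a$read_aln)
  bc <- res$base_counts
  rownames(bc) <- BASES
  ins <- data.frame(pos = res$ins_pos, seq = res$ins_seq,
                    count = res$ins_count, stringsAsFactors = FALSE)
  ins <- ins[order(ins$pos, ins$seq), , drop = FALSE]
  rownames(ins) <- NULL
  structure(list(coverage = res$coverage, del_count = res$del_count,
                 base_counts = bc, ins = ins,
                 genome_name = ref$name, genome_length = ref$length,
                 ref_sequence = ref$sequence),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cov <- sum(x$coverage > 0L)
  cat(sprintf("<pileup> %s: %s/%s positions covered (mean depth %.1f)\n",
              x$genome_name, format(cov, big.mark = ","),
              format(x$genome_length, big.mark = ","),
              mean(x$coverage)))
  invisible(x)
}

#' Inspect one pileup column
#'
#' @param pileup a [build_pileup()] result.
#' @param pos 1-based reference position.
#' @return List with `ref_pos`, `ref_base`, `base_counts`, `del_count`,
#'   `ins_events` and `coverage`.
#' @export
pileup_column <- function(pileup, pos) {
  stopifnot(inherits(pileup, "pileup"), pos >= 1L, pos <= pileup$genome_length)
  ins <- pileup$ins[pileup$ins$pos == pos, , drop = FALSE]
  ev <- ins$count
  names(ev) <- ins$seq
  list(ref_pos = as.integer(pos),
       ref_base = substr(pileup$ref_sequence, pos, pos),
       base_counts = pileup$base_counts[, pos],
       del_count = pileup$del_count[pos],
       ins_events = ev,
       coverage = pileup$coverage[pos])
}
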