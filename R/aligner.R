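#' Aligner parameters
#'
#' The alignment contract mirrors short-read BLASTN mapping with a word size
#' of 11, at most 6 alignment errors (mismatches plus gap columns combined;
#' gaps are single-base columns, runs of which realise multi-base indels) and
#' a minimum aligned length. When `min_align_len` is `NULL` it defaults, per
#' read set, to `ceiling(0.8 * modal read length)` - 27 for 33 bp reads.
#'
#' @param word_size exact-match seed length in bases (>= 4).
#' @param max_errors maximum mismatches + gap columns in a reported alignment.
#' @param min_align_len minimum number of alignment columns, or `NULL` for
#'   the per-read-set default rule.
#' @param both_strands also align the reverse complement of each read.
#' @return An object of class `aligner_params`.
#' @export
aligner_params <- function(word_size = 11L, max_errors = 6L,
                           min_align_len = NULL, both_strands = TRUE) {
  word_size <- as.integer(word_size)
  max_errors <- as.integer(max_errors)
  if (word_size < 4L) stop("word_size must be >= 4")
  if (max_errors < 0L) stop("max_errors must be >= 0")
  if (!is.null(min_align_len)) {
    min_align_len <- as.integer(min_align_len)
    if (min_align_len < word_size) stop("min_align_len must be >= word_size")
  }
  structure(list(word_size = word_size, max_errors = max_errors,
                 min_align_len = min_align_len, both_strands = both_strands),
            class = "aligner_params")
}

default_min_align_len <- function(modal_length) {
  as.integer(ceiling(0.8 * modal_length))
}

#' Build an exact-match seed index of a reference genome
#'
#' Maps every `word_size`-mer of the forward strand to its start positions
#' (1-based). Words containing N are excluded. The index is a session object
#' (external pointer); rebuild it rather than serialising it.
#'
#' @param ref a [reference_genome()].
#' @param word_size seed length (4-15 bases).
#' @return An object of class `seed_index`.
#' @export
build_seed_index <- function(ref, word_size = 11L) {
  stopifnot(inherits(ref, "reference_genome"))
  word_size <- as.integer(word_size)
  if (word_size > ref$length) stop("reference shorter than word_size")
  structure(list(ptr = cpp_seed_index(ref$sequence, word_size),
                 word_size = word_size, genome_name = ref$name,
                 ref_length = ref$length),
            class = "seed_index")
}

#' Look up a seed word in the index
#'
#' @param index a [build_seed_index()] result.
#' @param word a string of exactly `word_size` bases.
#' @return Integer vector of 1-based start positions (empty when the word is
#'   absent or contains non-ACGT characters).
#' @export
seed_lookup <- function(index, word) {
  stopifnot(inherits(index, "seed_index"))
  cpp_seed_lookup(index$ptr, toupper(word))
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %s: %d distinct %d-mers\n", x$genome_name,
              cpp_seed_index_nwords(x$ptr), x$word_size))
  invisible(x)
}

as_alignment_df <- function(res, ids) {
  ok <- res$status == "aligned"
  data.frame(read_id = ids[ok],
             ref_start = res$ref_start[ok],
             ref_end = res$ref_end[ok],
             strand = res$strand[ok],
             n_mismatches = res$n_mismatches[ok],
             n_gap_columns = res$n_gap_columns[ok],
             aligned_len = res$aligned_len[ok],
             ref_aln = res$ref_aln[ok],
             read_aln = res$read_aln[ok],
             stringsAsFactors = FALSE)
}

#' Align one read against the mediator genome
#'
#' Seeds from the read (and its reverse complement when `both_strands`) are
#' extended by a banded edit-distance dynamic program permitting
#' substitutions and single-base gap columns. The best alignment minimises
#' errors, then maximises aligned length, then takes the smaller reference
#' start, then the plus strand. Reads whose two best placements tie on
#' (errors, aligned length) at distinct loci are discarded as ambiguous.
#'
#' @param read a single read sequence (string).
#' @param index a [build_seed_index()] of `ref`.
#' @param ref the [reference_genome()] the index was built from.
#' @param params an [aligner_params()]; `min_align_len` must be set here (the
#'   read-set default rule needs a read set).
#' @return A one-row alignment data.frame, or `NULL` when the read is
#'   unaligned (unalignable, ambiguous, or shorter than the word size -
#'   valid outcomes, not errors; [align_readset()] reports the breakdown).
#' @export
align_read <- function(read, index, ref, params = aligner_params(min_align_len = 27L)) {
  stopifnot(inherits(index, "seed_index"), inherits(ref, "reference_genome"))
  if (index$genome_name != ref$name)
    stop("seed index was built for genome '", index$genome_name, "'")
  mal <- params$min_align_len %||% default_min_align_len(nchar(read))
  res <- cpp_align_reads(toupper(read), index$ptr, ref$sequence,
                         params$max_errors, mal, params$both_strands)
  if (res$status[1L] != "aligned") return(NULL)
  as_alignment_df(res, "read")
}

#' Align a read set against the mediator genome
#'
#' Applies [align_read()]'s contract to every read and tallies the counts the
#' pipeline reports: reads aligned, unaligned, discarded as ambiguous, and
#' aligned with one or more errors.
#'
#' @param reads a non-empty [read_set()].
#' @param ref a [reference_genome()].
#' @param params an [aligner_params()].
#' @param index optional pre-built [build_seed_index()] (rebuilt when `NULL`).
#' @return An object of class `alignment_set`: list with `alignments` (one
#'   row per placed read), `unaligned` and `ambiguous` (read ids), `counts`,
#'   and the `min_align_len` actually applied.
#' @export
align_readset <- function(reads, ref, params = aligner_params(), index = NULL) {
  stopifnot(inherits(reads, "read_set"), inherits(ref, "reference_genome"))
  if (reads$n_reads == 0L) stop("empty read set")
  if (is.null(index)) index <- build_seed_index(ref, params$word_size)
  if (index$word_size != params$word_size)
    stop("index word_size differs from params$word_size")
  mal <- params$min_align_len %||% default_min_align_len(reads$modal_length)
  res <- cpp_align_reads(reads$sequence, index$ptr, ref$sequence,
                         params$max_errors, mal, params$both_strands)
  aln <- as_alignment_df(res, reads$id)
  counts <- list(
    total = reads$n_reads,
    aligned = nrow(aln),
    unaligned = sum(res$status %in% c("unaligned", "too_short")),
    ambiguous = sum(res$status == "ambiguous"),
    with_errors = sum(aln$n_mismatches + aln$n_gap_columns >= 1L))
  structure(list(alignments = aln,
                 unaligned = reads$id[res$status %in% c("unaligned", "too_short")],
                 ambiguous = reads$id[res$status == "ambiguous"],
                 counts = counts,
                 genome_name = ref$name,
                 min_align_len = mal),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(paste0("<alignment_set> vs %s: %s/%s reads aligned ",
                     "(%.1f%% with >=1 error), %s unaligned, %s ambiguous\n"),
              x$genome_name, format(ct$aligned, big.mark = ","),
              format(ct$total, big.mark = ","),
              if (ct$aligned) 100 * ct$with_errors / ct$aligned else 0,
              format(ct$unaligned, big.mark = ","),
              format(ct$ambiguous, big.mark = ",")))
  invisible(x)
}

#' Exhaustive-alignment oracle for one read
#'
#' Scans every placement on both strands with an unbanded dynamic program
#' under the identical scoring contract as [align_read()] (no seeding).
#' Intended for validation on small instances; cost grows with
#' `length(ref) * nchar(read)`.
#'
#' @inheritParams align_read
#' @return A list with `aligned` and, when `TRUE`, `errors`, `aligned_len`,
#'   `ref_start` and `strand`.
#' @export
oracle_align <- function(read, ref, params = aligner_params(min_align_len = 27L)) {
  stopifnot(inherits(ref, "reference_genome"))
  mal <- params$min_align_len %||% default_min_align_len(nchar(read))
  cpp_oracle_align(toupper(read), ref$sequence, params$max_errors, mal,
                   params$both_strands)
}

#' Import externally produced alignments in BLAST tabular (outfmt 6) form
#'
#' Columns expected: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore. Gap columns cannot be reconstructed from this
#' dialect, so only ungapped rows (`gapopen == 0`) are imported and the
#' resulting alignments support SNV calling only; gapped rows are skipped
#' with a message.
#'
#' @param path tabular alignment file.
#' @param reads the [read_set()] the query ids refer to.
#' @param ref the [reference_genome()] the subject coordinates refer to.
#' @return An `alignment_set` (ungapped alignments only).
#' @export
read_blast_tab <- function(path, reads, ref) {
  stopifnot(inherits(reads, "read_set"), inherits(ref, "reference_genome"))
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 tab-separated columns (outfmt 6)")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  gapped <- df$gapopen > 0L
  if (any(gapped))
    message(sum(gapped), " gapped alignment(s) skipped: gap columns are not ",
            "recoverable from tabular input; imported alignments support ",
            "SNV calling only")
  message("imported tabular alignments support SNV calling only ",
          "(no gap columns)")
  df <- df[!gapped, , drop = FALSE]
  idx <- match(df$qseqid, reads$id)
  if (anyNA(idx)) stop("query id(s) absent from read set: ",
                       paste(head(unique(df$qseqid[is.na(idx)])), collapse = ", "))
  minus <- df$sstart > df$send
  s0 <- ifelse(minus, df$send, df$sstart)
  e0 <- ifelse(minus, df$sstart, df$send)
  ra <- substring(ref$sequence, s0, e0)
  qa <- substring(reads$sequence[idx], df$qstart, df$qend)
  qa[minus] <- revcomp_chr(qa[minus])
  if (any(nchar(ra) != nchar(qa)))
    stop("ungapped alignment with unequal query/subject spans")
  nmm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ra, qa, USE.NAMES = FALSE)
  aln <- data.frame(read_id = df$qseqid, ref_start = s0, ref_end = e0,
                    strand = ifelse(minus, "-", "+"),
                    n_mismatches = as.integer(nmm),
                    n_gap_columns = 0L,
                    aligned_len = as.integer(nchar(ra)),
                    ref_aln = ra, read_aln = qa, stringsAsFactors = FALSE)
  structure(list(alignments = aln, unaligned = setdiff(reads$id, df$qseqid),
                 ambiguous = character(0),
                 counts = list(total = reads$n_reads, aligned = nrow(aln),
                               unaligned = reads$n_reads - length(unique(df$qseqid)),
                               ambiguous = 0L,
                               with_errors = sum(nmm >= 1L)),
                 genome_name = ref$name,
                 min_align_len = NA_integer_,
                 snv_only = TRUE),
            class = "alignment_set")
}

#' Write alignments as SAM
#'
#' Minimal single-reference SAM export; unmapped reads are included with
#' flag 4, minus-strand alignments with flag 16. The stored read bases are
#' already expressed on the forward reference strand.
#'
#' @param aln_set an `alignment_set`.
#' @param reads the [read_set()] that was aligned (for unmapped sequences).
#' @param ref the [reference_genome()].
#' @param path output SAM file.
#' @export
write_sam <- function(aln_set, reads, ref, path) {
  stopifnot(inherits(aln_set, "alignment_set"), inherits(reads, "read_set"))
  a <- aln_set$alignments
  cigar <- vapply(seq_len(nrow(a)), function(i) {
    rc <- strsplit(a$ref_aln[i], "")[[1]]
    qc <- strsplit(a$read_aln[i], "")[[1]]
    op <- ifelse(rc == "-", "I", ifelse(qc == "-", "D", "M"))
    r <- rle(op)
    paste0(r$lengths, r$values, collapse = "")
  }, "")
  seqs <- gsub("-", "", a$read_aln, fixed = TRUE)
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length),
    sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
            a$read_id, ifelse(a$strand == "-", 16L, 0L), ref$name,
            a$ref_start, cigar, seqs,
            a$n_mismatches + a$n_gap_columns))
  un <- c(aln_set$unaligned, aln_set$ambiguous)
  if (length(un)) {
    ui <- match(un, reads$id)
    lines <- c(lines, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*",
                              un, reads$sequence[ui]))
  }
  writeLines(lines, path)
  invisible(path)
}
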