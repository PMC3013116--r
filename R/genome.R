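#' Reference (mediator) genome
#'
#' A named DNA sequence over the alphabet A/C/G/T/N that serves as the shared
#' coordinate system onto which both isolates' reads are mapped. All
#' coordinates in this package are 1-based inclusive, both internally and in
#' every written report.
#'
#' @param name sequence name (single string).
#' @param sequence DNA sequence; lowercase is uppercased, U is mapped to T;
#'   any character outside A/C/G/T/N is rejected with its position.
#' @return An object of class `reference_genome` with fields `name`,
#'   `sequence` and `length`.
#' @export
reference_genome <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- chartr("u", "t", sequence)
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", name, "'")
  check_alphabet(seq, paste0("record '", name, "'"))
  structure(list(name = name, sequence = seq, length = nchar(seq)),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf("<reference_genome> %s: %s bp\n", x$name,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Read a FASTA file of reference sequences
#'
#' @param path FASTA file.
#' @return A list of [reference_genome()] records, one per header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    stop("duplicate record name(s) in '", path, "': ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  out <- lapply(seq_along(set), function(i) {
    reference_genome(nms[i], as.character(set[[i]]))
  })
  names(out) <- nms
  out
}

#' Write reference sequences to FASTA
#'
#' @param genomes a `reference_genome` or list of them.
#' @param path output file.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "reference_genome")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
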