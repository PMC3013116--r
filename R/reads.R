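#' Construct a read set
#'
#' Unpaired short reads with ids, sequences and optional per-base Phred+33
#' qualities. Carries read-length statistics (modal length, total bases) used
#' to pick the aligner's default minimum alignment length.
#'
#' @param ids character vector of read ids.
#' @param sequences character vector of read sequences (A/C/G/T/N).
#' @param qualities optional character vector of Phred+33 quality strings,
#'   each the same length as its read.
#' @return An object of class `read_set`.
#' @export
read_set <- function(ids, sequences, qualities = NULL) {
  stopifnot(is.character(ids), is.character(sequences),
            length(ids) == length(sequences))
  if (length(sequences) > 0L) {
    if (any(!nzchar(sequences))) stop("empty read sequence")
    sequences <- toupper(sequences)
    bad <- grepl("[^ACGTN]", sequences)
    if (any(bad)) {
      i <- which(bad)[1L]
      check_alphabet(sequences[i], paste0("read '", ids[i], "'"))
    }
  }
  if (!is.null(qualities)) {
    stopifnot(is.character(qualities), length(qualities) == length(sequences))
    mism <- nchar(qualities) != nchar(sequences)
    if (any(mism))
      stop("sequence/quality length mismatch for record '",
           ids[which(mism)[1L]], "'")
  }
  lens <- nchar(sequences)
  tab <- if (length(lens)) table(lens) else table(integer(0))
  modal <- if (length(tab)) as.integer(names(tab)[which.max(tab)]) else NA_integer_
  structure(list(id = ids, sequence = sequences, quality = qualities,
                 n_reads = length(sequences),
                 modal_length = modal,
                 length_table = tab,
                 total_bases = sum(lens)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %s reads, modal length %s bp, %s bases\n",
              format(x$n_reads, big.mark = ","), x$modal_length,
              format(x$total_bases, big.mark = ",")))
  invisible(x)
}

#' @export
length.read_set <- function(x) x$n_reads

#' Subset a read set by index or by id
#' @param x a `read_set`.
#' @param i integer/logical index, or character vector of read ids.
#' @param ... unused.
#' @export
`[.read_set` <- function(x, i, ...) {
  if (is.character(i)) i <- x$id %in% i
  read_set(x$id[i], x$sequence[i],
           if (!is.null(x$quality)) x$quality[i])
}

#' Read short reads from FASTQ or FASTA
#'
#' FASTQ qualities are parsed as Phred+33. An empty FASTA yields a valid
#' zero-read set (downstream operations reject it).
#'
#' @param path input file.
#' @param format `"fastq"` or `"fasta"`; default guessed from the extension.
#' @return A [read_set()].
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) stop("malformed FASTA '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
    return(read_set(sub("\\s.*$", "", names(set)), as.character(set)))
  }
  # FASTQ: read records directly so that a seq/qual length mismatch can be
  # reported with its record id (strict 4-line records, the NGS export form)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': record count not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L) return(read_set(character(0), character(0), character(0)))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(hd, 1L, 1L) != "@") || any(substr(pl, 1L, 1L) != "+"))
    stop("malformed FASTQ '", path, "': missing @/+ record markers")
  ids <- sub("\\s.*$", "", substring(hd, 2L))
  mism <- nchar(sq) != nchar(qu)
  if (any(mism))
    stop("sequence/quality length mismatch for record '",
         ids[which(mism)[1L]], "' in '", path, "'")
  read_set(ids, sq, qu)
}

#' Write a read set to FASTQ or FASTA
#'
#' Reads without stored qualities are written with constant Q30 when FASTQ is
#' requested.
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @param format `"fastq"` or `"fasta"`.
#' @export
write_reads <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  stopifnot(inherits(reads, "read_set"))
  if (format == "fasta") {
    out <- character(2L * reads$n_reads)
    out[c(TRUE, FALSE)] <- paste0(">", reads$id)
    out[c(FALSE, TRUE)] <- reads$sequence
  } else {
    qual <- reads$quality %||%
      vapply(nchar(reads$sequence),
             function(n) strrep(rawToChar(as.raw(33L + 30L)), n), "")
    out <- character(4L * reads$n_reads)
    out[seq(1L, by = 4L, length.out = reads$n_reads)] <- paste0("@", reads$id)
    out[seq(2L, by = 4L, length.out = reads$n_reads)] <- reads$sequence
    out[seq(3L, by = 4L, length.out = reads$n_reads)] <- "+"
    out[seq(4L, by = 4L, length.out = reads$n_reads)] <- qual
  }
  writeLines(out, path)
  invisible(path)
}
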