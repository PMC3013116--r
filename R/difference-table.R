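#' Construct a difference table
#'
#' The per-isolate set of called differences against the mediator genome.
#' Each row is one variant call: `pos` (1-based), `type` (`SNV`, `INS`,
#' `DEL`), `ref_allele` (empty for INS), `alt_allele` (empty for DEL),
#' `coverage`, `alt_fraction` and `pass_mode` (`strict` or `relaxed`).
#' Insertions are anchored to the reference position preceding the inserted
#' bases.
#'
#' @param calls data.frame with the columns above (may have zero rows).
#' @param isolate label of the isolate the calls belong to.
#' @param genome_name name of the mediator sequence the calls are against.
#' @return A data.frame of class `difference_table`, sorted by position then
#'   type, with attributes `isolate` and `genome_name`.
#' @export
difference_table <- function(calls = NULL, isolate = "isolate",
                             genome_name = "genome") {
  if (is.null(calls) || nrow(calls) == 0L) {
    calls <- data.frame(pos = integer(0), type = character(0),
                        ref_allele = character(0), alt_allele = character(0),
                        coverage = integer(0), alt_fraction = numeric(0),
                        pass_mode = character(0), stringsAsFactors = FALSE)
  }
  need <- c("pos", "type", "ref_allele", "alt_allele", "coverage",
            "alt_fraction", "pass_mode")
  missing <- setdiff(need, names(calls))
  if (length(missing)) stop("calls lack column(s): ", paste(missing, collapse = ", "))
  calls <- calls[need]
  calls$pos <- as.integer(calls$pos)
  if (!all(calls$type %in% c("SNV", "INS", "DEL")))
    stop("type must be SNV, INS or DEL")
  bad <- calls$type == "SNV" & calls$alt_allele == calls$ref_allele
  if (any(bad)) stop("SNV with alt equal to ref at position ", calls$pos[which(bad)[1L]])
  if (any(calls$type == "DEL" & nzchar(calls$alt_allele)))
    stop("DEL calls must have an empty alt_allele")
  if (any(calls$type == "INS" & nzchar(calls$ref_allele)))
    stop("INS calls must have an empty ref_allele")
  calls <- calls[order(calls$pos, calls$type, calls$alt_allele), , drop = FALSE]
  if (anyDuplicated(calls[c("pos", "type")]))
    stop("duplicate (position, type) entries in difference table")
  rownames(calls) <- NULL
  structure(calls, class = c("difference_table", "data.frame"),
            isolate = isolate, genome_name = genome_name)
}

#' @export
print.difference_table <- function(x, ...) {
  cat(sprintf("<difference_table> isolate '%s' vs genome '%s': %d call(s)\n",
              attr(x, "isolate"), attr(x, "genome_name"), nrow(x)))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Write a difference table as TSV
#'
#' Positions are 1-based inclusive; rows are ordered by position then type.
#' Fractions are written with full precision so the file round-trips.
#'
#' @param table a [difference_table()].
#' @param path output file.
#' @export
write_difference_table <- function(table, path) {
  stopifnot(inherits(table, "difference_table"))
  df <- as.data.frame(table)
  df$alt_fraction <- sprintf("%.17g", df$alt_fraction)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("position", "type", "ref_allele", "alt_allele",
                     "coverage", "alt_fraction", "pass_mode"), collapse = "\t"),
             con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Read a difference table written by [write_difference_table()]
#'
#' @param path input TSV.
#' @param isolate,genome_name labels to attach.
#' @return A [difference_table()].
#' @export
read_difference_table <- function(path, isolate = "isolate",
                                  genome_name = "genome") {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("integer", "character", "character",
                                  "character", "integer", "numeric",
                                  "character"), na.strings = NULL)
  names(df) <- c("pos", "type", "ref_allele", "alt_allele", "coverage",
                 "alt_fraction", "pass_mode")
  df$ref_allele[is.na(df$ref_allele)] <- ""
  df$alt_allele[is.na(df$alt_allele)] <- ""
  difference_table(df, isolate = isolate, genome_name = genome_name)
}
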