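#' Read gene features (GFF3 or simple TSV)
#'
#' Loads a gene feature table used for codon-level effect annotation.
#' Coordinates are 1-based inclusive in both dialects (the GFF3 convention)
#' and are kept 1-based inclusive internally.
#'
#' The TSV dialect has columns `locus<TAB>description<TAB>start<TAB>end<TAB>strand`
#' (a header line starting with "locus" is permitted and skipped).
#'
#' @param path input file.
#' @param dialect `"gff3"` or `"tsv"`; default guessed from the extension.
#' @param genome optional [reference_genome()]; when supplied, features
#'   exceeding the genome length are rejected at load time.
#' @return A data.frame of class `gene_features` with columns `locus_tag`,
#'   `description`, `start`, `end`, `strand` and logical `partial`, sorted by
#'   `start`. Overlapping features are permitted.
#' @export
read_features <- function(path, dialect = c("auto", "gff3", "tsv"),
                          genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (dialect == "gff3") {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e) stop("malformed GFF3 '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
    md <- S4Vectors::mcols(gr)
    pick <- function(...) {
      for (nm in c(...)) {
        if (nm %in% names(md)) {
          v <- as.character(md[[nm]])
          if (any(!is.na(v))) return(v)
        }
      }
      rep(NA_character_, length(gr))
    }
    df <- data.frame(
      locus_tag = pick("locus_tag", "ID", "Name"),
      description = pick("product", "description", "Name"),
      start = BiocGenerics::start(gr),
      end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      stringsAsFactors = FALSE)
    df$partial <- if ("partial" %in% names(md))
      !is.na(md$partial) & as.character(md$partial) %in% c("true", "TRUE", "1")
    else FALSE
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(raw) > 0L && tolower(raw[1, 1]) == "locus") raw <- raw[-1, , drop = FALSE]
    if (ncol(raw) < 5L) stop("TSV feature dialect needs 5 columns, got ", ncol(raw))
    df <- data.frame(locus_tag = as.character(raw[[1]]),
                     description = as.character(raw[[2]]),
                     start = as.integer(raw[[3]]),
                     end = as.integer(raw[[4]]),
                     strand = as.character(raw[[5]]),
                     partial = if (ncol(raw) >= 6L) as.logical(raw[[6]]) else FALSE,
                     stringsAsFactors = FALSE)
  }
  if (any(df$end < df$start))
    stop("feature with end < start at row ", which(df$end < df$start)[1L])
  if (!all(df$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  if (!is.null(genome)) {
    if (any(df$start < 1L) || any(df$end > genome$length))
      stop("feature exceeds genome bounds (genome length ", genome$length, ")")
  }
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Build a gene feature table in code
#'
#' @param locus_tag,description,start,end,strand,partial vectors, recycled to
#'   a common length; coordinates 1-based inclusive.
#' @return A `gene_features` data.frame as from [read_features()].
#' @export
gene_features <- function(locus_tag, description = locus_tag, start, end,
                          strand = "+", partial = FALSE) {
  df <- data.frame(locus_tag = locus_tag, description = description,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, partial = partial,
                   stringsAsFactors = FALSE)
  if (any(df$end < df$start)) stop("feature with end < start")
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_features", "data.frame")
  df
}

#' Write a gene feature table as GFF3
#'
#' Used by the synthetic-data generator to emit toy gene models.
#'
#' @param features a `gene_features` data.frame.
#' @param path output file.
#' @param seqname sequence name placed in column 1.
#' @export
write_features_gff3 <- function(features, path, seqname = "genome") {
  lines <- c("##gff-version 3",
             sprintf("%s\tmedresq\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;locus_tag=%s;product=%s",
                     seqname, features$start, features$end, features$strand,
                     features$locus_tag, features$locus_tag,
                     features$description))
  writeLines(lines, path)
  invisible(path)
}
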