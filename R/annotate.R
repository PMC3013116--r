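#' Classify a codon substitution
#'
#' Translates both codons under the bacterial genetic code (translation
#' table 11; start-codon special cases do not apply to internal codons,
#' where its amino-acid assignments coincide with the standard code) and
#' classifies the change. Vectorised over pairs.
#'
#' @param wt_codon,mut_codon length-3 codons over A/C/G/T.
#' @return A data.frame with `wt_aa`, `mut_aa` (one-letter, `*` for stop) and
#'   `effect` (`synonymous`, `nonsynonymous`, or `nonsense`).
#' @export
classify_codon_change <- function(wt_codon, mut_codon) {
  wt_codon <- toupper(wt_codon)
  mut_codon <- toupper(mut_codon)
  stopifnot(length(wt_codon) == length(mut_codon))
  if (any(nchar(wt_codon) != 3L) || any(nchar(mut_codon) != 3L))
    stop("codons must have length 3")
  if (any(grepl("[^ACGT]", c(wt_codon, mut_codon))))
    stop("codons must be over A/C/G/T")
  code <- Biostrings::GENETIC_CODE
  wt_aa <- unname(code[wt_codon])
  mut_aa <- unname(code[mut_codon])
  effect <- ifelse(wt_aa == mut_aa, "synonymous",
                   ifelse(mut_aa == "*" & wt_aa != "*", "nonsense",
                          "nonsynonymous"))
  data.frame(wt_aa = wt_aa, mut_aa = mut_aa, effect = effect,
             stringsAsFactors = FALSE)
}

# lowercase the positions of mut_codon that differ from wt_codon
lowercase_changed <- function(wt_codon, mut_codon) {
  mapply(function(w, m) {
    wc <- strsplit(w, "")[[1]]
    mc <- strsplit(m, "")[[1]]
    mc[wc != mc] <- tolower(mc[wc != mc])
    paste(mc, collapse = "")
  }, wt_codon, mut_codon, USE.NAMES = FALSE)
}

annotate_one <- function(pos, type, ref_allele, alt_allele, features, ref) {
  inter <- data.frame(pos = pos, type = type, ref_allele = ref_allele,
                      alt_allele = alt_allele, locus_tag = "intergenic",
                      description = "N/A", wt_codon = NA_character_,
                      mut_codon = NA_character_, wt_aa = NA_character_,
                      mut_aa = NA_character_, effect = "intergenic",
                      stringsAsFactors = FALSE)
  if (is.null(features) || nrow(features) == 0L) return(inter)
  hit <- features$start <= pos & features$end >= pos
  if (!any(hit)) return(inter)
  out <- lapply(which(hit), function(fi) {
    f <- features[fi, ]
    row <- inter
    row$locus_tag <- f$locus_tag
    row$description <- f$description
    flen <- f$end - f$start + 1L
    if (flen %% 3L != 0L && !isTRUE(f$partial))
      stop("CDS '", f$locus_tag, "' length ", flen,
           " not divisible by 3 and not flagged partial")
    if (type != "SNV") {
      indel_len <- if (type == "INS") nchar(alt_allele) else nchar(ref_allele)
      row$effect <- if (indel_len %% 3L != 0L) "frameshift" else "inframe_indel"
      return(row)
    }
    if (nchar(alt_allele) != 1L || nchar(ref_allele) != 1L)
      stop("multi-base substitutions must lie within one codon")
    if (f$strand == "+") {
      off <- pos - f$start
      cs <- f$start + 3L * (off %/% 3L)
      wt_codon <- substr(ref$sequence, cs, cs + 2L)
      cp <- off %% 3L + 1L
      mut_codon <- wt_codon
      substr(mut_codon, cp, cp) <- alt_allele
    } else {
      gene <- revcomp_chr(substring(ref$sequence, f$start, f$end))
      off <- f$end - pos
      cs <- 3L * (off %/% 3L) + 1L
      wt_codon <- substr(gene, cs, cs + 2L)
      cp <- off %% 3L + 1L
      mut_codon <- wt_codon
      substr(mut_codon, cp, cp) <- comp_base(alt_allele)
    }
    cls <- classify_codon_change(wt_codon, mut_codon)
    row$wt_codon <- wt_codon
    row$mut_codon <- mut_codon
    row$wt_aa <- cls$wt_aa
    row$mut_aa <- cls$mut_aa
    row$effect <- cls$effect
    row
  })
  do.call(rbind, out)
}

#' Annotate variants with gene context and codon-level effect
#'
#' Each variant inside a CDS is annotated with the wild-type and mutated
#' codon (reading frame taken from the feature's start; minus-strand
#' features are reverse-complemented before codon extraction), the
#' amino-acid pair, and the effect class. Indels whose length is not
#' divisible by 3 inside a CDS are frameshifts; variants overlapping several
#' features get one annotation per feature; variants in no feature are
#' intergenic.
#'
#' @param table a [difference_table()] (or compatible data.frame).
#' @param features a `gene_features` data.frame from [read_features()] /
#'   [gene_features()], or `NULL`.
#' @param ref the [reference_genome()].
#' @return A data.frame of class `variant_annotations`, one row per
#'   (variant, feature) pair.
#' @export
annotate_variants <- function(table, features, ref) {
  stopifnot(inherits(ref, "reference_genome"))
  if (nrow(table) == 0L) {
    out <- annotate_one(1L, "SNV", "A", "C", NULL, ref)[0L, ]
  } else {
    out <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
      annotate_one(table$pos[i], table$type[i], table$ref_allele[i],
                   table$alt_allele[i], features, ref)
    }))
  }
  rownames(out) <- NULL
  class(out) <- c("variant_annotations", "data.frame")
  out
}

#' Write an annotated variant table as TSV
#'
#' Mirrors the classic mutant-report layout: 1-based position, locus,
#' description, wild-type and mutant codon (mutated bases lowercased),
#' amino acids, effect.
#'
#' @param annotations a [annotate_variants()] result.
#' @param path output file.
#' @export
write_annotated_table <- function(annotations, path) {
  df <- as.data.frame(annotations)
  show <- !is.na(df$wt_codon) & !is.na(df$mut_codon)
  df$mut_codon[show] <- lowercase_changed(df$wt_codon[show], df$mut_codon[show])
  for (nm in c("wt_codon", "mut_codon", "wt_aa", "mut_aa"))
    df[[nm]][is.na(df[[nm]])] <- "N/A"
  names(df)[names(df) == "pos"] <- "position"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect a direct repeat flanking a deletion
#'
#' A deleted segment flanked on both sides by an identical sequence (a
#' direct repeat) is the signature of recombination-mediated deletion.
#' Returns the longest `k` in `[min_repeat, max_repeat]` such that the `k`
#' bases immediately preceding the deletion start equal the `k` bases ending
#' at the deletion end.
#'
#' @param ref the [reference_genome()] (the mediator carrying the undeleted
#'   allele).
#' @param deletion_start,deletion_end deleted interval, 1-based inclusive.
#' @param min_repeat,max_repeat repeat length bounds in bases.
#' @return List with `length` and `sequence`, or `NULL` when no repeat of at
#'   least `min_repeat` bases exists (including insufficient flank at a
#'   genome end).
#' @export
find_flanking_direct_repeat <- function(ref, deletion_start, deletion_end,
                                        min_repeat = 4L, max_repeat = 50L) {
  stopifnot(inherits(ref, "reference_genome"),
            deletion_start >= 1L, deletion_end <= ref$length,
            deletion_start <= deletion_end)
  kmax <- min(max_repeat, deletion_start - 1L,
              deletion_end - deletion_start + 1L)
  if (kmax < min_repeat) return(NULL)
  s <- ref$sequence
  for (k in seq.int(kmax, min_repeat)) {
    left <- substr(s, deletion_start - k, deletion_start - 1L)
    right <- substr(s, deletion_end - k + 1L, deletion_end)
    if (left == right) return(list(length = k, sequence = left))
  }
  NULL
}

#' Summarise mutation classes over a panel of isolates
#'
#' Tabulates, for a panel of independently derived mutant isolates, how many
#' carry each class of mutation at a locus of interest, as whole-number
#' percentages of the panel, plus the percentage carrying any mutation.
#'
#' @param counts named integer vector: isolates per mutation class.
#' @param none_class name of the "no mutation" class, if present.
#' @return List with `table` (class, n, percent) and `percent_mutated`.
#' @export
isolate_class_summary <- function(counts, none_class = "none") {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  total <- sum(counts)
  if (total == 0L) stop("empty isolate panel")
  tab <- data.frame(class = names(counts), n = as.integer(counts),
                    percent = round(100 * as.integer(counts) / total),
                    stringsAsFactors = FALSE)
  n_none <- if (none_class %in% names(counts)) counts[[none_class]] else 0L
  list(table = tab, total = total,
       percent_mutated = round(100 * (total - n_none) / total))
}
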