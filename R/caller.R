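#' Variant-calling thresholds
#'
#' The strict pass marks a position as mutated when it is consistently
#' different from the mediator: coverage of at least `min_coverage` reads and
#' the most frequent non-reference event supported by strictly more than
#' `min_alt_fraction` of the reads overlapping the position. The relaxed pass
#' applies the lower thresholds, and only inside flagged hyper-mutated
#' regions.
#'
#' @param min_coverage strict minimum overlap coverage (reads).
#' @param min_alt_fraction strict alt-fraction threshold (exclusive).
#' @param relaxed_min_coverage,relaxed_min_alt_fraction relaxed-pass
#'   thresholds, applied only inside flagged regions.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(min_coverage = 5L, min_alt_fraction = 0.60,
                          relaxed_min_coverage = 2L,
                          relaxed_min_alt_fraction = 0.50) {
  stopifnot(min_alt_fraction > 0, min_alt_fraction < 1,
            relaxed_min_alt_fraction > 0, relaxed_min_alt_fraction < 1)
  if (relaxed_min_coverage > min_coverage ||
      relaxed_min_alt_fraction > min_alt_fraction)
    stop("relaxed thresholds must not exceed strict thresholds")
  structure(list(min_coverage = as.integer(min_coverage),
                 min_alt_fraction = min_alt_fraction,
                 relaxed_min_coverage = as.integer(relaxed_min_coverage),
                 relaxed_min_alt_fraction = relaxed_min_alt_fraction),
            class = "caller_params")
}

ref_base_index <- function(seq) {
  r <- charToRaw(seq)
  refi <- integer(length(r))
  refi[r == as.raw(65L)] <- 1L  # A
  refi[r == as.raw(67L)] <- 2L  # C
  refi[r == as.raw(71L)] <- 3L  # G
  refi[r == as.raw(84L)] <- 4L  # T
  refi
}

in_regions <- function(pos, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions)))
    hit <- hit | (pos >= regions$start[i] & pos <= regions$end[i])
  hit
}

#' Call differences between an isolate's reads and the mediator
#'
#' At every pileup column with sufficient coverage, the single most frequent
#' non-reference event (alternative base, deletion, or inserted sequence) is
#' called when its count exceeds the alt-fraction threshold of the total
#' overlap coverage (a strict inequality). Ties between two top events yield
#' no call (a true mixed site fails the consistency rule by construction).
#' Adjacent called single-base deletions, and insertions on consecutive
#' anchors, are merged into one multi-base event. Reference positions whose
#' base is N are never callable.
#'
#' @param pileup a [build_pileup()] result.
#' @param params a [caller_params()].
#' @param mode `"strict"` (genome-wide) or `"relaxed"` (inside `regions`
#'   only).
#' @param regions data.frame of regions (`start`, `end`, 1-based inclusive);
#'   required in relaxed mode.
#' @param isolate label recorded on the resulting table.
#' @return A [difference_table()].
#' @export
call_differences <- function(pileup, params = caller_params(),
                             mode = c("strict", "relaxed"), regions = NULL,
                             isolate = "isolate") {
  mode <- match.arg(mode)
  stopifnot(inherits(pileup, "pileup"))
  if (mode == "relaxed" && is.null(regions))
    stop("relaxed mode requires the flagged regions")
  min_cov <- if (mode == "strict") params$min_coverage else params$relaxed_min_coverage
  frac <- if (mode == "strict") params$min_alt_fraction else params$relaxed_min_alt_fraction

  cov <- pileup$coverage
  refi <- ref_base_index(pileup$ref_sequence)
  eligible <- cov >= min_cov & refi > 0L
  if (mode == "relaxed")
    eligible <- eligible & in_regions(seq_along(cov), regions)
  p <- which(eligible)
  empty <- difference_table(NULL, isolate, pileup$genome_name)
  if (!length(p)) return(empty)

  np <- length(p)
  cnt <- pileup$base_counts[, p, drop = FALSE]
  ri <- refi[p]
  cnt[cbind(ri, seq_len(np))] <- -1L
  b1 <- max.col(t(cnt), ties.method = "first")
  m1b <- cnt[cbind(b1, seq_len(np))]
  cnt[cbind(b1, seq_len(np))] <- -1L
  b2 <- max.col(t(cnt), ties.method = "first")
  m2b <- cnt[cbind(b2, seq_len(np))]
  del <- pileup$del_count[p]

  i1c <- integer(np); i2c <- integer(np); i1s <- character(np)
  insf <- pileup$ins[pileup$ins$pos %in% p, , drop = FALSE]
  if (nrow(insf)) {
    o <- order(insf$pos, -insf$count, insf$seq)
    insf <- insf[o, , drop = FALSE]
    first <- !duplicated(insf$pos)
    top <- insf[first, , drop = FALSE]
    ix <- match(top$pos, p)
    i1c[ix] <- top$count
    i1s[ix] <- top$seq
    rest <- insf[!first, , drop = FALSE]
    if (nrow(rest)) {
      second <- rest[!duplicated(rest$pos), , drop = FALSE]
      i2c[match(second$pos, p)] <- second$count
    }
  }

  m1 <- pmax(m1b, del, i1c)
  achievers <- (m1b == m1) + (pmax(m2b, 0L) == m1) + (del == m1) +
    (i1c == m1) + (i2c == m1)
  called <- (m1 / cov[p]) > frac & achievers == 1L & m1 > 0L
  if (!any(called)) return(empty)

  cp <- p[called]
  m1c <- m1[called]
  covc <- cov[p][called]
  type <- ifelse(m1b[called] == m1c, "SNV",
                 ifelse(del[called] == m1c, "DEL", "INS"))
  refb <- substring(pileup$ref_sequence, cp, cp)
  calls <- data.frame(
    pos = cp, type = type,
    ref_allele = ifelse(type == "INS", "", refb),
    alt_allele = ifelse(type == "SNV", BASES[b1[called]],
                        ifelse(type == "INS", i1s[called], "")),
    coverage = covc,
    alt_fraction = m1c / covc,
    pass_mode = mode, stringsAsFactors = FALSE)
  calls <- merge_adjacent_indels(calls, pileup$ref_sequence)
  difference_table(calls, isolate, pileup$genome_name)
}

# Left-align an insertion event (anchored after `pos`) to its canonical
# representation: while the inserted string ends with the reference base at
# the anchor, the event can slide one base left.  Used by both the caller and
# the synthetic-truth recorder so representations always agree.
normalize_ins <- function(ref_seq, pos, seq) {
  L <- nchar(seq)
  while (pos >= 2L && substr(ref_seq, pos, pos) == substr(seq, L, L)) {
    seq <- paste0(substr(ref_seq, pos, pos), substr(seq, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, seq = seq)
}

# Left-align a deletion of ref_seq[pos .. pos+len-1].
normalize_del <- function(ref_seq, pos, len) {
  while (pos >= 2L &&
         substr(ref_seq, pos - 1L, pos - 1L) ==
           substr(ref_seq, pos + len - 1L, pos + len - 1L)) {
    pos <- pos - 1L
  }
  pos
}

# Merge runs of adjacent single-base (or already multi-base) DEL calls, and
# INS calls on consecutive anchors, into one event each: a 2 bp insertion
# split by the aligner over two anchors is one biological insertion.
merge_adjacent_indels <- function(calls, ref_seq) {
  out <- calls[calls$type == "SNV", , drop = FALSE]
  for (tp in c("DEL", "INS")) {
    cc <- calls[calls$type == tp, , drop = FALSE]
    if (nrow(cc) == 0L) next
    cc <- cc[order(cc$pos), , drop = FALSE]
    # insertion fragments of one event can anchor a few bases apart when the
    # inserted sequence matches adjacent reference bases; group nearby
    # anchors and let the contiguity reconstruction below decide
    grp <- if (nrow(cc) == 1L) 1L
    else if (tp == "INS") cumsum(c(1L, diff(cc$pos) > 5L))
    else cumsum(c(1L, cc$pos[-1L] !=
                    cc$pos[-nrow(cc)] + nchar(cc$ref_allele[-nrow(cc)])))
    merged <- lapply(split(cc, grp), function(g) {
      if (nrow(g) == 1L) return(g)
      if (tp == "DEL") {
        return(data.frame(
          pos = g$pos[1L], type = tp,
          ref_allele = paste(g$ref_allele, collapse = ""), alt_allele = "",
          coverage = min(g$coverage), alt_fraction = min(g$alt_fraction),
          pass_mode = g$pass_mode[1L], stringsAsFactors = FALSE))
      }
      # insertions on consecutive anchors p..q interleave reference bases:
      # the child segment after ref[p] reads S_p r_{p+1} S_{p+1} ... S_q.
      # They form one contiguous insertion after ref[q] iff that segment
      # starts with ref[p+1..q]; otherwise keep the calls separate.
      p <- g$pos[1L]
      q <- g$pos[nrow(g)]
      gaps <- substring(ref_seq, g$pos[-nrow(g)] + 1L, g$pos[-1L])
      child_seg <- paste0(paste0(g$alt_allele[-nrow(g)], gaps,
                                 collapse = ""), g$alt_allele[nrow(g)])
      ref_seg <- substr(ref_seq, p + 1L, q)
      if (startsWith(child_seg, ref_seg)) {
        data.frame(
          pos = q, type = tp, ref_allele = "",
          alt_allele = substring(child_seg, nchar(ref_seg) + 1L),
          coverage = min(g$coverage), alt_fraction = min(g$alt_fraction),
          pass_mode = g$pass_mode[1L], stringsAsFactors = FALSE)
      } else g
    })
    merged <- do.call(rbind, merged)
    for (i in seq_len(nrow(merged))) {
      if (tp == "INS") {
        nz <- normalize_ins(ref_seq, merged$pos[i], merged$alt_allele[i])
        merged$pos[i] <- nz$pos
        merged$alt_allele[i] <- nz$seq
      } else {
        len <- nchar(merged$ref_allele[i])
        p <- normalize_del(ref_seq, merged$pos[i], len)
        merged$pos[i] <- p
        merged$ref_allele[i] <- substr(ref_seq, p, p + len - 1L)
      }
    }
    out <- rbind(out, merged)
  }
  rownames(out) <- NULL
  out
}

#' Merge the strict and relaxed calling passes
#'
#' Union of the two tables; where both passes call at one (position, type),
#' the strict call wins. Every relaxed call must lie inside the flagged
#' regions.
#'
#' @param strict_table,relaxed_table [difference_table()]s from the two
#'   passes.
#' @param regions the flagged regions the relaxed pass was restricted to.
#' @return A combined [difference_table()] with `pass_mode` recorded per
#'   call.
#' @export
merge_passes <- function(strict_table, relaxed_table, regions) {
  stopifnot(inherits(strict_table, "difference_table"),
            inherits(relaxed_table, "difference_table"))
  if (attr(strict_table, "genome_name") != attr(relaxed_table, "genome_name"))
    stop("difference tables refer to different genomes")
  if (nrow(relaxed_table) &&
      !all(in_regions(relaxed_table$pos, regions)))
    stop("relaxed call outside the flagged regions")
  sk <- paste(strict_table$pos, strict_table$type)
  rk <- paste(relaxed_table$pos, relaxed_table$type)
  extra <- as.data.frame(relaxed_table)[!(rk %in% sk), , drop = FALSE]
  difference_table(rbind(as.data.frame(strict_table), extra),
                   isolate = attr(strict_table, "isolate"),
                   genome_name = attr(strict_table, "genome_name"))
}
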