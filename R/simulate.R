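#' Generate a random mediator genome
#'
#' I.i.d. bases at a given GC fraction; deterministic per seed.
#'
#' @param length genome length in bases (>= 1000).
#' @param gc_fraction GC content in (0, 1).
#' @param seed RNG seed.
#' @param name sequence name.
#' @return A [reference_genome()].
#' @export
generate_mediator <- function(length, gc_fraction = 0.5, seed = 1L,
                              name = "mediator") {
  if (length < 1000L) stop("genome length must be >= 1000")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be inside (0, 1)")
  seq <- with_seed(seed, {
    p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
           (1 - gc_fraction) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  reference_genome(name, seq)
}

new_truth_set <- function(substitutions = NULL, indels = NULL,
                          deletions = NULL, cassettes = NULL) {
  structure(list(
    substitutions = substitutions %||%
      data.frame(pos = integer(0), ref = character(0), alt = character(0),
                 class = character(0), stringsAsFactors = FALSE),
    indels = indels %||%
      data.frame(pos = integer(0), type = character(0), seq = character(0),
                 stringsAsFactors = FALSE),
    deletions = deletions %||%
      data.frame(start = integer(0), end = integer(0),
                 repeat_len = integer(0), stringsAsFactors = FALSE),
    cassettes = cassettes %||%
      data.frame(start = integer(0), end = integer(0),
                 divergence = numeric(0), stringsAsFactors = FALSE)),
    class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(paste0("<truth_set> %d substitution(s), %d small indel(s), ",
                     "%d large deletion(s), %d cassette(s)\n"),
              nrow(x$substitutions), nrow(x$indels), nrow(x$deletions),
              nrow(x$cassettes)))
  invisible(x)
}

#' Force a direct repeat around a planned deletion
#'
#' Rewrites the genome so that the `repeat_len` bases immediately preceding
#' `del_start` also appear as the last `repeat_len` bases of the deletion
#' interval - the recombination-prone geometry in which deleting the
#' interval leaves one repeat copy behind.
#'
#' @param genome a [reference_genome()].
#' @param del_start,del_end the planned deletion, 1-based inclusive.
#' @param repeat_len repeat length in bases.
#' @return The modified [reference_genome()].
#' @export
plant_direct_repeat <- function(genome, del_start, del_end, repeat_len) {
  stopifnot(inherits(genome, "reference_genome"),
            del_start - repeat_len >= 1L, del_end <= genome$length,
            del_end - del_start + 1L >= repeat_len)
  s <- genome$sequence
  left <- substr(s, del_start - repeat_len, del_start - 1L)
  substr(s, del_end - repeat_len + 1L, del_end) <- left
  reference_genome(genome$name, s)
}

#' Derive a child genome with planted mutations and a truth set
#'
#' Emulates the divergence between the sequenced isolates and the mediator:
#' point substitutions drawn uniformly among the three alternative bases,
#' small insertions/deletions, large deletions, and locally hyper-diverged
#' cassettes mutated i.i.d. at a stated local divergence. Every event is
#' recorded in parent coordinates; events never overlap.
#'
#' @param parent the parent [reference_genome()].
#' @param n_subs number of random substitutions.
#' @param n_small_indels number of random 1-3 bp insertions/deletions.
#' @param indels explicit small indels instead of random ones: data.frame
#'   with `pos` (insertion anchor / first deleted base), `type`
#'   (`INS`/`DEL`) and `seq` (inserted bases, or deleted length as bases for
#'   DEL taken from the parent).
#' @param deletions data.frame of large deletions (`start`, `end`, optional
#'   `repeat_len` metadata).
#' @param cassettes data.frame of hyper-diverged cassettes (`start`, `end`,
#'   `divergence`).
#' @param avoid_pos positions (parent coordinates) that random events must
#'   keep clear of, e.g. the planted events of an earlier derivation.
#' @param seed RNG seed.
#' @param name child genome name.
#' @return List with `genome` (the child [reference_genome()]) and `truth`
#'   (a `truth_set` in parent coordinates).
#' @export
derive_genome <- function(parent, n_subs = 0L, n_small_indels = 0L,
                          indels = NULL, deletions = NULL, cassettes = NULL,
                          avoid_pos = NULL, seed = 1L,
                          name = paste0(parent$name, "_derived")) {
  stopifnot(inherits(parent, "reference_genome"))
  glen <- parent$length
  if (!is.null(deletions) && nrow(deletions) &&
      (any(deletions$start < 1L) || any(deletions$end > glen)))
    stop("deletion outside genome bounds")
  if (!is.null(cassettes) && nrow(cassettes) &&
      (any(cassettes$start < 1L) || any(cassettes$end > glen)))
    stop("cassette outside genome bounds")

  with_seed(seed, {
    blocked <- rep(FALSE, glen)
    margin <- 5L  # keep random events off interval edges and each other
    block <- function(s, e) {
      s <- max(1L, s - margin); e <- min(glen, e + margin)
      blocked[s:e] <<- TRUE
    }
    if (!is.null(deletions)) for (i in seq_len(NROW(deletions)))
      block(deletions$start[i], deletions$end[i])
    if (!is.null(cassettes)) for (i in seq_len(NROW(cassettes)))
      block(cassettes$start[i], cassettes$end[i])
    if (!is.null(avoid_pos)) for (p in avoid_pos) block(p, p)

    # explicit or random small indels
    ind <- data.frame(pos = integer(0), type = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
    if (!is.null(indels) && nrow(indels)) {
      ind <- data.frame(pos = as.integer(indels$pos),
                        type = as.character(indels$type),
                        seq = toupper(as.character(indels$seq)),
                        stringsAsFactors = FALSE)
    } else if (n_small_indels > 0L) {
      for (i in seq_len(n_small_indels)) {
        for (try in 1:1000) {
          p <- sample.int(glen - 10L, 1L) + 5L
          if (!any(blocked[(p - 3L):(p + 3L)])) break
          if (try == 1000) stop("could not place indel without overlap")
        }
        len <- sample.int(3L, 1L)
        if (runif(1) < 0.5) {
          ind <- rbind(ind, data.frame(
            pos = p, type = "INS",
            seq = paste(sample(BASES, len, replace = TRUE), collapse = ""),
            stringsAsFactors = FALSE))
        } else {
          ind <- rbind(ind, data.frame(
            pos = p, type = "DEL",
            seq = substring(parent$sequence, p, p + len - 1L),
            stringsAsFactors = FALSE))
        }
        block(p, p + 3L)
      }
    }
    # record left-aligned canonical representations, as the caller reports
    # (an equivalent representation of the same edited sequence)
    for (i in seq_len(nrow(ind))) {
      if (ind$type[i] == "INS") {
        nz <- normalize_ins(parent$sequence, ind$pos[i], ind$seq[i])
        ind$pos[i] <- nz$pos
        ind$seq[i] <- nz$seq
      } else {
        len <- nchar(ind$seq[i])
        p <- normalize_del(parent$sequence, ind$pos[i], len)
        ind$pos[i] <- p
        ind$seq[i] <- substr(parent$sequence, p, p + len - 1L)
      }
    }
    for (i in seq_len(nrow(ind))) {
      e <- if (ind$type[i] == "DEL") ind$pos[i] + nchar(ind$seq[i]) - 1L
           else ind$pos[i]
      block(ind$pos[i], e)
    }

    # substitutions on unblocked positions
    free <- which(!blocked)
    if (n_subs > length(free)) stop("not enough free positions for substitutions")
    sub_pos <- sort(sample(free, n_subs))
    chars <- strsplit(parent$sequence, "")[[1]]
    subs <- data.frame(pos = integer(0), ref = character(0),
                       alt = character(0), class = character(0),
                       stringsAsFactors = FALSE)
    if (n_subs > 0L) {
      refb <- chars[sub_pos]
      altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), "")
      subs <- data.frame(pos = sub_pos, ref = refb, alt = unname(altb),
                         class = "background", stringsAsFactors = FALSE)
      chars[sub_pos] <- subs$alt
    }

    # hyper-diverged cassettes: i.i.d. substitutions at the local divergence
    cas <- new_truth_set()$cassettes
    if (!is.null(cassettes) && nrow(cassettes)) {
      for (i in seq_len(nrow(cassettes))) {
        s <- cassettes$start[i]; e <- cassettes$end[i]
        dv <- cassettes$divergence[i]
        idx <- s:e
        mut <- idx[runif(length(idx)) < dv]
        if (length(mut)) {
          refb <- chars[mut]
          altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1L), "")
          subs <- rbind(subs, data.frame(pos = mut, ref = refb,
                                         alt = unname(altb),
                                         class = "cassette",
                                         stringsAsFactors = FALSE))
          chars[mut] <- unname(altb)
        }
      }
      cas <- data.frame(start = as.integer(cassettes$start),
                        end = as.integer(cassettes$end),
                        divergence = cassettes$divergence,
                        stringsAsFactors = FALSE)
    }

    # assemble child sequence: apply indels and large deletions right-to-left
    dels <- new_truth_set()$deletions
    if (!is.null(deletions) && nrow(deletions)) {
      dels <- data.frame(start = as.integer(deletions$start),
                         end = as.integer(deletions$end),
                         repeat_len = if ("repeat_len" %in% names(deletions))
                           as.integer(deletions$repeat_len) else 0L,
                         stringsAsFactors = FALSE)
    }
    edits <- rbind(
      if (nrow(dels)) data.frame(pos = dels$start, end = dels$end,
                                 type = "DEL", seq = "",
                                 stringsAsFactors = FALSE),
      if (nrow(ind)) data.frame(
        pos = ind$pos,
        end = ifelse(ind$type == "DEL", ind$pos + nchar(ind$seq) - 1L,
                     ind$pos),
        type = ind$type, seq = ind$seq, stringsAsFactors = FALSE))
    if (!is.null(edits) && nrow(edits)) {
      edits <- edits[order(-edits$pos), , drop = FALSE]
      pieces <- chars
      for (i in seq_len(nrow(edits))) {
        if (edits$type[i] == "DEL") {
          pieces <- pieces[-(edits$pos[i]:edits$end[i])]
        } else {
          at <- edits$pos[i]  # insert after this parent position
          pieces <- append(pieces, strsplit(edits$seq[i], "")[[1]], after = at)
        }
      }
      child_seq <- paste(pieces, collapse = "")
    } else {
      child_seq <- paste(chars, collapse = "")
    }

    sub_order <- order(subs$pos)
    truth <- new_truth_set(
      substitutions = subs[sub_order, , drop = FALSE],
      indels = ind[order(ind$pos), , drop = FALSE],
      deletions = dels, cassettes = cas)
    list(genome = reference_genome(name, child_seq), truth = truth)
  })
}

#' Map child-genome coordinates back to parent coordinates
#'
#' Inverts the coordinate shifts introduced by a derivation's insertions and
#' deletions (substitutions do not shift coordinates). Positions falling
#' inside inserted sequence map to `NA`.
#'
#' @param truth the `truth_set` of the derivation.
#' @param pos integer positions in the child genome.
#' @return Integer positions in the parent genome (NA inside insertions).
#' @export
lift_to_parent <- function(truth, pos) {
  stopifnot(inherits(truth, "truth_set"))
  ev <- rbind(
    if (nrow(truth$deletions))
      data.frame(start = truth$deletions$start,
                 len = truth$deletions$end - truth$deletions$start + 1L,
                 type = "DEL", stringsAsFactors = FALSE),
    if (nrow(truth$indels))
      data.frame(start = truth$indels$pos,
                 len = nchar(truth$indels$seq),
                 type = truth$indels$type, stringsAsFactors = FALSE))
  out <- as.integer(pos)
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  ev <- ev[order(ev$start), , drop = FALSE]
  # walk events in parent order, translating child -> parent
  res <- integer(length(pos))
  for (q in seq_along(pos)) {
    p <- pos[q]          # child coordinate
    shift <- 0L          # parent - child so far
    val <- NA_integer_
    ok <- TRUE
    for (i in seq_len(nrow(ev))) {
      if (ev$type[i] == "DEL") {
        if (p + shift >= ev$start[i]) shift <- shift + ev$len[i] else break
      } else {
        ins_child_start <- ev$start[i] - shift + 1L
        if (p >= ins_child_start && p < ins_child_start + ev$len[i]) {
          ok <- FALSE; break
        }
        if (p >= ins_child_start + ev$len[i]) shift <- shift - ev$len[i]
        else break
      }
    }
    res[q] <- if (ok) p + shift else NA_integer_
  }
  res
}

#' Map parent-genome coordinates to child coordinates
#'
#' Forward companion of [lift_to_parent()]: positions deleted in the child
#' map to `NA`.
#'
#' @param truth the `truth_set` of the derivation.
#' @param pos integer positions in the parent genome.
#' @return Integer positions in the child genome (NA inside deletions).
#' @export
parent_to_child <- function(truth, pos) {
  stopifnot(inherits(truth, "truth_set"))
  ev <- rbind(
    if (nrow(truth$deletions))
      data.frame(start = truth$deletions$start,
                 end = truth$deletions$end,
                 len = truth$deletions$end - truth$deletions$start + 1L,
                 type = "DEL", stringsAsFactors = FALSE),
    if (nrow(truth$indels))
      data.frame(start = truth$indels$pos,
                 end = ifelse(truth$indels$type == "DEL",
                              truth$indels$pos + nchar(truth$indels$seq) - 1L,
                              truth$indels$pos),
                 len = nchar(truth$indels$seq),
                 type = truth$indels$type, stringsAsFactors = FALSE))
  out <- as.integer(pos)
  if (is.null(ev) || nrow(ev) == 0L) return(out)
  ev <- ev[order(ev$start), , drop = FALSE]
  res <- integer(length(pos))
  for (q in seq_along(pos)) {
    p <- as.integer(pos[q])
    shift <- 0L  # child - parent so far
    val <- p
    for (i in seq_len(nrow(ev))) {
      if (ev$start[i] > p && !(ev$type[i] == "INS" && ev$start[i] == p)) break
      if (ev$type[i] == "DEL") {
        if (p >= ev$start[i] && p <= ev$end[i]) { val <- NA_integer_; break }
        if (p > ev$end[i]) shift <- shift - ev$len[i]
      } else if (ev$start[i] < p) {
        shift <- shift + ev$len[i]
      }
    }
    res[q] <- if (is.na(val)) NA_integer_ else p + shift
  }
  res
}

#' Simulate unpaired short reads from a genome
#'
#' Read count is `round(mean_coverage * genome_length / read_len)`; start
#' positions and strands are uniform; substitution errors are i.i.d. at
#' `error_rate`. FASTQ-style qualities are emitted as constant Q30 (the
#' aligner does not use them). Deterministic per seed.
#'
#' @param genome a [reference_genome()].
#' @param read_len read length in bases.
#' @param mean_coverage target mean depth.
#' @param error_rate per-base substitution error rate.
#' @param seed RNG seed.
#' @param id_prefix read-id prefix.
#' @return A [read_set()].
#' @export
simulate_reads <- function(genome, read_len = 33L, mean_coverage = 50,
                           error_rate = 0.002, seed = 1L,
                           id_prefix = "read") {
  stopifnot(inherits(genome, "reference_genome"))
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  if (read_len > genome$length) stop("read_len exceeds genome length")
  glen <- genome$length
  n <- as.integer(round(mean_coverage * glen / read_len))
  with_seed(seed, {
    starts <- sample.int(glen - read_len + 1L, n, replace = TRUE)
    seqs <- substring(genome$sequence, starts, starts + read_len - 1L)
    nerr <- rbinom(n, read_len, error_rate)
    which_err <- which(nerr > 0L)
    for (i in which_err) {
      cc <- strsplit(seqs[i], "")[[1]]
      at <- sample.int(read_len, nerr[i])
      cc[at] <- vapply(cc[at], function(b) {
        if (b %in% BASES) sample(setdiff(BASES, b), 1L) else b
      }, "")
      seqs[i] <- paste(cc, collapse = "")
    }
    minus <- runif(n) < 0.5
    if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])
    qual <- strrep(rawToChar(as.raw(63L)), read_len)  # Q30, Phred+33
    read_set(sprintf("%s_%07d", id_prefix, seq_len(n)), seqs,
             rep(qual, n))
  })
}

#' Build the default synthetic study scenario
#'
#' One call that reproduces, at desk scale, the study design the pipeline
#' targets: a mediator genome; a WT isolate genome at background divergence
#' from it (substitutions, plus optional shared large deletions and
#' hyper-diverged cassettes, all inherited by the mutant); a mutant genome
#' derived from the WT carrying a handful of additional substitutions and a
#' small insertion; and uniform short-read sets for both isolates.
#'
#' Defaults emulate the study conditions scaled to a 100 kb mediator:
#' 750 shared substitutions (0.75% divergence), 19 mutant-unique
#' substitutions plus one 2 bp insertion, 33 bp reads at 50x coverage with a
#' 0.2% per-base error rate.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param genome_length mediator length (bases).
#' @param gc_fraction mediator GC content.
#' @param n_shared_subs substitutions separating WT from the mediator.
#' @param shared_deletions,shared_cassettes optional data.frames passed to
#'   [derive_genome()] for the WT (inherited by the mutant).
#' @param n_unique_subs mutant-only substitutions.
#' @param unique_insertion mutant-only inserted sequence (`NULL` for none);
#'   anchored at a random position.
#' @param read_len,coverage,error_rate read-simulation settings (both
#'   isolates).
#' @return List with `mediator`, `wt`, `mutant` (genomes), `wt_truth`,
#'   `mutant_truth` (truth sets; WT truth in mediator coordinates, mutant
#'   truth in WT coordinates), `wt_reads`, `mutant_reads`.
#' @export
mediator_scenario <- function(seed = 42L, genome_length = 100000L,
                              gc_fraction = 0.5, n_shared_subs = 750L,
                              shared_deletions = NULL,
                              shared_cassettes = NULL,
                              n_unique_subs = 19L,
                              unique_insertion = "GT",
                              read_len = 33L, coverage = 50,
                              error_rate = 0.002) {
  seed <- as.integer(seed) %% 100000L
  mediator <- generate_mediator(genome_length, gc_fraction,
                                seed = seed * 7L + 1L, name = "mediator")
  wt_d <- derive_genome(mediator, n_subs = n_shared_subs,
                        deletions = shared_deletions,
                        cassettes = shared_cassettes,
                        seed = seed * 7L + 2L, name = "wt")
  indels <- NULL
  if (!is.null(unique_insertion)) {
    anchor <- with_seed(seed * 7L + 3L,
                        sample.int(wt_d$genome$length - 1000L, 1L) + 500L)
    indels <- data.frame(pos = anchor, type = "INS", seq = unique_insertion,
                         stringsAsFactors = FALSE)
  }
  mut_d <- derive_genome(wt_d$genome, n_subs = n_unique_subs,
                         indels = indels,
                         avoid_pos = stats::na.omit(
                           parent_to_child(wt_d$truth,
                                           wt_d$truth$substitutions$pos)),
                         seed = seed * 7L + 4L, name = "mutant")
  wt_reads <- simulate_reads(wt_d$genome, read_len, coverage, error_rate,
                             seed = seed * 7L + 5L, id_prefix = "wt")
  mut_reads <- simulate_reads(mut_d$genome, read_len, coverage, error_rate,
                              seed = seed * 7L + 6L, id_prefix = "mut")
  list(mediator = mediator, wt = wt_d$genome, mutant = mut_d$genome,
       wt_truth = wt_d$truth, mutant_truth = mut_d$truth,
       wt_reads = wt_reads, mutant_reads = mut_reads)
}
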