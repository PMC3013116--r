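test_that("pileups tally bases, deletions and insertions per reference position", {
  g <- generate_mediator(1000, 0.5, seed = 3)
  # one exact read covering 33 positions
  pil <- build_pileup(exact_alignment(g, 11, 33), g)
  expect_equal(sum(pil$coverage), 33L)
  expect_true(all(pil$coverage[11:43] == 1L))
  col <- pileup_column(pil, 20)
  expect_equal(unname(col$base_counts[col$ref_base]), 1L)
  expect_equal(col$coverage, 1L)

  # a second read with a C-vs-ref mismatch at position 20
  a1 <- exact_alignment(g, 11, 33, "r1")
  a2 <- exact_alignment(g, 11, 33, "r2")
  refb <- substr(g$sequence, 20, 20)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  substr(a2$read_aln, 10, 10) <- altb  # position 20 is column 10
  a2$n_mismatches <- 1L
  pil2 <- build_pileup(rbind(a1, a2), g)
  col2 <- pileup_column(pil2, 20)
  expect_equal(unname(col2$base_counts[refb]), 1L)
  expect_equal(unname(col2$base_counts[altb]), 1L)
  expect_equal(col2$coverage, 2L)

  # a read with a gap column (deletion) at position 30
  a3 <- exact_alignment(g, 11, 33, "r3")
  substr(a3$read_aln, 20, 20) <- "-"  # ref position 30
  a3$n_gap_columns <- 1L
  pil3 <- build_pileup(a3, g)
  expect_equal(pileup_column(pil3, 30)$del_count, 1L)
  expect_equal(pileup_column(pil3, 30)$coverage, 1L)

  # an insertion anchors to the preceding reference position
  a4 <- exact_alignment(g, 11, 33, "r4")
  a4$ref_aln <- paste0(substr(a4$ref_aln, 1, 10), "--", substring(a4$ref_aln, 11))
  a4$read_aln <- paste0(substr(a4$read_aln, 1, 10), "GT", substring(a4$read_aln, 11))
  pil4 <- build_pileup(a4, g)
  expect_equal(pileup_column(pil4, 20)$ins_events, c(GT = 1L))

  # out-of-bounds alignment is an integrity error
  bad <- exact_alignment(g, 990, 33)
  expect_error(build_pileup(bad, g), "bounds")
})

test_that("depth totals equal the aligned match-column totals", {
  g <- generate_mediator(3000, 0.5, seed = 14)
  reads <- simulate_reads(derive_genome(g, n_subs = 30, seed = 15)$genome,
                          33, 20, 0.005, seed = 16)
  aln <- align_readset(reads, g, aligner_params())
  pil <- build_pileup(aln, g)
  track <- coverage_profile(pil)
  a <- aln$alignments
  ncols_match <- sum(a$aligned_len) -
    sum(vapply(seq_len(nrow(a)), function(i) {
      sum(strsplit(a$ref_aln[i], "")[[1]] == "-") +
        sum(strsplit(a$read_aln[i], "")[[1]] == "-")
    }, 0L))
  expect_equal(sum(track$depth), ncols_match)
})

test_that("the consensus rule enforces coverage and a strict alt-fraction inequality", {
  g <- generate_mediator(1000, 0.5, seed = 23)
  refb <- substr(g$sequence, 20, 20)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  stack <- function(n_alt, n_ref) {
    alt <- exact_alignment(g, 11, 33, "a")
    substr(alt$read_aln, 10, 10) <- altb
    rows <- alt[rep(1, n_alt), ]
    if (n_ref > 0) rows <- rbind(rows, exact_alignment(g, 11, 33, "r")[rep(1, n_ref), ])
    build_pileup(rows, g)
  }
  # coverage 10, alt 7: 0.70 > 0.60 -> called
  t1 <- call_differences(stack(7, 3))
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$alt_allele, altb)
  expect_equal(t1$coverage, 10L)
  # coverage 4, alt 4: below the coverage floor -> no call
  expect_equal(nrow(call_differences(stack(4, 0))), 0L)
  # coverage 10, alt 6: 0.60 is not > 0.60 -> no call
  expect_equal(nrow(call_differences(stack(6, 4))), 0L)
  # relaxed thresholds inside a region: coverage 4, alt 3 (0.75 > 0.50)
  reg <- data.frame(start = 1L, end = 1000L)
  t2 <- call_differences(stack(3, 1), mode = "relaxed", regions = reg)
  expect_equal(nrow(t2), 1L)
  expect_equal(t2$pass_mode, "relaxed")
  # relaxed mode requires regions
  expect_error(call_differences(stack(3, 1), mode = "relaxed"), "regions")
})

test_that("tied top events at a column yield no call", {
  g <- generate_mediator(1000, 0.5, seed = 24)
  refb <- substr(g$sequence, 20, 20)
  alts <- setdiff(c("A", "C", "G", "T"), refb)
  one <- function(b) {
    a <- exact_alignment(g, 11, 33)
    substr(a$read_aln, 10, 10) <- b
    a
  }
  rows <- rbind(one(alts[1])[rep(1, 5), ], one(alts[2])[rep(1, 5), ])
  expect_equal(nrow(call_differences(build_pileup(rows, g))), 0L)
})

test_that("a planted 2 bp insertion is reported as one merged INS", {
  med <- generate_mediator(4000, 0.5, seed = 33)
  mut <- derive_genome(med, indels = data.frame(pos = 2000L, type = "INS",
                                                seq = "GT"),
                       seed = 34, name = "mut")
  reads <- simulate_reads(mut$genome, 33, 50, 0, seed = 35)
  aln <- align_readset(reads, med, aligner_params())
  tab <- call_differences(build_pileup(aln, med))
  ins <- tab[tab$type == "INS", ]
  expect_equal(nrow(ins), 1L)
  # the call matches the (left-normalised) planted event
  expect_equal(ins$pos, mut$truth$indels$pos)
  expect_equal(ins$alt_allele, mut$truth$indels$seq)
  expect_equal(nchar(ins$alt_allele), 2L)
})

test_that("no call falls below its mode's thresholds and calling is deterministic", {
  g <- generate_mediator(4000, 0.5, seed = 43)
  reads <- simulate_reads(derive_genome(g, n_subs = 40, seed = 44)$genome,
                          33, 25, 0.005, seed = 45)
  aln <- align_readset(reads, g, aligner_params())
  pil <- build_pileup(aln, g)
  tab <- call_differences(pil)
  expect_true(all(tab$coverage >= 5L))
  expect_true(all(tab$alt_fraction > 0.60))
  expect_identical(as.data.frame(call_differences(pil)), as.data.frame(tab))
})

test_that("sequencing errors alone never reach the consensus rule", {
  # reads drawn from the mediator itself: every disagreement is a sequencing
  # error; at 0.2% error no column may pass the strict rule
  g <- generate_mediator(20000, 0.5, seed = 53)
  reads <- simulate_reads(g, 33, 30, 0.002, seed = 54)
  aln <- align_readset(reads, g, aligner_params())
  tab <- call_differences(build_pileup(aln, g))
  expect_equal(nrow(tab), 0L)
})

test_that("pass merging keeps strict precedence and rejects out-of-region calls", {
  mk <- function(pos, mode, alt = "C") difference_table(
    data.frame(pos = pos, type = "SNV", ref_allele = "A", alt_allele = alt,
               coverage = 10L, alt_fraction = 0.9, pass_mode = mode,
               stringsAsFactors = FALSE), "iso", "g")
  reg <- data.frame(start = 100L, end = 200L)
  strict <- mk(c(50L, 150L), "strict")
  relaxed <- mk(c(150L, 160L), "relaxed")
  merged <- merge_passes(strict, relaxed, reg)
  expect_equal(merged$pos, c(50L, 150L, 160L))
  expect_equal(merged$pass_mode[merged$pos == 150L], "strict")

  disjoint <- merge_passes(mk(50L, "strict"), mk(160L, "relaxed"), reg)
  expect_equal(nrow(disjoint), 2L)

  expect_error(merge_passes(strict, mk(500L, "relaxed"), reg),
               "outside the flagged regions")
})
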