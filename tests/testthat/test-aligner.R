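test_that("seed index maps words to all their start positions and excludes N", {
  g <- reference_genome("g", "ACGTACGT")
  idx <- build_seed_index(g, 4)
  expect_equal(seed_lookup(idx, "ACGT"), c(1L, 5L))
  expect_equal(seed_lookup(idx, "CGTA"), 2L)
  expect_length(seed_lookup(idx, "TTTT"), 0L)

  gn <- reference_genome("n", "ACGNACGTACGT")
  idx2 <- build_seed_index(gn, 4)
  expect_length(seed_lookup(idx2, "ACGN"), 0L)  # N-containing words excluded
  expect_length(seed_lookup(idx2, "NACG"), 0L)
  expect_equal(seed_lookup(idx2, "ACGT"), c(5L, 9L))

  expect_error(build_seed_index(reference_genome("s", "ACG"), 4),
               "shorter than word_size")
})

test_that("exact substrings align with zero errors on the correct strand", {
  g <- generate_mediator(2000, 0.5, seed = 7)
  idx <- build_seed_index(g, 11)
  p <- aligner_params(min_align_len = 27)
  rd <- substr(g$sequence, 101, 133)
  a <- align_read(rd, idx, g, p)
  expect_equal(a$ref_start, 101L)
  expect_equal(a$ref_end, 133L)
  expect_equal(a$strand, "+")
  expect_equal(a$n_mismatches + a$n_gap_columns, 0L)

  b <- align_read(rc(rd), idx, g, p)
  expect_equal(b$ref_start, 101L)
  expect_equal(b$strand, "-")
  expect_equal(b$n_mismatches, 0L)
})

test_that("reads beyond the error cap are unaligned", {
  g <- generate_mediator(2000, 0.5, seed = 8)
  idx <- build_seed_index(g, 11)
  rd <- substr(g$sequence, 501, 533)
  cc <- strsplit(rd, "")[[1]]
  # 7 substitutions placed so that every window of >= 30 columns holds all of
  # them, while the first 11 bases stay intact as a seed
  at <- seq(12L, by = 2L, length.out = 7L)
  for (i in at) cc[i] <- setdiff(c("A", "C", "G", "T"), cc[i])[1]
  rd7 <- paste(cc, collapse = "")
  expect_null(align_read(rd7, idx, g, aligner_params(min_align_len = 30)))
})

test_that("reported alignments never violate max_errors or min_align_len", {
  g <- generate_mediator(3000, 0.5, seed = 21)
  reads <- simulate_reads(derive_genome(g, n_subs = 40, seed = 22)$genome,
                          33, 15, 0.01, seed = 23)
  aln <- align_readset(reads, g, aligner_params())
  a <- aln$alignments
  expect_true(all(a$n_mismatches + a$n_gap_columns <= 6L))
  expect_true(all(a$aligned_len >= aln$min_align_len))
  expect_equal(aln$min_align_len, 27L)  # ceiling(0.8 * 33)
})

test_that("aligning reverse complements flips strands but not intervals", {
  g <- generate_mediator(2000, 0.5, seed = 31)
  idx <- build_seed_index(g, 11)
  p <- aligner_params(min_align_len = 27)
  set.seed(32)
  for (i in 1:40) {
    st <- sample.int(1960, 1)
    rd <- substr(g$sequence, st, st + 32)
    a <- align_read(rd, idx, g, p)
    b <- align_read(rc(rd), idx, g, p)
    expect_false(is.null(a))
    expect_equal(b$ref_start, a$ref_start)
    expect_equal(b$ref_end, a$ref_end)
    expect_true(a$strand != b$strand)
  }
})

test_that("best placements match an exhaustive dynamic-programming scan", {
  set.seed(77)
  n_checked <- 0L
  for (i in 1:60) {
    g <- generate_mediator(1000 + sample.int(1000, 1), 0.5, seed = 1000 + i)
    idx <- build_seed_index(g, 11)
    p <- aligner_params(min_align_len = 27)
    st <- sample.int(g$length - 50, 1)
    len <- sample(33:50, 1)
    rd <- substr(g$sequence, st, st + len - 1)
    ne <- sample(0:3, 1)
    cc <- strsplit(rd, "")[[1]]
    if (ne > 0) {
      at <- sample(len, ne)
      for (j in at) cc[j] <- setdiff(c("A", "C", "G", "T"), cc[j])[1]
    }
    rd <- paste(cc, collapse = "")
    if (runif(1) < 0.5) rd <- rc(rd)
    a <- align_read(rd, idx, g, p)
    if (is.null(a)) next  # ambiguous or seed miss: documented outcomes
    o <- oracle_align(rd, g, p)
    expect_true(o$aligned)
    expect_equal(a$n_mismatches + a$n_gap_columns, o$errors)
    expect_equal(a$aligned_len, o$aligned_len)
    expect_equal(a$ref_start, o$ref_start)
    expect_equal(a$strand, o$strand)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 40L)
})

test_that("repeat-ambiguous reads are discarded, not misplaced", {
  block <- generate_mediator(1000, 0.5, seed = 41)$sequence
  seg <- substr(block, 1, 60)
  g <- reference_genome("dup", paste0(block, seg, substr(generate_mediator(
    1000, 0.5, seed = 42)$sequence, 1, 400)))
  idx <- build_seed_index(g, 11)
  rd <- substr(seg, 10, 42)
  expect_null(align_read(rd, idx, g, aligner_params(min_align_len = 27)))
  rs <- read_set("amb", rd)
  out <- align_readset(rs, g, aligner_params(), index = idx)
  expect_equal(out$ambiguous, "amb")
})

test_that("align_readset handles foreign reads, duplicates, and empty input", {
  g <- generate_mediator(2000, 0.5, seed = 51)
  foreign <- generate_mediator(2000, 0.5, seed = 52)
  fr <- simulate_reads(foreign, 33, 2, 0, seed = 53)
  out <- align_readset(fr, g, aligner_params())
  # chance 11-mer seeds can rescue the odd foreign read within the error
  # budget; the overwhelming majority must stay unaligned
  expect_lt(out$counts$aligned / fr$n_reads, 0.05)
  expect_equal(length(out$unaligned) + length(out$ambiguous) +
                 out$counts$aligned, fr$n_reads)

  rd <- substr(g$sequence, 101, 133)
  dup <- read_set(c("d", "d"), c(rd, rd))
  out2 <- align_readset(dup, g, aligner_params())
  expect_equal(out2$alignments$read_id, c("d", "d"))

  expect_error(align_readset(read_set(character(0), character(0)), g),
               "empty read set")
})

test_that("BLAST tabular import reconstructs ungapped alignments for SNV calling", {
  g <- generate_mediator(2000, 0.5, seed = 61)
  rd <- substr(g$sequence, 301, 333)
  rd <- mutate_at(rd, 17, setdiff(c("A", "C", "G", "T"), substr(rd, 17, 17))[1])
  reads <- read_set(c("q1", "q2"), c(rd, rc(rd)))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    sprintf("q1\tg\t97.0\t33\t1\t0\t1\t33\t301\t333\t1e-10\t60"),
    sprintf("q2\tg\t97.0\t33\t1\t0\t1\t33\t333\t301\t1e-10\t60"),
    sprintf("q1\tg\t97.0\t33\t0\t1\t1\t33\t501\t534\t1e-9\t55")), f)
  expect_message(aln <- read_blast_tab(f, reads, g), "SNV calling only")
  a <- aln$alignments
  expect_equal(nrow(a), 2L)  # gapped row skipped
  expect_equal(a$n_mismatches, c(1L, 1L))
  expect_equal(a$ref_start, c(301L, 301L))
  expect_equal(a$strand, c("+", "-"))
  expect_equal(a$read_aln[1], a$read_aln[2])
})

test_that("SAM export emits mapped and unmapped records with sound CIGARs", {
  g <- generate_mediator(2000, 0.5, seed = 71)
  reads <- read_set(c("m", "u"),
                    c(substr(g$sequence, 101, 133), strrep("ACGTT", 7)))
  aln <- align_readset(reads, g, aligner_params())
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, reads, g, f)
  lines <- readLines(f)
  body <- grep("^@", lines, value = TRUE, invert = TRUE)
  flags <- as.integer(vapply(strsplit(body, "\t"), `[[`, "", 2))
  expect_true(any(flags == 4L))
  m <- strsplit(body[flags != 4L][1], "\t")[[1]]
  expect_equal(m[6], "33M")
  expect_equal(as.integer(m[4]), 101L)
})
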