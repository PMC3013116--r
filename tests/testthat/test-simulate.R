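test_that("mediator generation is seed-deterministic with the requested GC", {
  g1 <- generate_mediator(10000, 0.5, seed = 42)
  g2 <- generate_mediator(10000, 0.5, seed = 42)
  expect_identical(g1$sequence, g2$sequence)
  gc <- mean(strsplit(g1$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.03)
  g3 <- generate_mediator(10000, 0.3, seed = 1)
  gc3 <- mean(strsplit(g3$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc3 - 0.3), 0.03)
  expect_error(generate_mediator(10000, 0, seed = 1), "gc_fraction")
  expect_error(generate_mediator(500, 0.5, seed = 1), ">= 1000")
})

test_that("derivation plants exactly the requested events and records truth", {
  med <- generate_mediator(10000, 0.5, seed = 2)
  same <- derive_genome(med, n_subs = 0, seed = 3)
  expect_identical(same$genome$sequence, med$sequence)
  expect_equal(nrow(same$truth$substitutions), 0L)

  d <- derive_genome(med, n_subs = 19, seed = 4)
  tr <- d$truth$substitutions
  expect_equal(nrow(tr), 19L)
  expect_identical(nchar(d$genome$sequence), med$length)
  # truth records the parent base and the planted alternative
  expect_identical(substring(med$sequence, tr$pos, tr$pos), tr$ref)
  expect_identical(substring(d$genome$sequence, tr$pos, tr$pos), tr$alt)
  expect_true(all(tr$ref != tr$alt))

  # a deletion with engineered flanking-repeat metadata
  med2 <- plant_direct_repeat(med, 5001L, 5042L, 10L)
  d2 <- derive_genome(med2, deletions = data.frame(start = 5001L, end = 5042L,
                                                   repeat_len = 10L),
                      seed = 5)
  expect_equal(d2$truth$deletions$repeat_len, 10L)
  expect_equal(nchar(d2$genome$sequence), med$length - 42L)

  # cassette divergence lands near its target rate
  d3 <- derive_genome(med, cassettes = data.frame(start = 2001L, end = 4000L,
                                                  divergence = 0.08),
                      seed = 6)
  ncas <- sum(d3$truth$substitutions$class == "cassette")
  expect_gt(ncas, 2000 * 0.08 - 3 * sqrt(2000 * 0.08 * 0.92))
  expect_lt(ncas, 2000 * 0.08 + 3 * sqrt(2000 * 0.08 * 0.92))
})

test_that("read simulation honours the count formula and error model", {
  med <- generate_mediator(100000, 0.5, seed = 7)
  rs <- simulate_reads(med, 33, 50, 0.002, seed = 8)
  expect_equal(rs$n_reads, 151515L)  # round(50 * 100000 / 33)
  expect_equal(rs$modal_length, 33L)
  expect_error(simulate_reads(med, 33, 0, 0.002, seed = 1), "positive")

  # error rate 0: every read is an exact (possibly reverse-complemented)
  # substring of the genome
  small <- generate_mediator(5000, 0.5, seed = 9)
  clean <- simulate_reads(small, 33, 2, 0, seed = 10)
  hits <- vapply(clean$sequence[1:50], function(s) {
    grepl(s, small$sequence, fixed = TRUE) ||
      grepl(rc(s), small$sequence, fixed = TRUE)
  }, TRUE)
  expect_true(all(hits))

  # empirical error rate over >= 1e6 simulated bases: a homopolymer genome
  # makes planted errors directly countable on either strand
  homo <- reference_genome("homo", strrep("A", 10000))
  noisy <- simulate_reads(homo, 50, 100, 0.002, seed = 11)
  nbases <- noisy$total_bases
  expect_gte(nbases, 1e6)
  # a plus-strand read is A's except errors, a minus-strand read T's
  nerr <- sum(vapply(noisy$sequence, function(s) {
    cc <- strsplit(s, "")[[1]]
    min(sum(cc != "A"), sum(cc != "T"))
  }, 0L, USE.NAMES = FALSE))
  expected <- nbases * 0.002
  expect_lt(abs(nerr - expected), 3 * sqrt(nbases * 0.002 * 0.998) + 2)

  # determinism
  again <- simulate_reads(small, 33, 2, 0, seed = 10)
  expect_identical(again$sequence, clean$sequence)
})

test_that("coordinate lifting inverts insertions and deletions", {
  med <- generate_mediator(10000, 0.5, seed = 12)
  d <- derive_genome(med,
                     indels = data.frame(pos = c(2000L, 7000L),
                                         type = c("INS", "DEL"),
                                         seq = c("GTC", "AA")),
                     deletions = data.frame(start = 4001L, end = 4100L),
                     seed = 13)
  child <- d$genome
  # spot-check: bases agree between child and parent at lifted coordinates
  probe <- c(100L, 1999L, 2500L, 5000L, 8000L, child$length)
  par <- lift_to_parent(d$truth, probe)
  expect_false(anyNA(par))
  expect_identical(substring(child$sequence, probe, probe),
                   substring(med$sequence, par, par))
  # inserted bases have no parent coordinate
  expect_true(is.na(lift_to_parent(d$truth, 2001L)))
  # forward map round-trips
  back <- parent_to_child(d$truth, par)
  expect_identical(back, probe)
  # deleted parent bases have no child coordinate
  expect_true(is.na(parent_to_child(d$truth, 4050L)))
})

test_that("the default scenario wires shared and unique events coherently", {
  sc <- mediator_scenario(seed = 1L, genome_length = 10000L,
                          n_shared_subs = 60L, n_unique_subs = 5L)
  expect_equal(nrow(sc$wt_truth$substitutions), 60L)
  expect_equal(nrow(sc$mutant_truth$substitutions), 5L)
  expect_equal(sc$mutant_truth$indels$type, "INS")
  expect_equal(nchar(sc$mutant_truth$indels$seq), 2L)
  # shared substitutions are present in both derived genomes
  wt_tr <- sc$wt_truth$substitutions
  expect_identical(substring(sc$wt$sequence, wt_tr$pos, wt_tr$pos), wt_tr$alt)
  # unique substitutions never collide with shared ones
  expect_false(any(sc$mutant_truth$substitutions$pos %in% wt_tr$pos))
})
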