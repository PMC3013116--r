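test_that("published codon substitutions reproduce their amino-acid pairs", {
  got <- classify_codon_change(codon_rows$wt, codon_rows$mut)
  expect_equal(got$wt_aa, codon_rows$wt_aa)
  expect_equal(got$mut_aa, codon_rows$mut_aa)
  expect_equal(got$effect[1], "synonymous")      # ATC -> ATT, I -> I
  expect_true(all(got$effect[-1] == "nonsynonymous"))
})

test_that("codon classification covers identity, nonsense and bad input", {
  expect_equal(classify_codon_change("GCA", "GCA")$effect, "synonymous")
  n <- classify_codon_change("TCA", "TAA")
  expect_equal(n$mut_aa, "*")
  expect_equal(n$effect, "nonsense")
  expect_error(classify_codon_change("AXG", "AAG"), "A/C/G/T")
  expect_error(classify_codon_change("AA", "AAG"), "length 3")
})

test_that("effect class is symmetric under swapped codons when no stop appears", {
  set.seed(12)
  for (i in 1:30) {
    a <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
    f <- classify_codon_change(a, b)
    r <- classify_codon_change(b, a)
    if (f$wt_aa != "*" && f$mut_aa != "*")
      expect_equal(f$effect == "synonymous", r$effect == "synonymous")
  }
})

test_that("SNVs are annotated by reading frame on either strand", {
  g <- generate_mediator(2000, 0.5, seed = 13)
  feats <- gene_features(c("plusG", "minusG"), start = c(101L, 1001L),
                         end = c(400L, 1300L), strand = c("+", "-"))
  # + strand, codon position 2: middle base of the codon changes
  pos <- 105L  # offset 4 => codon 2, codon position 2
  refb <- substr(g$sequence, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  tab <- difference_table(data.frame(pos = pos, type = "SNV",
                                     ref_allele = refb, alt_allele = alt,
                                     coverage = 50L, alt_fraction = 1,
                                     pass_mode = "strict"), "m", "mediator")
  ann <- annotate_variants(tab, feats, g)
  expect_equal(ann$locus_tag, "plusG")
  expect_equal(substr(ann$wt_codon, 1, 1), substr(ann$mut_codon, 1, 1))
  expect_equal(substr(ann$wt_codon, 3, 3), substr(ann$mut_codon, 3, 3))
  expect_false(substr(ann$wt_codon, 2, 2) == substr(ann$mut_codon, 2, 2))

  # intergenic variant
  tab2 <- difference_table(data.frame(pos = 700L, type = "SNV",
                                      ref_allele = substr(g$sequence, 700, 700),
                                      alt_allele = setdiff(c("A", "C", "G", "T"),
                                                           substr(g$sequence, 700, 700))[1],
                                      coverage = 50L, alt_fraction = 1,
                                      pass_mode = "strict"), "m", "mediator")
  ann2 <- annotate_variants(tab2, feats, g)
  expect_equal(ann2$effect, "intergenic")
  expect_true(is.na(ann2$wt_codon))
})

test_that("minus-strand annotation agrees with whole-gene translation", {
  g <- generate_mediator(3000, 0.5, seed = 14)
  feats <- gene_features("mg", start = 1001L, end = 1600L, strand = "-")
  set.seed(15)
  for (i in 1:20) {
    pos <- sample(1001:1600, 1)
    refb <- substr(g$sequence, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
    tab <- difference_table(data.frame(pos = pos, type = "SNV",
                                       ref_allele = refb, alt_allele = alt,
                                       coverage = 50L, alt_fraction = 1,
                                       pass_mode = "strict"), "m", "mediator")
    ann <- annotate_variants(tab, feats, g)
    # oracle: translate the whole WT and mutated gene and diff the proteins
    mutseq <- mutate_at(g$sequence, pos, alt)
    tr <- function(s) as.character(Biostrings::translate(
      Biostrings::reverseComplement(Biostrings::DNAString(substr(s, 1001, 1600))),
      if.fuzzy.codon = "X"))
    aw <- strsplit(tr(g$sequence), "")[[1]]
    am <- strsplit(tr(mutseq), "")[[1]]
    d <- which(aw != am)
    if (length(d) == 0) {
      expect_equal(ann$effect, "synonymous")
    } else {
      expect_equal(ann$wt_aa, aw[d])
      expect_equal(ann$mut_aa, am[d])
    }
  }
})

test_that("indels in a CDS are frameshifts unless their length is a multiple of 3", {
  g <- generate_mediator(2000, 0.5, seed = 16)
  feats <- gene_features("cds", start = 101L, end = 400L, strand = "+")
  mk <- function(type, seq) difference_table(data.frame(
    pos = 200L, type = type,
    ref_allele = if (type == "DEL") substr(g$sequence, 200, 200 + nchar(seq) - 1) else "",
    alt_allele = if (type == "INS") seq else "",
    coverage = 50L, alt_fraction = 1, pass_mode = "strict"), "m", "g")
  expect_equal(annotate_variants(mk("INS", "GT"), feats, g)$effect, "frameshift")
  expect_equal(annotate_variants(mk("INS", "GTA"), feats, g)$effect, "inframe_indel")
  expect_equal(annotate_variants(mk("DEL", "NN"), feats, g)$effect, "frameshift")

  badf <- gene_features("bad", start = 101L, end = 401L, strand = "+")
  expect_error(annotate_variants(mk("INS", "GT"), badf, g), "divisible by 3")
  partf <- gene_features("part", start = 101L, end = 401L, strand = "+",
                         partial = TRUE)
  expect_equal(annotate_variants(mk("INS", "GT"), partf, g)$effect, "frameshift")
})

test_that("direct repeats flanking a deletion are found, capped, or absent", {
  g <- generate_mediator(1000, 0.5, seed = 17)
  g10 <- plant_direct_repeat(g, 501, 542, 10)
  hit <- find_flanking_direct_repeat(g10, 501, 542)
  expect_equal(hit$length, 10L)
  expect_equal(hit$sequence, substr(g10$sequence, 491, 500))

  # random flanks: no repeat of >= 4 bases expected at this locus
  expect_null(find_flanking_direct_repeat(
    reference_genome("r", paste0(strrep("A", 200), "CGTG",
                                 strrep("T", 100), "ACAC",
                                 strrep("G", 200))), 205L, 304L))

  # fully identical 60 bp flanks are capped at max_repeat
  g50 <- plant_direct_repeat(g, 301, 400, 60)
  expect_equal(find_flanking_direct_repeat(g50, 301, 400)$length, 50L)

  # insufficient flank at the genome start
  expect_null(find_flanking_direct_repeat(g, 3L, 44L))
})

test_that("isolate panels are summarised as whole-number percentages", {
  s <- isolate_class_summary(c(frameshift = 19L, del42 = 25L, stop = 3L,
                               point = 1L, none = 6L), none_class = "none")
  expect_equal(s$total, 54L)
  expect_equal(s$table$percent[s$table$class == "del42"], 46)
  expect_equal(s$table$percent[s$table$class == "frameshift"], 35)
  expect_equal(s$percent_mutated, 89)
})
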