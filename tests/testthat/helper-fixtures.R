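# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The default synthetic study scenario (100 kb mediator, 750 shared
# substitutions, 19 mutant-unique substitutions plus one 2 bp insertion,
# 33 bp reads at 50x with 0.2% error) and the full pipeline run over it.
default_scenario <- function() {
  cached("scenario", function() mediator_scenario(seed = 42L))
}

default_report <- function() {
  cached("report", function() {
    sc <- default_scenario()
    run_full(list(reference = sc$mediator, wt_reads = sc$wt_reads,
                  mutant_reads = sc$mutant_reads))
  })
}

# build an alignment data.frame row for a read placed exactly (no errors)
exact_alignment <- function(ref, start, len, id = "r") {
  s <- substr(ref$sequence, start, start + len - 1L)
  data.frame(read_id = id, ref_start = start, ref_end = start + len - 1L,
             strand = "+", n_mismatches = 0L, n_gap_columns = 0L,
             aligned_len = len, ref_aln = s, read_aln = s,
             stringsAsFactors = FALSE)
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# The coding codon substitutions reported for the sequenced host-independent
# isolate, with their published amino-acid pairs (frozen from the printed
# mutation table; one row is synonymous, the rest non-synonymous).
codon_rows <- data.frame(
  wt  = c("ATC", "GGG", "GGG", "CGC", "TCT", "GGA", "GGG", "ACG", "TAT",
          "AAG", "CAT", "GAC", "ATG", "TCC"),
  mut = c("ATT", "TGG", "AGG", "TGC", "TTT", "GAG", "GAG", "CCG", "TGT",
          "AGG", "CAA", "AAC", "ATT", "TAC"),
  wt_aa  = c("I", "G", "G", "R", "S", "G", "G", "T", "Y", "K", "H", "D",
             "M", "S"),
  mut_aa = c("I", "W", "R", "C", "F", "E", "E", "P", "C", "R", "Q", "N",
             "I", "Y"),
  stringsAsFactors = FALSE)

mutate_at <- function(seq, at, alt) {
  substr(seq, at, at) <- alt
  seq
}
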