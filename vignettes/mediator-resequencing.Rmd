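---
title: "Mediator-based resequencing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediator-based resequencing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Resequencing a bacterial mutant to find the mutation behind a phenotype
normally requires an a-priori reference genome of the wild-type (WT) strain,
because unpaired short reads rarely assemble de novo. `medresq` implements
the *mediator* strategy: both the mutant and the WT isolate are sequenced,
and both read sets are mapped to the genome of a sequenced relative. Neither
isolate is ever compared to the other directly; each is compared to the
mediator, yielding two difference tables, and the tables are subtracted.
Differences shared by the two isolates measure the (large) evolutionary
distance to the mediator and carry no information about the phenotype;
differences unique to the mutant are the candidates.

The model rests on three assumptions:

* **Clonality.** Each isolate is a clone, so at every genomic position the
  reads carry (up to sequencing error) a single allele. This is why the
  caller demands a *consistent* majority rather than fitting genotype
  likelihoods, and why a truly mixed column — two alternative events tying —
  is treated as a no-call rather than a heterozygous site.
* **Moderate divergence.** The mediator must be close enough that most
  short reads still align within the error budget. At ~0.75% divergence and
  33 bp reads, roughly a third of reads carry at least one mismatch but very
  few exceed six errors. Regions diverged far beyond that (hyper-mutated
  cassettes) lose coverage instead, which the region detector turns into a
  signal.
* **Symmetric artefacts.** Alignment and calling artefacts caused by the
  mediator's distance affect both isolates alike and cancel in the
  subtraction. Only mutant-specific events survive.

## The alignment contract

Reads are seeded by exact `word_size = 11` matches (both strands, every read
offset) and extended with a banded dynamic program over three column types:
match/mismatch, insertion (read base over a reference gap), and deletion
(reference base over a read gap). The error count is mismatches plus gap
columns; an alignment is reportable when errors ≤ `max_errors = 6` and its
matched (non-gap) columns number at least `min_align_len`. Gap columns may
be adjacent — a 2 bp insertion aligns as two insertion columns — but each
gap column spends one error, and alignments may not begin or end with a gap
column. The optimum is lexicographic: fewest errors, then most matched
columns, then fewest gap columns, then smallest reference start, then the
plus strand. Ranking gaps below mismatches at equal error count mirrors
blastn's scoring (gaps are penalised above mismatches) and is load-bearing:
were total column count the tie-break, a deletion+insertion path (8
columns) would beat an equal-error two-substitution path (7 columns)
whenever two real substitutions sit ~2 bp apart in suitable context, the
chosen representation would then vary with each read's window, and the two
isolates could flip representation independently — manufacturing false
mutant-unique calls out of shared variation. An exhaustive
dynamic-programming oracle (`oracle_align()`) implements the identical
contract without seeding and is used in the tests to certify the seeded
search's optimality whenever a seed exists; a read whose true locus contains
no intact 11-mer can be missed, exactly as with a word-seeded local aligner.

Decisions worth recording:

* `min_align_len` defaults to `ceiling(0.8 × modal read length)` — a single
  formula covering the classic 27-for-33 bp setting; it yields 31 rather
  than 30 for 38 bp reads, and the configuration can override it where exact
  reproduction of that choice is wanted.
* Reads whose two best placements tie on (errors, aligned length) at
  distinct loci are discarded as ambiguous. Repeat-borne reads would
  otherwise be placed arbitrarily and could fabricate variants; discarding
  them costs a little coverage inside repeats instead.
* An E-value threshold is deliberately not modelled: with bounded read
  lengths, the error cap plus the minimum alignment length subsume its
  filtering role, and no low-complexity masking is applied.
* Alignment minimises errors before maximising length, so a read whose
  disagreements sit near its ends is clipped rather than forced through
  them. Consequences: positions covered only by the clipped tail of a read
  lose that read from both numerator and denominator of the caller — a
  conservative loss — and alignments never carry terminal gap columns
  (a terminal gap adds an error without adding read content).

## Calling thresholds

The strict pass marks a column mutated when coverage ≥ 5 reads and the most
frequent non-reference event exceeds 60% of the overlap coverage — a strict
inequality, so 6 of 10 is not enough. The denominator is the total overlap
coverage (reference-supporting reads and deletions included), the most
conservative reading of "consistently different". At 0.2% per-base error
and coverage ≥ 20 the chance that errors alone reach the rule at a given
column is far below 10⁻⁶ (binomial tail: at least 13 of 20 reads would have
to carry the same error base), so genome-wide false positives are not
expected, and the test suite verifies zero spurious calls on error-only
data.

The relaxed pass exists because strongly diverged regions depress coverage
below the strict floor. Its thresholds are not dictated by the method —
only the existence of a relaxed re-scan is. The defaults here, coverage ≥ 2
and fraction > 50%, are the weakest rule that still demands an absolute
majority of at least two concordant reads; relaxed calls are confined to
flagged regions and labelled `relaxed` in every report, so downstream users
can always segregate them.

Insertions anchor to the reference position preceding the inserted bases,
and a called insertion's coverage is its anchor column's coverage. Adjacent
single-base insertion/deletion calls merge into one multi-base event, so a
frameshifting 2 bp insertion is reported as one call whether the aligner
represented it as one two-base gap or two adjacent one-base gaps.

## Regions

Coverage depth counts aligned (non-gap) read bases per position; the mean
and standard deviation include zero-depth positions — otherwise "one
standard deviation below the average" would be ill-defined on a genome with
deletions — and a flag (`exclude_zeros`) reproduces the other convention.
Hyper-mutated flagging slides 500 bp windows by 250 bp and requires *both*
depressed mean depth (below mean − 1 SD) and ≥ 5 strict calls in the
window; qualifying windows are merged. The window size, step, and cluster
threshold are this package's choices (the method's description gives none):
they are set so that a gene-sized cassette at ≥ 1% local divergence is
flagged at 50× coverage, and all three are exposed in the configuration.
Because the cluster requirement is a count over a fixed window, raising
`min_cluster` can only shrink the flagged set — a monotonicity the tests
assert.

Zero-coverage runs are candidate large deletions; their boundaries carry up
to a read length of fuzz, since breakpoint-spanning reads clip at the
junction. Runs unique to the mutant (no overlap with any WT uncovered run,
length ≥ 50 bp) are reported separately. The maximal total insertion the
method can have missed is bounded by the summed length of unaligned reads
divided by the mean depth, rounded down.

## Annotation

Codon effects use the bacterial genetic code (translation table 11); for
internal codon substitutions its amino-acid assignments coincide with the
standard table, and start-codon special cases are irrelevant. Reading frames
are taken from the feature's start; minus-strand features are
reverse-complemented before codon extraction, and the test suite checks the
frame arithmetic against a whole-gene translate-and-diff oracle. Indels in a
CDS are frameshifts iff their length is not divisible by three. A CDS whose
length is not a multiple of three is an annotation error unless flagged
partial; partial features are annotated on the stated frame. Multi-base
substitutions are supported within a single codon (annotated as one codon
substitution); the pipeline's own caller only emits single-base SNVs.

Direct-repeat detection at a deletion returns the longest k in [4, 50] such
that the k bases immediately preceding the deletion equal the k bases ending
at the deletion end — the geometry in which recombination between two repeat
copies excises the intervening segment and one repeat copy.

## The synthetic-data generator

`mediator_scenario()` encodes the study conditions at desk scale: a 100 kb
i.i.d. mediator at 50% GC; a WT isolate at 750 substitutions from it (0.75%,
the observed congeneric divergence); a mutant carrying 19 additional
substitutions plus one 2 bp insertion; 33 bp reads at 50× mean coverage with
a 0.2% per-base substitution error rate for both isolates. Shared large
deletions and hyper-diverged cassettes can be added and are inherited by the
mutant. Truth sets record every event in parent coordinates;
`lift_to_parent()` / `parent_to_child()` translate across derivations when
indels shift coordinates.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: coverage bias (GC, origin-proximity),
indel-type sequencing errors, quality-score structure (qualities are emitted
as constant Q30 and ignored by the aligner), genome-scale repeat families,
and paired ends. Positions inside perfect repeats longer than a read are
unrecoverable by design (ambiguous reads are discarded); the synthetic
i.i.d. genome makes such repeats vanishingly rare, which is why planted-truth
recovery can be asserted exactly there while real genomes would lose loci
inside IS elements and rRNA operons.

Problem sizes in the shipped tests were chosen to keep the full suite fast
while preserving the study's rates: the end-to-end acceptance scenario uses
the 100 kb genome above (~300,000 reads across both isolates); unit tests
use 1–20 kb genomes. Scaling the scenario to the full 3.78 Mb mediator is a
matter of `mediator_scenario(genome_length = 3782950, n_shared_subs = 28379,
...)` and proportionally more runtime.

## Numerical and degenerate-input conventions

* All coordinates are 1-based inclusive, internally and in every report
  (BED export shifts to 0-based half-open at the boundary).
* Reference positions whose base is N are never callable; seed words
  containing N are not indexed; an N in a read never matches.
* Alt-fraction thresholds are exclusive bounds compared as plain doubles;
  the 6-of-10 boundary case is exercised in the tests.
* Ties: two top events at a column → no call; equal-best placements at
  distinct loci → read discarded; within one placement, gap positioning is
  resolved deterministically by the dynamic program's fixed transition
  order, so all reads spanning the same event report the same anchor.
* An empty read set is a usage error for alignment; an empty FASTA is a
  valid zero-read set; a zero-depth track makes the insertion bound
  undefined (usage error).
* Determinism: every random stage takes an explicit seed; identical inputs
  and seeds give byte-identical outputs.

## Known limitations

* Large insertions relative to the mediator are invisible except through
  the aggregate size bound; novel sequence cannot be placed.
* The relaxed-pass thresholds and the hyper-mutated window parameters are
  package choices (see above); analyses sensitive to them should sweep the
  configuration keys.
* Imported tabular alignments (BLAST outfmt 6) reconstruct ungapped
  alignments only, so they support SNV calling but not indel calling.
* The aligner's seeding can miss a true locus whose every 11-mer is
  disrupted; such reads are reported unaligned, mirroring word-seeded
  aligners generally.
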