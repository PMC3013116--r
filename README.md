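# medresq — mutation detection by mediator-genome resequencing

`medresq` finds the mutations that separate a bacterial mutant from its
wild-type (WT) parent when **neither strain has a reference genome**. Both
isolates are shotgun-sequenced with short unpaired reads (30–100 bp), and both
read sets are mapped onto the genome of a sequenced *related* organism — the
**mediator** — which serves purely as a shared coordinate system. Positions
where an isolate's reads consistently disagree with the mediator are recorded
in a per-isolate *difference table*; differences present in **both** tables
reflect the evolutionary distance between the sequenced strain and the
mediator and are discarded; what remains unique to the mutant is the candidate
causative set, which is then annotated at codon level.

This matters because the two isolates may each differ from the mediator at
tens of thousands of positions (~0.75% divergence is typical for a
congeneric mediator), yet differ from *each other* at only a handful of sites.
The subtraction turns an impossible candidate list into one short enough for
PCR validation.

## Method

For each isolate:

1. **Alignment.** Each read (and its reverse complement) is seeded by exact
   11-mer matches against the mediator and extended by a banded
   edit-distance dynamic program allowing substitutions and single-base gap
   columns. An alignment is reported only if
   *errors* = mismatches + gap columns ≤ 6 and the aligned length is at least
   `ceiling(0.8 × modal read length)` (27 columns for 33 bp reads). The best
   placement minimises errors, then maximises aligned length; reads with two
   equally good placements at different loci are discarded as ambiguous.
2. **Pileup and calling.** Alignment columns are projected onto the mediator.
   A position is called mutated when it is *consistently* different: coverage
   ≥ 5 reads and the single most frequent non-reference event (alternative
   base, deletion, or inserted sequence) supported by **more than 60%** of the
   reads overlapping the position. Adjacent single-base indel calls merge
   into one multi-base event.
3. **Regions.** Zero-coverage runs are reported as candidate large deletions.
   *Hyper-mutated* regions — windows whose mean depth falls more than one
   standard deviation below the genome-wide mean **and** that contain a
   cluster of ≥ 5 calls per 500 bp — are re-called with relaxed thresholds
   (coverage ≥ 2, fraction > 50%), confined to those regions.
4. **Subtraction.** Two calls are the same mutation iff they agree on
   (position, type, alternative allele). The mutant table is partitioned into
   common, unique-to-mutant and unique-to-WT sets. The total undetectable
   inserted sequence is bounded by
   (sum of unaligned read lengths) / (mean depth).
5. **Annotation.** Unique variants inside a CDS get wild-type/mutant codons,
   amino acids and an effect class (synonymous / nonsynonymous / nonsense /
   frameshift / inframe indel); deletions are screened for flanking direct
   repeats, the signature of recombination-mediated loss.

A synthetic-data module (`generate_mediator()`, `derive_genome()`,
`simulate_reads()`, `mediator_scenario()`) generates mediator/WT/mutant
genome trios with exact truth sets so the whole pipeline is testable without
any external data.

## Worked example

```r
library(medresq)

# a 20 kb mediator; WT at 150 substitutions from it; mutant = WT + 5
# substitutions + one 2 bp insertion; 33 bp reads at 50x, 0.2% error
sc <- mediator_scenario(seed = 42, genome_length = 20000, n_shared_subs = 150,
                        n_unique_subs = 5)
rep <- run_full(list(reference = sc$mediator, wt_reads = sc$wt_reads,
                     mutant_reads = sc$mutant_reads))
rep
#> <medresq_report> mediator-based resequencing
#>   mediator: mediator (20,000 bp)
#>   WT:     30,303 reads, 30,295 aligned, 150 calls
#>   mutant: 30,306 reads, 30,290 aligned, 156 calls
#>   common: 150 | unique to mutant: 6 | unique to WT: 0
#>   mutant max undetected insertion: 10 bp

as.data.frame(rep$unique_to_mutant)
#>     pos type ref_allele alt_allele coverage alt_fraction pass_mode
#> 1  4301  SNV          C          T       31    1.0000000    strict
#> 2  4310  INS                    GT       48    0.7708333    strict
#> 3  6723  SNV          G          A       35    0.9714286    strict
#> 4 11011  SNV          C          T       23    1.0000000    strict
#> 5 16566  SNV          T          C       32    1.0000000    strict
#> 6 17819  SNV          C          T       30    1.0000000    strict
```

The 150 substitutions shared by both isolates cancel in the subtraction; the
six calls that remain are exactly the five planted mutant-unique
substitutions plus the planted 2 bp insertion, reported as a single merged
`INS` at its anchor position. Every call carries its coverage, the fraction
of reads supporting the alternative allele, and the pass that produced it.

A thin command-line front end over the same functions lives at
`inst/cli/medresq.R` (subcommands `simulate`, `align`, `call`, `regions`,
`compare`, `annotate`, `run`).

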