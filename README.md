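# cas3design

Spacer and cloning-construct design for plasmid-based **compact type I-C
CRISPR-Cas3** genome engineering in high-GC bacteria (streptomycetes and
relatives).

Type I-C CASCADE-Cas3 reads a T-rich 5′-TTC-3′ PAM immediately 5′ of a
34-nt protospacer, and target recognition is dominated by perfect pairing
in the 8-nt PAM-proximal seed. Designing a deletion or substitution
experiment therefore needs, for a target region *R* in genome *G*:

1. **PAM discovery** — every 5′-TTC-3′ occurrence on both strands of *R*
   (`scan_pam()`, `extract_spacers()`), and genome-wide PAM censuses for
   any motif, e.g. TTC vs the Cas9 5′-NGG-3′ comparison (`pam_census()`).
2. **Off-target evaluation** — for each candidate protospacer *p*, two
   exact counts over both strands of all of *G*:
   * *n*<sub>full</sub> = occurrences of the full 34-mer (PAM-independent),
   * *n*<sub>seed</sub> = occurrences of PAM+seed (TTC + first 8 nt; seed
     matches count **only** when a PAM is adjacent),

   plus an exhaustive Hamming search within `max_mm` mismatches
   (`mismatch_scan()`). Both counts include the on-target site, so a
   perfectly specific spacer reads (1, 1); the default filters keep exactly
   those (`filter_spec()`, `rank_spacers()`).
3. **Cloning design** — the four-primer Gibson spacer cloning into the
   editing plasmid (`design_spacer_primers()`), verified in silico by
   restriction digestion plus overlap-based assembly
   (`digest_circular()`, `simulate_gibson()`), and repair templates with
   1-kb homology arms, optional cargo (e.g. a 51-bp attB site) and
   restriction-site screening (`design_repair_template()`,
   `predict_edited_locus()`).

Everything is testable offline: `generate_genome()` produces seeded
high-GC synthetic chromosomes and `plant_sites()` installs ground-truth
on-/off-target copies.

## Worked example

```r
library(cas3design)

g <- generate_genome(50000, gc = 0.72, seed = 42, id = "chr")

dplyr::bind_rows(pam_census(g, pam_motif("TTC")),
                 pam_census(g, pam_motif("NGG", side = "3prime")))
#>   pattern side   total_count forward_count reverse_count genome_length mean_spacing_bp
#> 1 TTC     5prime         741           371           370         50000            67.5
#> 2 NGG     3prime       12881          6428          6453         50000             3.9
```

In this 72% GC genome the Cas9 NGG PAM is ~17× denser than TTC — the
availability/off-target trade-off that motivates the T-rich PAM. Now design
against a 5-kb deletion target (CLI-style coordinates are 1-based
inclusive):

```r
region <- "chr:20001-25000"
ranked <- extract_spacers(g, region) |>
  annotate_and_rank(g, region = region)
dim(ranked)
#> [1] 76 13
head(ranked[, c("strand", "pam_start", "seed", "full_length_count",
                "seed_pam_count", "rank")], 3)
#>   strand pam_start seed     full_length_count seed_pam_count  rank
#> 1 +          20012 ATTGCAGC                 1              1     1
#> 2 -          20080 CGGCGACC                 1              1     2
#> 3 +          20086 GATCGGGG                 1              1     3
```

76 candidates in the region are unique genome-wide on both evaluations
(counts of 1 = the on-target site only). Primers for the top candidate:

```r
generics::tidy(design_spacer_primers(ranked$protospacer[1], toy_kit()))
#>   name       seq                    length    gc
#> 1 fixed_fwd  GCCGTGCCCCGCCAATCGTG       20 0.75
#> 2 fixed_rev  AGTTGTGCTGGCCCCGAGCG       20 0.7
#> 3 spacer_fwd ATTGCAGCGCGGAGGCGGACC…     56 0.714
#> 4 spacer_rev CGAGCATGCAGGCGGTCCGCC…     56 0.696
```

The two 56-nt primers anneal to the CRISPR repeats and carry the 34-nt
spacer (or its reverse complement) in their 5′ overhangs; the two fixed
20-nt primers complete the two PCRs whose products Gibson-assemble with
the BstBI/NdeI-digested backbone. `cmd_verify_assembly()` (or the
`verify-assembly` CLI subcommand) checks the reconstruction in silico.

The end-to-end workflow — candidates, ranking, repair template, primers,
TSV/BED/FASTA reports and a parameter log — is `design_deletion()` /
`cmd_design()`; a thin command-line entry point with subcommands
`census`, `design`, `offtarget`, `primers`, `template`,
`verify-assembly` and `fixture` ships at `inst/cli/cas3design`.

## Documentation

The methods vignette (`vignettes/cas3-spacer-design.Rmd`) documents the
model, the counting conventions, every tunable parameter with its default
and rationale, what the synthetic-genome generator does and does not
emulate, and known limitations.
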