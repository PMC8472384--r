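# lofburden

Rare loss-of-function (LOF) variant prioritization and domain-restricted
burden testing for case-control cohort studies, with frozen
reference-population comparators.

## Who this is for

Cancer-genetics groups asking whether rare protein-truncating germline
variants of a candidate gene — possibly restricted to one functional
domain — are enriched in a case cohort relative to internal comparator
strata and to population allele-frequency resources (gnomAD-style frozen
counts). The packaged worked example is the RAD50 zinc-hook analysis in
familial esophageal squamous cell carcinoma (ESCC): two truncating
variants in the zinc-hook dimerization motif (protein residues 635–734 of
NM_005732) tested in 1,044 familial patients against 2,245 pooled
non-familial individuals and gnomAD East Asian / all-population counts.

## What it computes

For each variant set *S* (e.g. all LOF variants; LOF variants in the zinc
hook; an explicit list such as p.Q672X/p.K722fs) and each pair of groups
with allele totals 2N₁ and 2N₂, the package forms the allele-count table

|          | carrier | non-carrier |
|----------|---------|-------------|
| group 1  | a       | b           |
| group 2  | c       | d           |

and reports the sample odds ratio OR = (a·d)/(b·c) — `inf` when c = 0 —
and the two-sided Fisher exact p-value under the minimum-likelihood rule:
with both margins fixed, the sum of hypergeometric point probabilities of
every table no more likely than the observed one. Upstream of that:
cDNA coding-change parsing (both `c.2014C>T` and `c.C2014T` dialects),
consequence classification (frameshift by net indel length; stop
gain/missense/synonymous by codon translation; LOF ⇔ stop gain or
frameshift), residue mapping `floor((pos−1)/3)+1`, domain assignment on
closed residue intervals, CADD ≥ 25 filtering for missense, and carrier
aggregation over cohort strata (allele totals = 2N, carriers
heterozygous). A seedable simulator generates genotype tables with known
per-stratum carrier frequencies and estimates type-I error and power of
the exact test at the study's sample sizes.

## Worked example

```r
library(lofburden)
cfg <- default_run_config(out_dir = "out")
reports <- reproduce_tables(cfg)
reports$combined
```

```
# Combined-cohort LOF risk

| variant set | group 1 | group 2 | carriers 1 | carriers 2 | p | OR |
|---|---|---|---|---|---|---|
| p.Q672X | familial | nonfamilial | 1/2088 | 0/4490 | 0.32 | inf |
| p.Q672X | familial | gnomad_ea | 1/2088 | 0/19954 | 0.095 | inf |
| p.Q672X | familial | gnomad_all | 1/2088 | 1/282670 | **0.015** | 135.44 |
| p.K722fs | familial | nonfamilial | 3/2088 | 0/4490 | **0.032** | inf |
| p.K722fs | familial | gnomad_ea | 3/2088 | 4/19954 | **0.022** | 7.18 |
| p.K722fs | familial | gnomad_all | 3/2088 | 4/282670 | **1.3e-05** | 101.68 |
| p.Q672X/p.K722fs | familial | nonfamilial | 4/2088 | 0/4490 | **0.010** | inf |
| p.Q672X/p.K722fs | familial | gnomad_ea | 4/2088 | 4/19954 | **0.0041** | 9.57 |
| p.Q672X/p.K722fs | familial | gnomad_all | 4/2088 | 5/282670 | **3.5e-07** | 108.51 |
| all_lof | familial | nonfamilial | 7/2088 | 8/4490 | 0.27 | 1.88 |
| all_lof | familial | gnomad_ea | 7/2088 | 30/19954 | 0.081 | 2.23 |
| all_lof | familial | gnomad_all | 7/2088 | 427/282670 | **0.043** | 2.22 |
```

Reading the grid: the two zinc-hook truncating variants jointly occur in 4
of 2,088 familial alleles and in none of 4,490 non-familial alleles
(p = 0.010, OR infinite), and are ~10-fold enriched over East Asian
reference alleles (OR 9.57) and ~100-fold over all populations
(OR 108.51) — while the burden of *all* LOF variants of the gene shows no
comparable enrichment (OR 1.88 vs the non-familial pool). Bold p-values
mark p < 0.05 (no multiplicity adjustment; 12 tests). Raw fractions,
exact p-values and the 2×2 behind every cell land in `out/combined.json`.

The LOF carrier census behind the grid:

```r
v <- annotate_variants(read_variant_table(cfg$paths$variant_table),
                       read_transcript_model(cfg$paths$transcript_model))
lof <- filter_deleterious(v, exclude_pos = cfg$exclude_pos)
carrier_census(lof[lof$is_lof, ],
               read_cohort_config(cfg$paths$cohort_config))
```

```
$n_variants
[1] 7
$n_carriers
[1] 15
$carriers_per_stratum
 discovery_fh validation_fh      sporadic       control
            4             3             4             4
$domain_fractions
     domain carriers  fraction percent
1 zinc_hook        4 0.2666667    26.7
```

Seven distinct LOF variants in 15 carriers; 4/15 (26.7%) map to the zinc
hook, all of them familial.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","lofburden.R",package="lofburden"))')" \
    reproduce-tables --out-dir out
```

Subcommands: `annotate`, `burden`, `assoc`, `simulate`, `calibrate`,
`reproduce-tables`. Exit codes: 0 ok, 2 configuration, 3 validation,
4 enumeration guard.

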