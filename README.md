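# chcohort

Cohort-aware quality control and calling of clonal hematopoiesis (CH)
variants from blood sequencing data.

## The problem

CH variants are somatic mutations carried by expanded blood-cell clones.
They sit at low variant allele frequencies (VAF, typically < 0.2) where
they are easily confused with three other things that show up in somatic
variant calls from blood: sequencing artifacts (often strand-biased and
recurrent across samples), germline heterozygotes (VAF ≈ 0.5, present in
population databases), and — in cancer cohorts — tumor cell-free DNA
leaking into the blood sample. Fixed, hard-coded thresholds (e.g. VAF ≥
0.02, DP > 20) behave very differently across sequencing depths
(whole-exome ~150× vs error-corrected targeted ~5000×) and cohort sizes,
so the appropriate cutoffs are a property of the cohort, not universal
constants.

`chcohort` is for groups who have per-sample somatic VCFs (Mutect2-style
FORMAT `AD/AF/DP/SB`, INFO `TLOD/SOR`, optionally ANNOVAR-annotated) from
a blood cohort, optionally with matched tumor samples, and want
reproducible, auditable CH calls with cohort-tuned thresholds.

## Method

**Four filter tiers**, applied population tier first:

1. *Population*: for each variant, the cohort prevalence is computed at
   allele level (carriers of the exact allele / cohort size *N*) and
   locus level (carriers of any alternate at the position / *N*). A
   variant is removed for all carriers iff either prevalence exceeds
   `prevalence_max` (default 0.10) — individually rare CH cannot be
   carried by a third of a cohort; such recurrence marks an artifact.
2. *Technical*: `vaf_min ≤ VAF ≤ vaf_max` (0.02, 0.35), `DP > dp_min`
   (20), `Alt_AD ≥ 5`, per-strand support `SAF, SAR ≥ 3`, strand odds
   ratio `SOR ≤ 3`, `TLOD ≥ 6.3`. SOR is the GATK-style symmetric odds
   ratio: with pseudocount 1 on all four strand counts and
   r = (ref_fw·alt_rv)/(ref_rv·alt_fw),
   `SOR = log(r + 1/r) + log(refRatio) − log(altRatio)`.
3. *Functional*: remove synonymous variants, effects outside the
   CH-relevant set, repeat-region variants, and likely germline database
   variants (gnomAD AF > 0.001, or bare dbSNP membership without COSMIC
   evidence — a COSMIC id rescues).
4. *Individual* (paired mode): a one-sided exact test on the 2×2 table
   `[blood alt, blood ref; tumor alt, tumor ref]`. Significant blood
   enrichment (p < 0.05) keeps the variant; otherwise it is removed as
   `PAIR_TUMOR` (tumor VAF higher: cfDNA contamination) or
   `PAIR_GERMLINE`.

Every record gets a decision with all firing reason codes, so removals
are fully auditable.

**Permutation tuning.** For each candidate value of one threshold (VAF,
prevalence, DP, SOR, or SAF/SAR), the cohort is repeatedly partitioned
into k random disjoint subsets (proportions 1/2 … 1/10), the pipeline is
re-run independently per subset (prevalence recomputed inside the
subset), and the pooled subset calls are compared with the full-cohort
calls. Consistency is the fraction of full-cohort calls recovered in the
pool, averaged over permutations. The smallest threshold at which the
consistency curve saturates (the plateau inflection) is reported as the
cohort-specific cutoff.

A seeded synthetic-cohort generator (`simulate_cohort()`) emulates both
depth regimes with all four variant classes and a truth table, so every
stage is testable without any external data.

## Worked example

```r
library(chcohort)

sim   <- simulate_cohort(sim_params(n_samples = 100, depth_mode = "ultradeep", seed = 1))
calls <- run_chipfilter(sim$table, filter_config())
calls
#> ch_callset: 202 CH calls from 1466 records across 100 samples (mode: single)
#>   records failing per reason:
#>     POP_ALLELE    1217
#>     POP_LOCUS     1217
#>     VAF_LOW       225
#>     VAF_HIGH      1039
#>     ALT_AD        1
#>     SAF           1
#>     SAR           2
#>     SOR           2
#>     SYNONYMOUS    463
#>     GERMLINE_DB   1039

head(calls$calls, 2)
#>   sample_id     pos ref alt        vaf   dp  gene     exonic_function
#> 1     S0001 9215468   C   G 0.07273603 6228 PPM1D frameshift deletion
#> 2     S0001 9217231   C   A 0.08203322 5961 PPM1D   nonsynonymous SNV
```

The cohort planted 203 true CH events; 202 survive the four tiers. The
1039 germline heterozygotes fail on VAF (≈0.5) and gnomAD frequency; the
recurrent low-VAF artifacts fail on cohort prevalence or the VAF floor.

Tuning the VAF threshold by permutation:

```r
plan <- permutation_plan("VAF", proportions = c(1/2, 1/5, 1/10),
                         n_perm = 20, seed = 1)
cv <- permutation_scan(sim$table, filter_config(), plan,
                       truth = sim$truth[sim$truth$class == "ch", ])
cv
#> consistency_curve: VAF scan, 21 grid values x 3 proportions, 20 permutations (seed 1)
#> inflection (plateau) per proportion:
#>  proportion inflection saturated
#>         0.5      0.000      TRUE
#>         0.2      0.015      TRUE
#>         0.1      0.015      TRUE

cv$full_calls[cv$full_calls$grid_value %in% c(0, 0.015, 0.02), ]
#>  grid_value n_calls precision    recall
#>       0.000     229 0.8864629 1.0000000
#>       0.015     203 1.0000000 1.0000000
#>       0.020     202 1.0000000 0.9950739
```

Below the artifact VAF band the pooled subset calls disagree with the
full cohort (partition-sensitive near-threshold artifacts), so
consistency saturates only once the VAF floor clears the band: the
smaller subsets place the inflection at 0.015, and precision jumps from
0.89 to 1.00 at the same point. `plot(cv)` draws the curves.

From a shell, the same pipeline is available as subcommands:

```sh
exec/chcohort simulate  --out sim_dir --n-samples 100 --seed 1
exec/chcohort vcf2input --sheet sim_dir/sample_sheet.tsv --out run
exec/chcohort filter    --table run/cohort_table.tsv --out run
exec/chcohort optimize  --table run/cohort_table.tsv --metric VAF --out run
```

Every run writes a `manifest.json` (resolved configuration, input
digests, seed) sufficient to reproduce its outputs.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch under a given seed — simulating a paired ultra-deep cohort,
writing and re-parsing its VCFs, applying the filter in both modes, and
scanning the VAF threshold — and writes its JSON result file:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
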