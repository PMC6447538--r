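# hypertad

Dosage effects and TAD-boundary insulation analysis for high hyperdiploid
(HeH) acute lymphoblastic leukemia — an R implementation of the full
analysis chain linking whole-chromosome gains to RNA/protein expression and
to chromatin architecture, with a synthetic-data module that plants ground
truth so every stage is testable without controlled-access patient data.

## Who this is for

Computational biologists studying aneuploid cancers who need, in one
package: Hi-C contact-matrix filtering and balancing (including removal of
copy-number bias), TAD boundary calling by directionality index and
insulation score, cross-sample boundary matching and recurrent-loss
detection, copy-number dosage statistics at the mRNA and protein layers,
TAD-membership gene-pair co-expression analysis, and CTCF/cohesin
anchor-gene enrichment — plus generators that simulate all the required
inputs with known truth.

## The statistics at the core

* **Normalized copy number** per chromosome:
  `mean_samples( (Σ_i copy_i · len_i / chrom_len) / ploidy )`, with ploidy
  2 for autosomes and 1/2/undefined for sex chromosomes.
* **Cohen's d** per feature, `d = (m₁ − m₂)/s_pooled`, averaged per
  chromosome and regressed on normalized copy number (OLS); chromosomes
  with `d > 0.3` are dosage-affected. The protein-layer slope relative to
  the RNA slope estimates the protein attenuation of dosage.
* **Directionality index** per bin:
  `DI = sign(B−A)·((A−E)²/E + (B−E)²/E)`, `E = (A+B)/2`, with A/B the
  upstream/downstream 500 kb contact sums; boundaries at standardized-DI
  sign switches.
* **Insulation score**: mean of a 250 kb square sliding across the
  diagonal, log2-normalized to the genome-wide median; boundaries at
  upward zero-crossings of the 125 kb delta vector.
* **cis/trans map**: Spearman correlation of every copy-number-variable
  gene against every expression feature, BH-controlled.
* **TAD co-expression readout**: mean Spearman correlation of same-TAD
  gene pairs minus different-TAD pairs (with random 1 Mb domains as
  reference and LOESS-smoothed distance curves).

## Worked example

Simulate a three-chromosome genome with 20 planted strength-1 boundaries,
normalize, and call boundaries from the directionality index:

```r
library(hypertad)
library(dplyr)

g    <- genome_spec(paste0("chr", 1:3), rep(2e7, 3), bin_size = 25000)
tads <- sim_tads(g, n_boundaries = c(7, 7, 6), strengths = 1, seed = 42)
sim  <- simulate_hic(g, tads, depth = 100, seed = 42)
map  <- balance(remove_short_range(sim$map), method = "caicb")
calls <- call_boundaries(directionality_index(map), sample_id = "HeH_sim")
calls$boundaries
#> # A tibble: 20 × 5
#>   sample  chrom      pos strength method
#> 1 HeH_sim chr1   4500000     4.78 di
#> 2 HeH_sim chr1   8575000     4.64 di
#> 3 HeH_sim chr1  10250000     4.37 di
#> ...
```

All 20 planted boundaries are recovered within one 25 kb bin. The dosage
side, on a simulated 20 HeH-like vs 20 control cohort:

```r
g8 <- genome_spec(paste0("chr", 1:8), rep(3e7, 8), bin_size = 25000)
co <- sim_cohort(g8, seed = 42)                      # trisomies planted
ex <- simulate_expression(g8, co, sim_tads(g8, 10, seed = 42),
                          n_genes = 1200, seed = 42)
heh <- co$samples$sample[co$samples$subtype == "HeH-like"]
ncn <- normalized_copy_number(ex$segments[ex$segments$sample %in% heh, ], g8)
d   <- cohens_d(ex$rna, genes = ex$genes)
fit <- regress_effect_size(inner_join(attr(d, "per_chromosome"), ncn,
                                      by = "chrom"))
fit
#> <dosage_fit> d = -2.145 + 2.067 * norm_copy (R^2 = 0.982);
#>   affected: chr1, chr2, chr3, chr4, chr5, chr6
```

Per-chromosome effect size is linear in normalized copy number
(R² = 0.98); exactly the six chromosomes with planted gains are flagged as
affected. The mRNA–protein layer comparison:

```r
mrna_protein_correlation(ex$rna, ex$protein)
#> <mrna_protein_cor> 1200 genes: mean rho 0.216, 90.9% positive,
#>   9.9% significant
```

`tidy()`/`glance()` methods give tabular access to fitted objects, and
`autoplot()`/`plot_*()` functions (contact maps, boundary profiles,
effect-size regressions, pair-correlation curves, volcano plots) cover the
main result types.

## Package layout

| Area | Functions |
|---|---|
| Synthetic data | `genome_spec`, `sim_tads`, `sim_cohort`, `simulate_hic`, `simulate_expression`, `simulate_annotations`, `simulate_cms` |
| Hi-C matrices | `load_contacts`, `filter_bins`, `remove_short_range`, `balance`, `coarsen` |
| TAD architecture | `directionality_index`, `insulation_score`, `call_boundaries`, `boundary_profile`, `compartments`, `compartment_agreement` |
| Boundary comparison | `match_boundaries`, `recurrent_lost_boundaries`, `classify_boundary_change`, `peak_support`, `boundary_proximal_enrichment` |
| Dosage effects | `normalized_copy_number`, `cohens_d`, `regress_effect_size`, `select_cna_genes`, `cis_trans_map` |
| TAD expression | `assign_genes`, `random_domains`, `pair_correlations`, `smooth_curves` |
| Regulatory enrichment | `count_ctcf_sites`, `ctcf_de_enrichment`, `consensus_interactions`, `classify_anchor_genes`, `anchor_de_enrichment` |
| Expression core | `filter_expressed`, `differential_expression`, `iterative_empirical_controls`, `mrna_protein_correlation`, `complex_coregulation`, `partial_correlation_by_subtype`, `strata_correlation_compare`, `compare_cms` |

See `vignettes/hypertad-methods.Rmd` for the models, parameter choices and
known limitations.
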