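# mircis

Integrative detection of miRNAs whose expression in tumors is driven
*in cis* by DNA-level aberrations at their own genomic locus — copy-number
gain or loss, promoter hypo- or hypermethylation, or a combination of both.

## Who this is for

Cancer genomics groups with matched per-sample tumor data on three layers —
miRNA expression arrays (log2 intensities), CpG methylation (β values with
probe annotation) and copy-number log-ratios (with probe positions) — plus a
normal-tissue methylation reference and, optionally, a second cohort for
replication and clinical covariates for downstream association scans.

## The method

For every miRNA genomic locus *j* and tumor *s*, two categorical aberration
axes are derived:

* **Copy number.** Centered log2 ratios are segmented per sample and
  chromosome by exact piecewise-constant fitting (PCF), minimizing
  `Σ_seg Σ_i (x_i − mean_seg)² + γ · #breakpoints` with an O(n²) dynamic
  program (penalty γ = 40 by default, scaled per track by a robust noise
  variance estimate). The covering segment mean is assigned to the locus and
  called **gain** if > 0.1, **loss** if < −0.1.
* **Methylation.** Probes map to loci through a three-tier hierarchy
  (vendor-designated promoter probes → host-gene promoter probes for
  intronic miRNAs → nearest probe), multi-probe loci take the median β. With
  normal-reference median *m* and standard deviation *SD* per locus, a tumor
  is **hypermethylated** if β > m + 2·SD and **hypomethylated** if
  β < m − 2·SD; a threshold falling outside [0, 1] disables that call.

Each locus is then tested under two scenarios (activating: gain/hypo;
silencing: loss/hyper) × three categories (copy number, methylation,
combined) by a Wilcoxon rank-sum test of expression between altered and
non-altered samples, with Benjamini–Hochberg adjustment within each
scenario-category family. A locus is **in-cis** if some test reaches
q < 0.05 *and* the direction filter passes (Spearman ρ(CN, expr) > 0, or
ρ(β, expr) < 0). Candidates are replicated in an independent cohort at
uncorrected p < 0.05 with matching aberration type (paired CpG assays over
one promoter report the larger p). Downstream utilities cover seed-family
complementarity (identical seeds, positions 2–8, define families; members'
activating aberrations are OR-ed per patient), clinical association scans
(Wilcoxon / Kruskal–Wallis + BH), median-split log-rank survival,
miRNA–mRNA Spearman screening (|ρ| > 0.3, cross-cohort consistent), and
functional screen hit calling (|viability| > 0.2, |z| > 1.96).

A synthetic cohort generator plants all of these structures with known
ground truth, so the whole pipeline is testable end to end without any
external download.

## Worked example

```r
library(mircis)
cfg <- simulation_config(seed = 1)           # 100 tumors, 500 loci, 80 planted
discovery   <- generate_cohort(cfg)
replication <- generate_cohort(simulation_config(seed = 1001),
                               template = discovery)   # twin cohort
out <- run_pipeline(discovery, replication = replication)

out$log$n_incis                  # 83  loci called in-cis in discovery
out$log$n_replicated             # 80  of them replicate at p < 0.05
out$log$n_complementary_families # 5   seed families with >= 2 in-cis members

head(incis_summary(out$detection, discovery$annotation), 4)
#>     locus_id mature_id     mimat_id     location    rho_cn    rho_meth     effect driver_class
#> 1 locus_0001  mir_0001 MIMAT0000001 chr1:2000000 0.6168617 -0.12446445 activating  copy_number
#> 2 locus_0002  mir_0002 MIMAT0000002 chr2:2000000 0.7277408  0.01776178 activating  copy_number
#> 3 locus_0003  mir_0003 MIMAT0000003 chr3:2000000 0.5511191  0.15911191 activating  copy_number
#> 4 locus_0004  mir_0004 MIMAT0000004 chr4:2000000 0.5389019  0.09815782 activating  copy_number

evaluate_against_truth(out$detection, discovery$truth)[
  c("sensitivity", "fdp", "mechanism_accuracy")]
#> sensitivity 1.000   fdp 0.036   mechanism_accuracy 1.000
```

The summary rows read like the method's main report: `locus_0001` sits in a
gained region (ρ between copy number and expression 0.62, methylation
uncorrelated), is upregulated in altered samples (`activating`), and its
driver class is `copy_number`. Against the generator's truth table, all 80
planted loci are recovered, 3 of 83 calls are false (FDP 0.036), and every
recovered locus gets the correct mechanism label. The planted TP53 effect
also surfaces in the clinical scan (`locus_0026`, Wilcoxon
q = 2.8 × 10⁻⁵, higher expression in mutant samples).

## Layout

* `R/` — implementation; `src/` — the exact PCF dynamic program (Rcpp)
* `vignettes/incis-detection.Rmd` — the model, parameters, design choices
  and limitations
* `tests/testthat/` — unit, property and acceptance tests with independent
  oracles
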