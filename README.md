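# toxaudit

Homology-based toxin annotation of venom-gland transcriptomes, and an
audit of how wrong it is.

## The problem

Putative venom toxins are usually called by protein homology: translate
every assembled contig, search the open reading frames against a toxin
database, keep hits with a predicted signal peptide. This systematically
overestimates the venom. Two error classes dominate: **non-toxin
paralogues** of toxin families (secreted or cellular homologues that were
never recruited into venom) and **untranslated isoforms** (toxin-clade
transcripts absent from the secreted proteome). How bad the overestimate
is depends on the database: annotation against a pan-taxon toxin set
(ToxProt-like) produces more false positives than a lineage-specific
toxin list, which produces more than a within-species, proteome-derived
list.

`toxaudit` implements the full procedure and its two refinements, with a
synthetic-data generator that provides exact ground truth so every claim
is testable:

* **six-frame ORF extraction** (≥ 40 aa, stop-to-stop, no start-codon
  requirement, partial CDSs flagged);
* **exact Smith–Waterman search** under BLOSUM62 with affine gaps
  (open 11, extend 1) and Karlin–Altschul E-values
  `E = K·m·n·exp(−λS)` (λ = 0.267, K = 0.041), threshold `E ≤ 0.001`,
  best-hit family assignment;
* **signal-peptide filtering and deduplication** (ground-truth labels on
  synthetic data; a documented rule-based heuristic otherwise);
* **comparative expression filtering**: keep a sequence iff venom-gland
  FPKM ≥ 100 and ≥ 10-fold over muscle (pseudocount 0.01, so
  venom-gland-unique contigs pass);
* **clade-evidence retention** on midpoint-rooted neighbor-joining family
  trees: keep a leaf iff it lies within a patristic radius (default: the
  tree's median pairwise distance) of a proteome-detected or
  expression-retained leaf;
* **evaluation**: Venn regions across database tiers, false-positive
  rates against the venom proteome, family-diversity profiles with
  percentage-point and fold deltas, precision/recall against ground
  truth, and intraspecific overlap by greedy identity clustering of
  mature peptides at 95%/90%.

Everything is tibble-in/tibble-out and composes with the pipe; trees are
`ape::phylo` objects; reports have `tidy()`, `glance()` and `autoplot()`
methods.

## A worked example

```r
library(toxaudit)

run <- run_pipeline(run_config(sim = sim_config(seed = 1),
                               log_level = "quiet"))
run$report
#> <tox_report>
#>   FP rates: distant=0.704 lineage=0.600 species=0.600
#>   filter retention: 91.7% of proteome-detected ids

glance(run$report)
#> # A tibble: 1 × 6
#>   fp_rate_distant fp_rate_lineage fp_rate_species filter_retention spearman_vg
#>             <dbl>           <dbl>           <dbl>            <dbl>       <dbl>
#> 1           0.704             0.6             0.6            0.917       0.644

run$report$overlap
#> # A tibble: 2 × 3
#>   threshold n_clusters n_shared
#>       <dbl>      <int>    <int>
#> 1      0.95         41        0
#> 2      0.9          39        2
```

Reading this run: annotation against the distant (ToxProt-like) database
tier called 70% of its putative toxins wrongly — they are not in the venom
proteome — against 60% for the lineage- and species-level tiers; the
100-FPKM/10-fold expression filter kept 91.7% of the proteome-confirmed
toxins while discarding most false positives; proteomic detection
correlates with venom-gland expression (Spearman r = 0.64); and the two
simulated populations share no mature peptide cluster at 95% identity and
two at 90%.

A thin CLI wraps the same functions
(`inst/scripts/toxaudit simulate|run-all`), and `validate_config()` reads
a YAML run configuration with all defaults resolved and unknown keys
rejected.

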