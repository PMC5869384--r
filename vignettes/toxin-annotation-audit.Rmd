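---
title: "Auditing homology-based toxin annotation against the venom proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing homology-based toxin annotation against the venom proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxaudit)
```

## The problem

Venom-gland transcriptomes are routinely annotated by protein-level
homology: assembled contigs are translated, searched against a toxin
database, and everything with a significant hit and a predicted signal
peptide is called a putative toxin. This overestimates the real venom:
a hit to a known toxin family does not mean the transcript encodes a
*secreted venom component*. Two false-positive classes dominate — non-toxin
paralogues of toxin families (recruited from ordinary secreted or cellular
proteins) and genuine toxin-clade isoforms that are transcribed but not
translated into venom. The size of the overestimate depends strongly on the
relatedness of the database: a pan-taxon toxin set (ToxProt-like) behaves
worst, a lineage-specific list better, a within-species proteome-derived
list best.

`toxaudit` implements this annotation procedure end to end, together with
the two refinements that rescue it — comparative expression filtering
between the venom gland and a non-venom tissue, and clade-level evidence
propagation on family trees — and audits every step against a venom
proteome and, on synthetic data, against exact ground truth.

## The pipeline

1. **ORF extraction.** Every contig is translated in all six frames;
   every maximal stop-free stretch of ≥ 40 residues is a candidate CDS.
   No start codon is required, so fragments truncated by contig ends are
   kept and flagged incomplete. Coordinates are 0-based half-open on the
   forward strand.
2. **Homology search.** Full Smith–Waterman local alignment under
   BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $g$ costs
   $11 + (g-1)$). Significance uses Karlin–Altschul statistics,
   $E = K\,m\,n\,e^{-\lambda S}$ with the standard gapped constants
   $\lambda = 0.267$, $K = 0.041$, and the tier's total residue count as
   $n$; hits are kept at $E \le 10^{-3}$ with no query-coverage filter.
   Exhaustive alignment replaces the seeded heuristic of blastp (word size
   is irrelevant here): at this scale exactness is affordable, and it can
   only find at least the hits a seeded search would.
3. **Family assignment.** Each query takes the family of its best hit
   (maximal bit score $(\lambda S - \ln K)/\ln 2$; ties broken by lower
   E-value, then lexicographic subject id).
4. **Post-processing.** Signal-peptide-positive CDSs are retained and
   exact duplicates removed (smallest id survives). On synthetic data the
   signal-peptide call reads the generator's ground-truth label; a
   rule-based heuristic (n-region charge, an 8-residue Kyte–Doolittle
   hydrophobic window ≥ 1.6, small residues at −3/−1 of the cleavage site)
   stands in for a dedicated predictor on real data and is clearly a
   stand-in, not a SignalP reimplementation.
5. **Expression filter.** FPKM is computed per tissue from fragment
   counts; a sequence is retained iff venom-gland FPKM ≥ 100 and
   venom-gland/muscle fold ≥ 10. The fold uses a 0.01-FPKM pseudocount in
   the denominator so venom-gland-unique sequences (muscle FPKM 0) pass —
   such contigs are treated as toxin evidence, not division errors. There
   are no replicates in this design, so the filter is a deterministic
   threshold rule, not a statistical test.
6. **Family trees.** Per family, pairwise global-alignment identity
   (denominator: shorter sequence, the CD-HIT convention) gives distances
   $d = -\ln(\text{identity})$, clamped at 5; neighbor joining with a
   deterministic tie-break builds the tree, which is midpoint rooted.
   A leaf is *evidence* if proteome-detected or expression-retained; a
   leaf is kept iff its patristic distance to the nearest evidence leaf is
   at most `d_max` (default: the median of all pairwise patristic
   distances in that tree).
7. **Evaluation.** Venn regions across tiers, false-positive rates
   against the proteome, per-family diversity profiles with
   percentage-point and fold deltas, precision/recall against ground
   truth, and intraspecific overlap (pooled identity clustering of mature
   peptides at 95% and 90% after signal-peptide removal).

## The synthetic study

The generator produces a two-tissue study with full ground truth. Its
defaults are the study conditions; they are design choices, stated here
once, with the reasoning.

* **Families.** 3 gene families of 16–24 leaves each on pure-birth trees
  (birth rate 1), rescaled so the mean root-to-leaf path is
  `subst_rate = 0.5` substitutions/site. Residues evolve by per-site
  Poisson replacement events; replacements are drawn from a
  BLOSUM62-conditional distribution (Boltzmann weights of matrix scores),
  so conservative changes dominate — a simple, oracle-checkable process.
* **Toxin recruitment.** With probability 0.7 a family has one recruited
  clade of roughly half its leaves; every study is guaranteed at least one
  recruited family (a venom-gland study has toxins by construction).
  Toxin-clade branches are accelerated 3× (`toxin_rate_multiplier`):
  venom toxins evolve under diversifying selection, and this
  hypervariability is exactly why remote homology misses them
  preferentially. Toxin leaves carry a family signal peptide that
  diverges along the tree like the mature region — a conserved signal
  peptide would otherwise act as a universal alignment anchor, which real
  signal peptides are not.
* **Secreted non-toxins.** Each non-toxin leaf is secreted with
  probability 0.5. These paralogues — secreted, family-homologous, absent
  from venom — are the principal false-positive class the audit must
  expose.
* **Databases.** *species*: the proteomically detected precursors of
  population A. *lineage*: two representatives per recruited family,
  derived from the toxin-clade ancestor with 0.3 extra
  substitutions/site (a related species' known-toxin list; it contains
  toxins only, and only for families that are toxins in this lineage).
  *distant*: one representative per family (coverage 0.9) derived from
  the family **root** with 0.6 extra substitutions/site, plus 4 decoy
  families with no transcriptome homologue — a ToxProt-like pan-taxon
  database that includes families recruited as toxins only in *other*
  lineages. This construction is what lets the qualitative result emerge
  rather than being hard-coded: the distant tier annotates conserved
  secreted non-toxins it should not (including families this species
  never recruited) while missing the hypervariable true toxins.
* **Expression.** Per gene and tissue, expected FPKM is log-normal:
  toxins $10^{N(2.5,\,0.6)}$ in the venom gland, everything else
  $10^{N(0.8,\,0.6)}$; muscle is class-independent at $10^{N(0.8,\,0.6)}$.
  Counts are allocated by a single multinomial per library (2 × 10⁶
  fragments) over gene masses FPKM × length plus an explicit background
  bin holding the remaining library mass: by the definition of FPKM a
  whole transcriptome has mass $\sum \text{FPKM} \cdot \text{length} =
  10^9$, and the simulated families are a small slice of it. The
  background bin is what keeps realized FPKM unbiased for the model
  values; library size is conserved exactly (gene counts plus background).
* **Detection.** Each secreted toxin enters the proteome with probability
  $\mathrm{logit}^{-1}(-3 + 1.5\,\log_{10}(\text{FPKM}_{vg}+1))$ — about
  0.5 at FPKM 100 — and nothing else ever does.
* **Fragmentation.** With probability 0.35 a contig is emitted truncated
  (5′ or 3′, cut uniform over the proximal half of the CDS); a 5′ cut
  usually removes the signal peptide. The fragmentation rate is a free
  parameter of this generator, not a literature value.
* **Populations.** Mature toxin peptides of a second population are
  produced by evolving each population-A toxin a further 0.15
  substitutions/site — enough that almost no cross-population pair
  reaches 95% identity while a few reach 90%, matching the intraspecific
  sparsity the method is meant to detect.

Determinism: all randomness flows from `seed`; per-stage and per-family
streams are derived by hashing stable labels with the seed, so identical
configs give byte-identical FASTA/TSV/JSON outputs and single families can
be regenerated in isolation.

### What the generator does *not* emulate

Read-level noise, assembly artifacts beyond simple truncation, codon
usage and selection, chimeric contigs, shared per-gene expression baselines
across tissues (venom-gland and muscle levels are drawn independently, so
transcriptome-wide tissue–tissue correlations are not reproduced), and the
composition of real toxin databases. Passing tests therefore demonstrate
that the pipeline's logic is correct and that its qualitative behaviour
matches the study design under the stated statistical structure — not that
any particular real transcriptome would yield the same numbers.

## Numerical choices and edge cases

* Unknown residues score through the `X` row of BLOSUM62; codons
  containing `N` translate to `X` (never to a stop).
* FPKM of an empty library is 0 by convention; FPKM = 0 iff count = 0
  otherwise.
* Spearman p-values use the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$ at all sample sizes; zero-variance input is
  an explicit undefined-result error, reported per cell (not raised) in
  the detection–expression table.
* Global-alignment identity maximizes the match count among score-optimal
  alignments, which makes it well-defined and symmetric (co-optimal
  tracebacks can otherwise disagree).
* Neighbor joining breaks Q-criterion ties by the lexicographically
  smallest label pair; negative branch lengths are clamped to zero with
  the deficit moved to the sibling edge, preserving each join's two-edge
  sum. On additive matrices the tree is exact.
* Midpoint rooting places a degree-2 root on the longest leaf-to-leaf
  path; all patristic distances are preserved to 10⁻⁹.
* The clade-evidence radius `d_max = "median"` adapts to each family's
  depth and makes retention monotone in `d_max`; both the radius and the
  evidence definition (detected ∨ expression-retained) are explicit free
  parameters of this formalization — the underlying clade rule is
  qualitative in practice.
* False-positive rates are reported over unique signal-peptide-positive
  CDS ids (the Venn unit) *and* over all annotated unique CDSs, because
  the denominator choice is ambiguous in practice; the report carries
  both.
* Precision comparisons between filtered and unfiltered tiers are made
  only where the filtered set is non-empty — the precision of an empty
  set is undefined (an empty filtered distant tier means the filter
  removed every distant prediction, which is a success of the filter).

## Problem sizes

The shipped test-suite and acceptance runs use 3 families × 16–24 leaves
(about 60 genes, ~400 extracted ORFs) per study and 50 replicate seeds for
the multi-seed properties; alignment-level oracles run on 10,000 random
peptide pairs and 1,000 random 2-kb contigs. These sizes were chosen so
that every stage's behaviour is measurable with tight Monte-Carlo error
while a full multi-seed audit completes in a few minutes on one CPU.

## A worked run

```{r, eval = FALSE}
library(toxaudit)

run <- run_pipeline(run_config(sim = sim_config(seed = 1)))
run$report          # FP rates per tier, filter retention
glance(run$report)  # one-row summary
tidy(run$report)    # long tibble of all metrics
autoplot(run$report)

# intraspecific overlap and clade retention
run$report$overlap
run$report$clade_retention
```

## Known limitations

* The homology engine is exact but quadratic; it is sized for desk-scale
  studies and curated databases, not for 10⁵-contig assemblies against
  ToxProt.
* The signal-peptide heuristic is a coarse stand-in; on real data a
  dedicated predictor should supply the labels (its output can be passed
  through truth mode).
* Family trees are neighbor-joining on alignment-identity distances, not
  maximum-likelihood phylogenies; the audited contribution is the
  clade-level evidence propagation, which only needs a reasonable,
  deterministic tree.
* The manual-inspection step of real annotation workflows is represented
  only as an optional id-exclusion list (`exclude_ids`), never automated.
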