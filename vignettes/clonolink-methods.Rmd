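---
title: "Methods: clonotype calling and clonotype-function integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype calling and clonotype-function integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonolink)
```

## Scope

clonolink analyses paired single-cell TCR sequencing (scTCR-seq) data
together with per-cell transcriptional readouts from the same cells. Its
motivating system is the human MAIT (mucosal-associated invariant T) cell:
an innate-like T cell whose semi-invariant TRAV1-2 alpha chain pairs with a
restricted set of TRAJ segments (TRAJ33, TRAJ12, TRAJ20) and a diverse beta
chain. Because every cell carries both a TCR and a transcriptome, clonal
identity can be linked to transcriptional state: which cluster a clone's
cells occupy, how active a regulon is in them, and where they sit on an
activation pseudotime.

The package implements the analysis layer only. Upstream processing
(alignment, contig assembly, normalisation, clustering, trajectory
inference, gene-regulatory-network inference) is consumed as input tables;
a ground-truthed synthetic generator stands in for real data so that every
statistical component can be validated by parameter recovery.

## Ingest and gating

Contig annotation tables follow the 10x `filtered_contig_annotations.csv`
dialect. Contigs are retained only when high-confidence, full-length,
productive and on a TCR alpha/beta locus. Cells are barcodes; a barcode
with two alpha and two beta chains, or more than two of either, is treated
as a doublet (two cells in one droplet) and discarded.

Design choices where the conventions of contig tables are ambiguous:

* Duplicate contig rows (same barcode, locus, V/J genes and CDR3
  nucleotide sequence) are collapsed to one chain keeping the highest-UMI
  copy; a cell's chain set is a set.
* Gene names are matched ignoring allele suffixes (`TRAV1-2*01` equals
  `TRAV1-2`); annotation of alleles varies across pipelines.
* Cells lacking an alpha or beta chain are retained through assembly and
  removed only by the population gates, which are the population-specific
  part of the procedure.

Two gates are provided. The MAIT gate keeps cells with at least one
TRAV1-2 alpha chain and at least one beta chain. The conventional-memory
(Tmem) gate keeps cells with at least one chain of each locus and then
removes presumed contaminating MAIT cells: any cell carrying a TRAV1-2
alpha with TRAJ33/TRAJ12/TRAJ20 and a CDR3 alpha of exactly 12 amino acids
(counted verbatim in the `cdr3` field, including both flanking residues).
A TRAV1-2 cell with a 13-residue CDR3 alpha passes both gates; the two
gates are disjoint only on repertoires whose TRAV1-2 cells all carry the
canonical 12-residue junction.

## Clonotype definitions

Chain identity is the tuple (locus, V gene, J gene, CDR3). D-segment calls
are excluded: they are unreliable in short-read data and inconsistent
across annotation tools. Six definition levels are supported: nucleotide
or functional (amino-acid) CDR3s, over paired alpha-beta chain sets, alpha
chains only, or beta chains only.

*Nucleotide clonotypes* require exact equality of the cell's full chain
set at the chosen level.

*Functional clonotypes* tolerate chain dropout: a cell belongs to a
clonotype provided every chain it does carry matches the clonotype's chain
set. The membership condition does not by itself define a partition (it is
not transitive), so assignment proceeds in three stages:

1. cells are grouped by exact amino-acid signature ("seed groups");
2. signatures that are not a strict subset of any other observed signature
   are *maximal* and anchor the clonotypes;
3. every non-maximal seed group merges into a compatible maximal clonotype
   (all its chains contained in the maximal signature; at the paired level
   gated cells always share at least one chain per locus with any
   containing signature). A group contained in two or more maximal
   signatures is assigned to the one whose seed group holds the most cells,
   ties broken by lexicographically smallest signature, and its cells carry
   an `ambiguous` flag.

Anchoring on maximal signatures makes the result order-independent and
deterministic; the ambiguity flag preserves the information that a unique
assignment was not forced by the data.

Clonotypes are numbered by descending size with ties permuted by a seeded
RNG (numbering is reproducible but otherwise arbitrary within a size
class) and ranked by competition ("min") ranking, so sizes 5, 3, 3, 1
receive ranks 1, 2, 2, 4.

## Repertoire metrics

* **Shannon diversity** `H = -sum(p_i log p_i)` in nats, computed with
  `vegan::diversity()` on clone-size vectors.
* **Clonality curves** are cumulative cell fractions over size-sorted
  clonotypes.
* **Chain-pairing promiscuity** counts, for each unique chain at
  nucleotide identity, the unique partner-locus chains it co-occurs with
  inside cells; a dual-alpha cell contributes one pairing per alpha-beta
  combination. Nucleotide identity is used because amino-acid identity
  would conflate convergent recombination with true chain reuse. Both a
  per-donor-and-tissue and a tissues-combined scope are available, since
  either pooling is defensible.
* **Cross-sample sharing** is the percentage of cells whose clonotype
  signature occurs in both samples of a matched pair. **Frequency
  correlation** between matched samples is Pearson on log10 within-sample
  frequencies over shared clonotypes only — restricting to shared
  clonotypes avoids log(0) without a pseudocount.
* **Publicness** is defined on functional (amino-acid) signatures: the
  occupancy of a signature is the number of donors in which it occurs, and
  each donor's cells are binned by their clonotype's occupancy.
* **Downsampled comparisons** equalise group sizes within each stratum by
  sampling without replacement, with 100 replicates by default (enough that
  replicate noise is small relative to the group differences of interest),
  reporting per-replicate values and their mean.

## Clonotype-cluster association

For a clonotype of `n` cells over `k` transcriptional clusters the null
hypothesis is multinomial: cells fall into clusters with the whole-sample
cluster proportions. The package keeps the tested clonotype's own cells in
those proportions (the plain "random distribution across clusters"
reading); a leave-clonotype-out null is available via `loo_null = TRUE` as
a sensitivity analysis.

The p-value is the total null probability of outcomes at most as likely as
the observed one. With `events = choose(n + k - 1, k - 1)` distinct
outcomes:

* `events < 1e6`: exact enumeration of all compositions. Probabilities are
  computed via log-factorials, and the "as or less likely" comparison uses
  a relative tolerance of 1e-12 so that floating-point ties in the pmf
  cannot change the result with enumeration order.
* otherwise: Monte Carlo with `ntrial = min(10 * events, 1e8)` null draws
  and the add-one estimator `p = (1 + hits) / (ntrial + 1)`. The add-one
  form is a valid p-value and cannot return exactly zero (a plain
  proportion can).

When the outcome space is still enumerable (up to 2e9 compositions), the
Monte Carlo estimate is produced by computing the per-trial hit
probability exactly and drawing the hit count as one binomial variate.
This has *exactly* the same sampling distribution as the literal trial
loop at a fraction of the cost; truly enormous outcome spaces fall back to
literal conditional-binomial sampling. Both paths run under R's RNG, so
results are reproducible given a seed.

The scan tests every clonotype with at least 20 cells (the size below
which the test has little power at these cluster numbers) and applies
Bonferroni correction within the donor-sample's family of tested
clonotypes. The size-significance summary reports Spearman's rho between
the clonotype size rank (ascending, so the largest clonotype has the
largest rank value) and the adjusted p-value; under size-dependent bias
larger clonotypes reach smaller p-values and rho is negative.

## Regulon consensus and activity

Gene-regulatory-network inference is stochastic: repeated runs on the same
data return different regulon sets. Stability across `R` runs separates
reproducible structure from noise:

* a regulon is **high-confidence** when its transcription factor occurs in
  strictly more than 80% of runs *and* at least five of its targets are
  high-confidence;
* a **high-confidence target** occurs in strictly more than 80% of the
  runs that contain the factor's regulon. The denominator is conditional
  on the factor being found — a target reliably recovered whenever its
  regulon is inferred should not be penalised for runs in which the whole
  regulon is absent. (The unconditional denominator is stricter and would
  couple the two thresholds.)

The gene-by-factor occurrence matrix reports, for a chosen gene panel, the
percentage of all runs in which each gene fell inside each high-confidence
factor's regulon, keeping factors whose maximum over the panel exceeds
50%.

Per-cell activity is a recovery-curve (AUCell-style) score: genes are
ranked by decreasing expression within the cell, the recovery curve counts
gene-set hits among the top `ceil(0.05 * G)` ranks (5% is the scoring
convention's usual default), and the score is the area under the step
curve divided by the maximal achievable area, giving values in [0, 1] that
depend only on ranks — hence invariant to any monotone transformation of a
cell's expression. Ties are broken at random under a seeded RNG by
default; a deterministic mode (ties broken by column order) is provided
for exact reproducibility.

Differential activity between two cell groups uses a two-sided Wilcoxon
rank-sum test per regulon with Bonferroni correction (threshold 0.01), and
additionally orders regulons by absolute difference in mean activity for
display. A hurdle-type model with donor covariates would be the richer
choice on real data; the rank-sum test is the deliberately simple
substitute used here, with per-donor stratification possible by running
the test within donors.

## Linking clones to function

* **Coreceptor assignment.** Gene mode: CD8+ if CD8A > 0 or CD8B > 0;
  otherwise CD4+ if CD4 > 0; DN if all three are undetected. A cell
  positive for both is labelled CD8+ (the CD8 rule is evaluated first)
  with an `ambiguous` flag. Protein mode thresholds: CD8+ if CD8 > 0.3;
  else CD4+ if CD4 > 2.5 and CD8 < 0.2; else DN — note a cell with CD8 =
  0.25 and CD4 = 3 is DN because it fails both rules.
* **Pseudotime association.** An omnibus Kruskal-Wallis test across groups
  (TRBV genes or clonotypes) after removing groups under 20 cells, and a
  per-clonotype scan (each clone against all remaining cells, a two-level
  Kruskal-Wallis, i.e. a rank-sum test) for planting-recovery analyses.
  Rank-based tests make results invariant to affine rescaling of
  pseudotime, which is arbitrary in magnitude.
* **Cross-trajectory correlation** is Spearman on per-group mean
  pseudotimes between two trajectories.
* **Clone size versus pseudotime** is Pearson between log10 clonotype
  frequency and pseudotime over clonotypes with at least 20 cells. Each
  cell contributes one point by default; a per-clonotype-mean variant is
  available, since the unit of observation is ambiguous for this display.
* **Differential gene importance** between two trajectories takes the
  ratio of importance ranks with the larger rank as numerator (so the
  ratio is at least 1 and symmetric in its inputs). A gene is selected
  when its importance FDR is below 0.05 on at least one trajectory and its
  rank is within the top 150 on at least one trajectory — "either
  trajectory" is the consistent reading of both conditions.

## The synthetic generator

`generate_repertoire()` emulates the statistical structure the analyses
assume, with the planted truth recorded:

* semi-invariant alphas: every alpha is TRAV1-2 with a 12-amino-acid CDR3
  carrying the canonical tyrosine; TRAJ drawn as 87% TRAJ33, 6% TRAJ12,
  6% TRAJ20 and 1% other;
* diverse betas biased toward TRBV6-1, TRBV6-4 and TRBV20-1, with
  TRAJ-conditional pairing (TRAJ12/TRAJ20 enriched for TRBV6-4, TRAJ33
  for TRBV20-1); CDR3 beta sequences are 36-48 nt, unique across clones
  by construction so ground-truth recovery is well defined;
* log-series clone sizes (oligoclonal rank-abundance);
* within-donor alpha reuse (30% of new clones reuse an existing alpha,
  generating promiscuous pairing) and 27 public alpha signatures planted
  in every donor, on the largest clones — public sharing is at the
  amino-acid level, with each donor rearranging its own nucleotide
  junction;
* matched-tissue overlap: clones of two or more cells are shared between
  blood and liver with a probability calibrated so the expected
  cell-weighted overlap equals the requested 72%;
* per-chain dropout (10%) that respects gating viability: a chain is only
  dropped if the cell still retains a TRAV1-2 alpha and a beta — chains
  whose loss would delete the cell at gating are not informative for
  dropout-tolerance testing;
* clones carry a secondary alpha (10%) or a secondary beta (5%) but never
  both: a real cell with two alphas and two betas is indistinguishable
  from a doublet and would be discarded by the assembly rule;
* doublets (2% of barcodes) formed by unioning two cells' chain sets, with
  only those violating the chain-count rule recorded as detectable;
* incomplete TCR capture (90%), cells without TCR appearing in the
  metadata only;
* a small rate of non-productive decoy contig rows that the filter must
  remove.

Companion generators emit cluster labels (unbiased cells from global
proportions; biased clonotypes from a Dirichlet-perturbed proposal or
fully concentrated in one cluster), regulon runs (stable factors at 90%
occurrence with 95%-occurrence core targets, decoys at 50%), pseudotime
(base + clonotype effect + TRBV effect + Gaussian noise, with a
configurable cross-trajectory effect correlation) and expression matrices
whose coreceptor channels satisfy the assignment rules and whose regulon
targets are up-shifted in designated cells.

What the generator does **not** emulate: transcriptome-wide count
distributions (library-size and dispersion structure), sequencing and PCR
error in CDR3 sequences, CDR3 length/motif biology beyond the canonical
tyrosine, allele-level gene annotation, ambient contamination, and
batch effects. Passing recovery tests therefore demonstrates that the
algorithms are correct under the stated statistical structure — not that
real data satisfy that structure.

## Validation design and problem sizes

The test suite validates each component against an independent oracle or
planted truth; the main experiments and the sizes chosen for them:

* partition recovery on 5 donors x 2 tissues x 2,000 cells (exact
  agreement without dropout; at 30% dropout at least 99% of cells
  co-assigned with their clone, ambiguity flags cross-checked by
  brute-force subset enumeration);
* exact-test equivalence with a brute-force enumeration oracle over 200
  random small instances, and pmf totals summing to 1;
* Monte Carlo versus exact agreement over 100 seeds, and empirical type-I
  error of the scan over ~2,000 null clonotypes (20-24 cells each, eight
  clusters) required to fall in [0.03, 0.06] at raw alpha 0.05 — the
  exact test is discrete and therefore slightly conservative;
* detection of a 40-cell clonotype concentrated in a 10% cluster within a
  30-test family over 100 seeds;
* sharing-versus-capture monotonicity over capture rates 0.4-1.0 with
  planted overlap 0.7 across 20 seeds, run with dropout disabled and a
  moderately oligoclonal size law so the capture effect is isolated from
  signature fragmentation and extreme clone-size variance;
* TRAJ-usage and pairing-matrix recovery at ~4,500 unique chains using
  Bonferroni-simultaneous binomial confidence bands, on a configuration
  with one chain pair per clone so the empirical proportions are i.i.d.
  draws from the planted matrix;
* regulon-consensus equality with a brute-force realized-occurrence rule
  in every seed, exclusion of decoys and of boundary cases at exactly
  0.80, and at least 99% mean recovery of planted stable factors across 20
  seeds (a stable factor drawn at 90% occurrence occasionally realises at
  or below the 80% threshold; the thresholds are then correct to exclude
  it);
* pseudotime-shift detection with two shifted clones (one noise s.d.)
  among 30 clones of 35 cells, pooled over 100 seeds, at >= 90%
  sensitivity and <= 10% false-positive rate — with few shifted clones the
  "rest" reference is only mildly contaminated, keeping the null clones'
  rejection rate near nominal.

These sizes are the package's validation choices: large enough that the
statistical assertions are stable across RNG streams, small enough to run
routinely.

## Known limitations

* Cross-sample and cross-donor matching is exact on chain-set signatures.
  A clone observed with its secondary chain in one donor and without it in
  another yields different signatures; dropout-tolerant matching is
  applied within a calling run, not across independently called tables.
* The Monte Carlo rule's 1e8 trials make single very large clonotypes
  (hundreds of cells over many clusters) expensive even with the
  binomial shortcut unavailable; the cost is inherent to the prescribed
  trial count.
* Bonferroni families are per donor-sample; pooling across tissues within
  a donor is a one-line change on the scan output but is not the default.
* The functional-clonotype tie-break (largest seed group, then smallest
  signature) is one defensible convention; flagged ambiguous cells should
  be excluded from analyses sensitive to single-cell assignment.
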