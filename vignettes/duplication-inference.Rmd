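---
title: "Inferring tandem duplication and neofunctionalization: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tandem duplication and neofunctionalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupshift)
```

## The inference problem

A claim that gene *B* arose from gene *A* by tandem duplication followed by
neofunctionalization rests on four independent observations:

1. *B*'s clade is **monophyletic** and **nested inside** *A*'s clade in a
   gene tree — it is a derived lineage of the *A* family, not an
   independent origin;
2. *B* carries a coherent set of **diagnostic residues** at the positions
   known to switch the enzymatic activity, while *A* retains the ancestral
   set;
3. *B* sits **immediately adjacent to** *A* in a gene-order block that is
   otherwise conserved across species, and is **absent** from that block in
   lineages that branched before the duplication;
4. *B* has acquired its own **expression context** (co-expression partners,
   tissue profile) distinct from *A*'s.

The motivating case is Apiaceae flavone synthase I (FNS I), which arose
from flavanone 3-hydroxylase (F3H) — two 2-oxoglutarate-dependent
dioxygenases that accept the same substrate (naringenin) but resolve it
differently: desaturation to apigenin versus 3-hydroxylation. The package
implements each of the four analyses and a simulator that generates the
complete scenario with ground truth, so that every step can be validated
end-to-end without external data.

## Sequence model

### Substitution process

Sequences evolve by an i.i.d.-site Poisson replacement process: along a
branch of length $d$ (expected substitutions per site), each site receives
$K \sim \text{Poisson}(d)$ replacement events, and each event draws a new
residue uniformly from the 19 alternatives. This is deliberately the model
family behind the Poisson-corrected distance used downstream,

$$\hat d = -\ln(1 - p),$$

with $p$ the observed proportion of differing sites, so the simulator and
the estimator are consistent by construction. The exact expectation under
the simulator is $p = \tfrac{19}{20}(1 - e^{-\frac{20}{19} d})$ once
back-substitution is accounted for; at the divergences used here
($d \le 0.25$) the difference from $1 - e^{-d}$ is below 0.3%, well inside
the 2% calibration band asserted by the test suite, so the simpler form is
used throughout the documentation.

### Diagnostic positions are deterministic, by class

The eight diagnostic positions (AAP57393.1 numbering: 106, 115, 116, 131,
195, 200, 215, 216) and the conserved auxiliary site (PaFNSI numbering
240, residue P in all Apiaceae F3H/FNS I) are **excluded from the
stochastic process in every lineage** and set from the class profile: the
parent lineage carries the F3H residues (M, I, V, I, D, V, L, K), the
duplicate carries the FNS I residues (T, T, I, F, E, I, V, R), and the
FNS I-like copy a partial profile. The observed grids show both profiles
conserved within their lineages, so freezing them in all lineages — not
only after the neofunctionalization event — keeps every ground-truth class
label exact; without this, rare drift at a frozen-in-one-lineage-only site
would silently falsify the truth table that all downstream tests compare
against.

### Scenario calibration

The default four-species tree is
`((Casiatica:0.15,(Dcarota:0.112,Agraveolens:0.112):0.10):0.05,Pginseng:0.22)`
with the duplication placed at fraction 0.98 of the ingroup stem. These
numbers are chosen so that the two identity levels characteristic of the
real system both hold in expectation: duplicate vs parent within
*D. carota*

$$1 - \frac{351\,(1 - e^{-0.228}) + 8}{360} \approx 77.9\% \;(\to 78\%),$$

(the 8 diagnostic sites always differ, the frozen auxiliary site never
does) and duplicate vs duplicate across species
$\approx 80.4\% \;(\to 80\%)$. The two constraints together force the
duplication close to the speciation: only then can the cross-species
duplicate identity be *similar to* the within-species duplicate–parent
identity. A consequence embraced by the tests: the internal edge
separating the parent pair from the duplicate clade has length
$\approx 0.004$, a de-facto polytomy, so exact gene-tree recovery is
asserted only up to that edge (RF $\le 2$) while the two claims that carry
the argument — monophyly and nesting — are asserted exactly and reach
bootstrap supports of 95–100.

The default protein length is 360 residues (typical for a plant 2-ODD);
identities computed from it carry a binomial sampling standard deviation
of about 2.1 percentage points, which is why identity checks are framed as
"within 3 SD of the planted expectation" rather than equality to a rounded
integer.

The scenario carries **one** FNS I-like copy (a duplication of the FNS I
lineage within *D. carota* at 30% of its terminal branch, with positions
116 reverted toward the parent state). The real carrot genome carries two
such copies from a further duplication inside the like lineage; the
generator supports one event per source copy per branch, and the tests
quantify over "all like copies present" so the simplification does not
weaken any assertion.

## Alignment and trimming

The in-repo aligner is progressive: pairwise identity distances, an NJ
guide tree, then profile–profile merges by affine-gap dynamic programming
with average-of-pairs BLOSUM62 column scores (gap open 11, extend 1
throughout — a gap of length $k$ costs $11 + k$). For exactly three
sequences all three join orders are evaluated and the best sum-of-pairs
result kept. This aligner exists to make fixtures and small candidate sets
self-contained; real analyses should import MAFFT/MUSCLE alignments via
`import_alignment()`, which the rest of the pipeline treats identically.

Occupancy trimming removes a column iff the fraction of rows holding a
non-gap character is **strictly below** the threshold (default 0.10); a
column at exactly 10% is kept. `X` counts as occupancy: it is an
amino-acid placeholder produced by fuzzy translation, not evidence of
absence. Both choices are configurable; trimming is idempotent and
monotone in the threshold, and the kept-column index map is returned so
reference numbering survives trimming.

## Distances, trees, and clade tests

Pairwise deletion restricts each pair to columns where both rows hold an
unambiguous residue; `X` is treated as missing here (an unknown residue
cannot be scored as same-or-different without biasing $p$ — note the
asymmetry with occupancy counting, where `X` is presence). Two guards
replace silent extrapolation: pairs with fewer than 30 shared columns and
pairs at $p \ge 0.95$ (where $-\ln(1-p)$ explodes) are flagged undefined,
and tree building refuses matrices containing undefined entries, naming
the pairs.

Neighbor joining follows Saitou–Nei with two deterministic conventions:
negative branch-length estimates are clamped to zero, and ties in the
$Q$ criterion join the lowest-index pair in the current matrix order. NJ
consistency — exact recovery of topology *and* branch lengths on additive
matrices — is verified on 100 random 5–10-taxon trees per run.

Bootstrap supports resample alignment columns with replacement; a
replicate whose resampled alignment produces an undefined pair is dropped
and counted (more than 50% dropped is an error), and an edge's support is
the percentage of retained replicates containing its bipartition.

The nesting test roots on a user-supplied outgroup (required — rooting is
never guessed), then requires (i) the inner set monophyletic, (ii) the
MRCA of the outer set to already contain the inner clade, and (iii) no
foreign leaf under the MRCA of inner + outer. Condition (ii) deserves a
note: a purely path-based formulation would also accept an inner clade
*sister to* the outer clade, which is precisely the topology that would
argue for an independent origin rather than an embedded one; requiring
containment in MRCA(outer) distinguishes the two.

## Residue diagnostics

Reference-numbered positions are mapped through the alignment by locating
the column of the reference's $r$-th ungapped residue; every other row
reports that column's character and its own ungapped coordinate. The
classification rule is the minimal one consistent with the observed
grids: all eight FNS I residues → `FNS_I`; all eight F3H residues →
`F3H`; at least one FNS I match short of all eight → `FNS_I_LIKE`; no
FNS I match without a full F3H profile → `UNCLASSIFIED`. Gaps are
non-matches, never errors, so truncated gene models degrade visibly
instead of failing. The two sufficiency sets (M106T+I131F+D195E and
I131F+L215V+K216R, the substitution sets shown experimentally to confer
FNS I activity) are reported as separate flags, and position 240 is
checked against its own numbering reference (PaFNSI) rather than
renumbering AAP57393.1, because the P/Y contrast is anchored to the
liverwort sequence.

The package does not redistribute the deposited candidate FASTA. The
shipped benchmark (`synthetic_residue_benchmark()`) is an explicitly
synthetic stand-in: an artificial family that embeds the published residue
grid at correctly mapped positions, with an insertion offsetting the two
numbering references and an internal deletion exercising gap bookkeeping.
It validates mapping and classification cell-for-cell; it does **not**
validate divergence levels (its backgrounds are near-identical), which is
the fixture's job.

## Microsynteny

Anchors are reciprocal best hits; a pair is formed only when each side is
the other's *unique* best score, so a recently duplicated paralog that
ties or out-scores the true ortholog removes the pair rather than
mis-anchoring it (on the fixture this occasionally costs the parent pair
itself — the duplicate pair, with its eight fixed residue differences, is
stable). Chaining is a longest-chain dynamic program over anchors sorted
by one genome's order index, with consecutive anchors advancing strictly
by at most `max_gap + 1` ranks in both genomes (mirrored for antiparallel
blocks), greedy extraction of one block at a time by score then leftmost
index, each anchor in at most one block, and blocks under `min_anchors`
(default 3) dropped. Exhaustive enumeration over all chains verifies the
DP on 200 random instances per run.

Presence/absence is asked about the **duplicate lineage**, not the whole
family — the parent is everywhere, so the informative statement is
"duplicate present in the syntenic block of the ingroup genomes only,
tandem-adjacent to its parent". A family id missing from a genome's
annotation is reported distinctly from annotated-but-outside-the-block,
and the six-frame translated scan (stop codons break segments; local
alignment per segment; coordinates back-converted per frame and strand)
exists to tell those apart in real genomes, where annotation gaps are the
rule.

## Expression

TPM follows the standard definition and each column sums to $10^6$;
subsetting genes breaks that invariant, and the package never
re-normalizes silently. The simulated matrices are abundance-scale values
*used as-is*: per-sample re-normalization would apply a different monotone
map to each sample and corrupt the planted cross-sample rank structure.

Spearman correlations use average ranks; p-values are exact by full
enumeration for $n < 8$, seeded Monte-Carlo (10^5 permutations) for
$8 \le n < 10$, and the $t$ approximation with $n - 2$ df above that. The
unnamed "adjusted p-value" of the original analysis is taken to be
Benjamini–Hochberg (the field default; Bonferroni is a config switch).
The low-expression floor is mean TPM ≥ 1 (unstated in the original;
echoed in the output attributes), outlier exclusion (|x − median| >
3·IQR, type-7 quantiles) applies to tissue summaries and plots only —
correlations are computed across all samples — and the reporting
thresholds are strict: rho > 0.65 and adjusted p < 0.05.

Planted modules use a Gaussian copula: module genes load on a shared
latent factor with loading $\sqrt{2\sin(\pi\rho_s/6)}$, giving every
within-module pair population Spearman correlation exactly $\rho_s$ after
the monotone log-normal transform; $\rho_s = 1$ degenerates to exact
comonotonicity. Defaults are $\rho_s = 0.8$ within modules and 146
samples (the study's sample count); at those values the focal gene's
partners are recovered with recall ≥ 0.99 and false-positive rate ≈ 0
across 20 seeded replicates. The within-module correlation is a fixture
choice, not an estimate of real co-expression effect sizes.

## What the synthetic system does and does not show

The generator reproduces the *structure* the analyses assume: a Poisson
substitution process matched to the distance correction, indel-free
homologs (alignments of simulated families are trivially columnar; the
aligner is exercised separately on indel-bearing toys), single-exon genes
on one chromosome per genome, uniform intergenic spacers, log-normal
expression with exact copula correlations, and noise-free annotations.
Passing the end-to-end suite therefore shows the inference chain is
correct *given* those assumptions; it does not show robustness to
alignment error, fragmented assemblies, mis-annotation, multi-exon
structure, rate heterogeneity across sites, or compositional bias. For
real data the intended workflow replaces the weakest in-repo stand-ins
with field tools at the module boundaries — imported MAFFT/MUSCLE
alignments, externally inferred ML trees via Newick — while the clade
tests, residue mapping, chaining, and co-expression statistics operate
unchanged.

## Reproducibility

Every generator and every stochastic routine is a pure function of its
configuration and an integer seed; fixture emission is byte-identical
under a fixed seed, and the pipeline writes each stage's table before the
next stage starts, reusing existing outputs on rerun. Problem sizes in the
shipped tests and acceptance script — 360-residue proteins, 12-gene
blocks, 146-sample matrices, 1000 bootstrap replicates, 100–1000-instance
property batteries — were chosen so a full validation completes in
minutes on a single CPU while keeping every statistical check
well-powered.
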