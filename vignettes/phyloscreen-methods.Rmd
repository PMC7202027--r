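---
title: "Models and methods behind phyloscreen"
author: "phyloscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phyloscreen screens sets of protein-coding gene alignments on a fixed,
rooted species tree for three molecular-evolution signals: convergent and
parallel amino-acid substitutions between designated branch pairs,
positive selection on a focal branch at the codon level, and amino-acid
substitutions unique to a focal lineage. This vignette explains the
models, the numerical strategy, the tunable parameters, and what the
built-in simulator does and does not emulate.

## Substitution models

**Amino acids.** All amino-acid computations use a general
time-reversible model assembled from the published JTT exchangeability
matrix and a choice of equilibrium frequencies: the published JTT
stationary frequencies (`JTT`), the gene's observed residue frequencies
(`JTT-Fgene`, the default for per-gene tests), or one frequency vector
per alignment column (`JTT-Fsite`, used for genome-wide expected-count
nulls, where it yields a deliberately high null expectation and hence a
conservative test). Observed frequencies are smoothed with a pseudocount
(default 0.1 per residue) so that no state has zero mass; columns with no
scoreable residue fall back to the gene-wide vector. Each rate matrix is
normalised to one expected substitution per site per unit branch length,
so branch lengths are expected substitutions per site. Transition
probabilities are computed by symmetric eigendecomposition of the
pi^(1/2)-similarity transform, which is numerically stable for
reversible generators; `P(0)` is returned as an exact identity so that
impossible events have probability exactly zero.

**Codons.** Codon analyses use the Goldman-Yang model on the 61 sense
codons of the standard genetic code: single-nucleotide changes have rate
proportional to the target codon frequency, multiplied by kappa for
transitions and by omega for nonsynonymous changes. Codon frequencies
default to `F3x4` (position-specific nucleotide frequencies), with
`F1x4` and `F61` available. For single-omega and free-ratio fits each
omega's rate matrix is normalised at its own omega (branch lengths are
expected substitutions per codon on that branch). Branch-site mixtures
instead share one time scale referenced at omega = 1, so site classes
with larger omega evolve proportionally faster; without a shared
reference the classes would differ only in substitution composition, not
rate, and the test would lose most of its power.

## Likelihoods and ancestral reconstruction

Site likelihoods come from Felsenstein pruning with per-node rescaling
(log accumulators per pattern), identical machinery for the 20-state and
61-state alphabets. Gaps and ambiguity codes contribute all-ones
partials (missing data). Marginal (empirical Bayes) ancestral posteriors
are computed from one down-pass and one up-pass; the posterior at a node
combines the partial likelihood of the data below it with the "outside"
partial of the rest of the tree, and is invariant to the rescaling. MAP
states break exact ties by fixed alphabetical residue order, making
reconstructions reproducible. Trees must be rooted (an outgroup label
can be supplied to root an unrooted input): substitution classification
needs a parent-to-child direction on every branch.

## Convergence and parallelism

On a branch pair with inferred ancestor/descendant states (a1 -> d1) and
(a2 -> d2), a site is *parallel* if both branches substituted to the same
residue from the same ancestral residue, *convergent* if they reached the
same residue from different ancestral residues, and *divergent* if both
substituted but to different residues. Observed classification uses MAP
ancestral states and observed tip residues; sites where a derived-side
tip carries a gap are excluded, since the ancestral state above a gapped
tip is unidentifiable. Branch pairs must not be nested (one branch
ancestral to the other): independent derivation is undefined along a
single lineage, so such pairs are rejected.

The model-based null follows the expected-count approach: per site, the
probability of a convergent (or parallel) event is a sum over
ancestral-state pairs, weighted by their posteriors, of the probability
that both branches substitute to a common destination satisfying the
class definition. Joint parent posteriors are approximated by the
product of the marginals when the parents differ (exact when shared);
the deviation is second order and covered by the Monte-Carlo oracle
tolerance in the tests. The default integrates over the posterior; a
strict-MAP mode is available. Expected counts are sums of per-site
probabilities, and the observed count is referred to either the exact
Poisson-binomial tail (dynamic-programming convolution, the default) or
its Poisson approximation. Per-gene tests use `JTT-Fgene`; genome-wide
expectations use `JTT-Fsite`. The per-gene significance threshold is
0.05 with no multiplicity correction, mirroring common practice for this
test; the branch-site screen, by contrast, is FDR-corrected.

The genome-wide empirical null regresses summed convergent-plus-parallel
counts on summed divergent counts across all non-nested branch pairs
(terminal pairs by default). Excess is judged by externally studentized
residuals computed from explicit leave-one-out refits — robust where the
held-out fit is exact, which standard studentization handles poorly —
with one-sided t tail probabilities, BH-adjusted across pairs before
flagging. Without that adjustment a null 55-pair set would flag about
three pairs by chance at alpha = 0.05. The divergence axis counts strict
divergent-class sites; the both-substituted total is also reported.

## Branch-site positive selection

The branch-site model has four site classes: 0 (omega0 < 1 everywhere),
1 (neutral everywhere), 2a and 2b (omega2 on the foreground branch,
omega0 or 1 on the background), with class proportions tied in the
standard way: writing s = p0 + p1 and r = p0/(p0 + p1), the four weights
are the products (s, 1-s) x (r, 1-r). The alternative model frees
omega2 >= 1; the null fixes omega2 = 1; twice the log-likelihood
difference is referred to chi-square with one degree of freedom (the
50:50 boundary mixture is available behind a flag, and can only reduce
p).

The fit is two-stage. Branch lengths and kappa are estimated once per
gene under the one-ratio model, rescaling the input tree proportionally,
and then held fixed — except the foreground branch length, which is
re-optimised inside both mixture fits because it interacts directly with
omega2. The product parameterisation makes the class proportions
profile out in closed form by EM given the per-site class
log-likelihoods. The remaining one or two shape parameters (omega0, and
omega2 in the alternative) are optimised by nested golden-section
searches; the full-tree pruning pass depends only on omega0, while
omega2 and the foreground branch length touch only the foreground-edge
contraction, which makes the nested scheme cheap. The alternative's
start set includes the null solution, so the LRT is nonnegative by
construction. This strategy was validated against exhaustive
multi-start direct optimisation of all five parameters (agreement within
1e-3 log-likelihood units). Positive-selection sites are reported as
empirical-Bayes posteriors of classes 2a/2b at the MLEs (NEB); full BEB
prior-averaging is not implemented, a documented difference from
CODEML's site identification.

Omega is capped at 999 and reported ratios use a synonymous-rate floor
of 1e-8, mirroring common guards against division by zero.

## Free-ratio dN/dS

`freeRatioFit(method = "ML")` maximises the GY94 likelihood with shared
kappa and one (t, omega) pair per branch; per-branch dN and dS derive
from the substitution-flux decomposition of that branch's rate matrix,
normalised by the nonsynonymous and synonymous mutational opportunities
computed at omega = 1, so omega = dN/dS holds identically. The
`"counting"` method is a fast approximation used by the screen by
default: fit the one-ratio model, reconstruct marginal MAP ancestral
codons, and count synonymous/nonsynonymous changes per branch with
Nei-Gojobori pathway averaging (stop-codon paths excluded) against
Nei-Gojobori site counts. No multiple-hit correction is applied to the
counting estimates; at the shallow divergences the screen targets the
bias is small. Cross-gene synonymous divergence between the focal branch
and its sister is compared with the Wilcoxon rank-sum test (midranks,
exact enumeration when both samples are of size 10 or less without ties,
normal approximation with continuity correction otherwise); genes with a
zero synonymous estimate on either branch are flagged in the report, not
silently dropped.

## Lineage-specific substitutions

A column is a focal-lineage-specific substitution when every background
taxon carries one identical residue — gaps or ambiguity codes among the
background disqualify the column outright — at least `minBackground`
background taxa are present (default 8 of 10; strict mode requires all),
and the focal taxon differs. Each hit gets a conservation delta score:
the mean over background residues of BLOSUM62(variant, b) -
BLOSUM62(reference, b), called deleterious at or below -2.5. The score
keeps the decision threshold and vocabulary of homology-profile impact
predictors while being computable from the alignment alone; it does not
reproduce the numeric scores of database-backed tools, which search and
align external homolog sets.

## The simulator and what passing tests mean

`simulateProteinGene` and `simulateCodonGene` evolve sites independently
down the tree from an equilibrium root sequence, with optional
per-branch omega or a branch-site class regime (class assignments
recorded as ground truth). `injectConvergence` rewrites the two
subtended clades at sampled eligible sites (parallel: equal stem MAP
states; convergent: differing ones) leaving other taxa untouched, so a
small fraction of injections can be misread by reconstruction — the
tests budget for at most 2 of 10. The default fixture phylogeny is an
11-taxon vertebrate topology (two sister pit-vipers, a five-pacer viper,
other squamates, archosaurs, a turtle, a mammal, a frog outgroup) with
synthetic branch lengths in [0.01, 0.5]; they are labelled synthetic and
are not estimates of real divergences. One master seed drives per-gene
streams through a fixed affine map (`deriveSeed`), so truth tables
reproduce across platforms.

The simulator emulates the statistical structure the analyses assume:
independent sites, a shared topology, no indels (gap handling is tested
via targeted gap-masking), no alignment error, no orthology error, and
no among-site rate variation beyond the branch-site classes. Passing
tests therefore certify the estimators against their own model class;
they do not certify robustness to misalignment, paralogy, or
rate-heterogeneity misspecification, which real transcriptome-derived
data contain.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen for a
single CPU: convergence null calibration on 200 simulated genes of 300
sites (per-gene tests on the comparator pairs; the observed-versus-
expected comparison at the genome-wide scope, aggregated over all
terminal branch pairs, where the site-frequency null is the inflated,
conservative one); injected-parallel recovery on a 5-gene set of
150-site genes, where a 10-site planted excess dominates the natural
scatter of the aggregated pair counts; branch-site size on 100 null
genes (6 taxa, 150 codons) and power
on 20 genes (400 codons, omega2 = 4 on 15% of sites, foreground branch
0.8 substitutions/codon — an informative foreground in the range used by
published branch-site power studies; on much shorter foreground branches
the exact LRT itself, verified by exhaustive optimisation, has power
well below the 0.7 reached here); end-to-end determinism on a 12-gene
11-taxon screen run twice. Optimiser tolerances: one-ratio stage 1e-7
relative; mixture searches 2e-3 on transformed scales with EM profiling
to 1e-8. Frequencies are floored at 1e-10 inside decompositions so
states absent from a gene cannot produce singular transforms. Exact
zero-length branches yield exact identity transitions, so a column that
is impossible under the tree has likelihood exactly zero.

## Known limitations

Marginal (not joint) ancestral reconstruction; NEB rather than BEB site
identification; product approximation for differing-parent joint
posteriors; counting-based dN/dS in the default screen configuration
(full ML available per gene); chi-square df = 1 reference for a boundary
test (conservative); no gamma rate heterogeneity (config extension
point); standard genetic code only.
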