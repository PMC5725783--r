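---
title: "Codon-model selection inference and opsin spectral tuning with opselect"
author: "opselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-model selection inference and opsin spectral tuning with opselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opselect)
```

## What the package does

`opselect` infers the kind and strength of natural selection acting on a
protein-coding gene from a codon alignment and a phylogeny, and predicts the
absorption peak (lambda-max) of visual pigments from the amino acids found
at canonical spectral tuning sites. The motivating application is the
comparative biology of snake visual opsins — the cone opsins *LWS* and
*SWS1* and the rod opsin *RH1* — where primarily diurnal and primarily
nocturnal lineages are expected to experience different functional
constraints, but every component is generic.

## The codon substitution model

The engine implements the Goldman–Yang-style codon model over the 61 sense
codons of the standard genetic code. The instantaneous rate from codon $i$
to codon $j$ is zero if the codons differ at more than one position, and
otherwise

$$q_{ij} = \pi_j \times \begin{cases}
1 & \text{synonymous transversion} \\
\kappa & \text{synonymous transition} \\
\omega & \text{nonsynonymous transversion} \\
\omega\kappa & \text{nonsynonymous transition,}
\end{cases}$$

with $\pi$ the codon frequencies (F3x4 by default: products of
position-specific nucleotide frequencies renormalized over sense codons),
$\kappa > 0$ the transition/transversion rate ratio, and $\omega = d_N/d_S$
the selection parameter: $\omega < 1$ purifying selection, $\omega \approx
1$ neutrality, $\omega > 1$ positive selection. The chain is reversible, so
likelihoods are computed by Felsenstein pruning (in compiled code, with
column pattern compression and per-node scaling) through the symmetric
eigendecomposition of the generator, and are invariant to root placement.
Cells of the alignment are *sets* of codons: IUPAC-ambiguous codons expand
to their compatible sense codons, and any codon containing a gap character
is treated as fully missing and summed over all 61 states (a strict
`cleandata` mode that drops such columns is available; columns are
retained by default).

**Rate scaling.** Branch lengths are measured in expected substitutions per
codon. For every branch the generator mixture present on that branch is
rescaled so that the *mixture-averaged* rate is one; for a single-ratio or
branch model this reduces to unit-rate scaling of each branch's generator,
and for site mixtures it means that high-$\omega$ site classes genuinely
evolve faster than low-$\omega$ classes, as in the standard implementation
of these models.

## Model families

* **Branch models** assign one $\omega$ to each class of a
  `BranchPartition`. The labeling schemes mirror the lineage structure of
  the motivating study: `1w` (one ratio), `2w` (non-snakes vs snakes),
  `3w` (plus henophidians), `4w` (colubrid subfamilies), `4w-activity`
  (primarily diurnal vs primarily nocturnal colubrids), and `free` (one
  ratio per branch). Terminal branches always take their species' class;
  an internal branch takes a class only when one side of its bipartition
  is a pure clade of that class, and otherwise takes the background class
  (the first class of the scheme). This monophyletic-clade convention is
  the default because the branch models are lineage models; a `leaf-only`
  alternative is available. Whether clade stems should be foreground in
  branch-site runs is not fixed by convention; both are reachable through
  the `foreground` argument (by class name, which includes stems under the
  clade convention, or by explicit branch ids).
* **Site models**: M0 (one ratio; identical to `1w`), M1a (nearly
  neutral: $\omega_0 < 1$ and $\omega_1 = 1$), M2a (M1a plus a class with
  $\omega_2 \ge 1$), M3 (three free discrete classes, matching the
  four-degree-of-freedom M3-vs-M0 test), M7 (beta-distributed $\omega$ on
  $(0,1)$, ten equal-probability categories at quantile midpoints) and M8
  (M7 plus a class with $\omega_s \ge 1$). The category count is
  configurable (`nBeta`).
* **Branch-site Model A** and its null: four site classes with proportions
  $p_0, p_1, p_{2a}, p_{2b}$; foreground branches carry $\omega_2 \ge 1$
  in the last two classes while background branches keep $\omega_0$ or 1.
  The null fixes $\omega_2 = 1$ exactly.

$\kappa$ is estimated by maximum likelihood and shared across branches and
site classes. Branch lengths are re-optimized jointly under every model by
default (`optimizeBranchLengths = FALSE` keeps them fixed and removes them
from the parameter count K). Optimization is bounded quasi-Newton
(L-BFGS-B) on transformed parameters — positive parameters on the log
scale, proportions through a unit-box product parameterization,
$\omega \ge 1$ parameters as $1 + e^x$ — with three seeded multi-starts by
default and a relative convergence tolerance of about $10^{-9}$ on the log
likelihood (`factr = 1e7`). Warm starts (`init =` a previous fit) carry
over branch lengths, $\kappa$ and any same-named template parameters,
which both speeds nested model chains and makes the nesting inequalities
hold in practice, since each alternative starts from its null's solution.

## Model comparison

`lrt()` computes twice the log-likelihood difference of a nested pair and
refers it to a chi-square distribution. Degrees of freedom default to the
difference in parameter counts; for the branch-site Model A versus its
null the comparison tables here follow the two-degree-of-freedom
convention by default, with df = 1 available explicitly (which of the two
is statistically preferable is a known open point of that test, and the
package takes no position). Negative statistics within 0.5 log units are
clamped to zero with a warning; anything larger signals mis-ordered models
and errors.

`bic()` computes $-2\ell + K \log n$. The comparison tables use the
base-10 logarithm with $n$ the alignment length in codons, because that
convention uniquely reconciles the published $(\ell, K, BIC)$ triples the
package reproduces in its acceptance checks ($\log_{10} n \approx 2.55$,
i.e. $n \approx 355$ codons); the natural logarithm is available through
`logBase`.

## Positively selected sites

`sitePosteriors()` computes per-site posterior probabilities of the
$\omega$ classes. NEB plugs the maximum-likelihood estimates into Bayes'
rule and is the cheap default. BEB averages the class posteriors over a
coarse grid prior on the mixture parameters — proportions on a triangular
grid, $\omega_0$ on $(0,1)$, the positive-class $\omega$ on $(1,11)$, with
$\kappa$, branch lengths, beta shapes and the rate scaling held at their
MLEs — weighting each grid point by its data likelihood, so uncertainty in
the mixture estimates is propagated. Sites are reported at the 0.95 and
0.99 posterior thresholds (the 0.99 list is nested in the 0.95 list by
construction). Site-specific posteriors for the published real data are
not reproduced here: they depend on the full multi-species GenBank
alignment.

## Spectral tuning prediction

Proteins are numbered by global pairwise alignment (BLOSUM62, affine gaps,
deterministic traceback) against a bovine rhodopsin reference scaffold
shipped with the package, the standard coordinate system for opsin tuning
sites. The canonical sites are: LWS 164, 181, 261, 269, 292; RH1 83, 90,
113, 118, 122, 164, 180, 261, 265, 269, 285, 292, 299; SWS1 86 plus
eleven accessory sites. The default rule sets encode the published
constants:

* LWS: S164/H181/Y261/T269/A292 gives 560 nm; S164A, H181Y, Y261F, T269A
  and A292S shift the peak down by 7, 28, 8, 15 and 27 nm; the published
  combinations S164A (553), S164A+Y261F (545) and S164A+T269A (537) are
  stored directly.
* RH1: D83/A292/S299 gives 500 nm; D83N, A292S, S299A shift down by 6, 10
  and 2 nm; published combinations D83N+S299A (493) and D83N+A292S+S299A
  (483).
* SWS1: F86 confers UV sensitivity (360 nm); F86V is recorded as a
  qualitative violet shift with no numeric magnitude, because none is
  established.

Combination entries take precedence over the additive sum. This is a
deliberate design choice: the published combination peaks deviate from
strict additivity by 1 nm in three cases (537 vs 538, 493 vs 492, 483 vs
482), and the package treats the printed values as authoritative while
`additiveOnly = TRUE` exposes the additive computation. RH1 tuning sites
other than 83/292/299 and the SWS1 accessory sites are extracted and
reported but carry no default shift, since none is established for them.
Unknown (unaligned or deleted) sites assume the base residue and are
flagged rather than suppressing the prediction; substitutions covered by
no rule contribute 0 nm and are flagged as unscored. Heterozygous sites
(IUPAC codons) resolve by Cartesian product into one prediction per
residue combination, capped at a configurable number; an F86V heterozygote
therefore yields both a 360 nm UV pigment and a qualitative
violet-shifted pigment, the two-photopigment situation reported for
*Helicops*. Custom rule tables load from a documented key=value text
format (`readSpectralRules()`).

## The synthetic-data generator

`simulateCodonAlignment()` draws root codons from $\pi$, assigns each site
its mixture class once at the root (recorded as truth), and evolves sites
along every branch under the class's $\omega$ for that branch — for
branch-site classes the foreground $\omega$ applies only on foreground
branches, which is exactly the Model A structure. The generator shares the
model structure code with the likelihood engine but not the pruning path,
so recovery experiments genuinely test the fitting machinery. Identical
seeds give bit-identical data; replicate seeds derive deterministically
from one master seed. `makeOpsinFixture()` back-translates a
bovine-rhodopsin-like protein carrying requested residues at requested
(bovine-numbered) sites — most-frequent codons under a supplied $\pi$,
heterozygous sites as single IUPAC codons, optional N-terminal extensions
and deletions — and attaches a truth record built from the construction,
independent of the extraction pipeline.

What the generator emulates: branch- and site-heterogeneous $\omega$ on a
labeled tree under the exact model family the engine fits, and opsin
coding sequences with known tuning residues and indel decorations. What it
does not emulate: alignment error, recombination, indel evolution,
sequencing error, codon usage beyond the stationary frequencies, and
among-site rate variation outside the specified $\omega$ classes. Passing
recovery tests therefore demonstrate the correctness of the inference
machinery under its own assumptions, not robustness to the ways real data
violate them.

## Study conditions used by the tests and acceptance script

The simulation checks run at sizes chosen to exercise the statistics
properly on a desk machine:

* One-ratio recovery: the 7-taxon study-shaped tree (two outgroups, one
  henophidian, two diurnal and two nocturnal colubrids), L = 2000 codons,
  truth $\omega = 0.2$; the estimate is required within $\pm 0.05$.
* Activity-pattern contrast: truth $\omega$ = 0.071 / 0.154 / 0.161 /
  0.391 for the four lineage classes (the published rod-opsin estimates),
  L = 2000, 20 replicates; the diurnal < nocturnal ordering must be
  recovered in at least 18.
* LRT calibration: a 6-taxon tree, L = 150 codons, truth $\omega = 0.3$
  under the one-ratio null, 200 replicates of the two-ratio test; the
  rejection rate at $\alpha = 0.05$ must fall inside the binomial 95%
  bounds. L = 150 keeps 200 replicates comfortably within a desk-scale
  run while leaving roughly 100 substitution events per branch class,
  plenty for the asymptotic chi-square approximation.
* Engine oracle: pruning equals brute-force enumeration over all
  internal-state assignments on random instances with up to 4 taxa and 3
  sites (tolerance $10^{-8}$), with transition matrices from an
  independent matrix-exponential implementation.

## Numerical choices and degenerate inputs

Codon frequencies are floored at $10^{-8}$ (F3x4) or carried with a
pseudocount (F61) so the symmetrized generator stays well-conditioned.
Transition-matrix entries are clamped at zero and rows renormalized to
absorb eigendecomposition round-off. Zero-probability site patterns abort
with the offending pattern reported. Zero branch lengths, single-site
alignments, two-taxon trees and empty spectral inputs are all legal;
sequences ending in a stop codon have the stop trimmed with a message, and
internal stops are errors naming the taxon and column. Codon columns are
reported 1-based everywhere; branch identifiers are the sorted leaf set on
the smaller side of the split a branch induces, which makes them stable
under leaf reordering and re-rooting of the input file.

## Known limitations

The free-ratio model on large trees and BEB on long alignments are the
expensive corners; both scale linearly in alignment patterns. K counts
parameters actually optimized, so fixed branch lengths change K (by
design). The bovine reference scaffold anchors numbering only; predictions
depend on the rule tables, not on the scaffold's residues. No
multiple-testing correction is applied across genes or comparisons, no
AIC/AICc is offered, and counting-based dN/dS estimators, nucleotide and
amino-acid models, and tree search are out of scope: the tree is an input.
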