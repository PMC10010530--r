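---
title: "Trajectory-aware inference of Potts fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-aware inference of Potts fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the approximations it makes, the parameters that matter, and what the
synthetic fixtures do and do not establish.

## The evolutionary model

A directed-evolution experiment iterates mutagenesis and selection on a
population of coding sequences. `evoscape` models one lineage per round
as a Markov transition over the space of codon sequences (61 sense
codons per position; stop codons are excluded from the state space, and
transitions into them are treated as lethal and renormalized away):

$$p(x \to y) = \frac{g(x \to y)\,\pi(y)}{\sum_z g(x \to z)\,\pi(z)}$$

Three assumptions make this tractable, and each is an explicit, tested
contract of the code:

* **Known, independent mutation process.** Mutations act independently
  at each DNA base with a known substitution bias; the codon kernel
  `g_i` is the three-fold product of per-base transitions, identical at
  every position and every round (time-homogeneity). The bias ships as
  data (a 4x4 TSV), never as code. The packaged default table is a
  constructed, transition-dominated Taq-style error-prone PCR spectrum,
  labelled synthetic; it is scaled so the expected number of DNA
  substitutions per gene per round matches a target load (default 4).
* **Relative fitness only.** The landscape is a Potts model over amino
  acids, $\log \pi = \sum_i h_i(a_i) + \sum_{i<j} e_{ij}(a_i,a_j)$ up to
  a constant. The normalizer over $61^L$ sequences is never evaluated;
  everything downstream uses score differences.
* **Lineage-local selection.** Selection acts among a parent's direct
  descendants, not across the whole population. The scalable simulator
  draws a brood of B mutagenized offspring per parent and keeps one with
  probability proportional to fitness (sampled exactly with the
  Gumbel-max trick); as B grows this converges to the transition law
  above, and a dedicated test verifies total-variation agreement with
  the exactly enumerated kernel at L = 1, B = 1000.

On enumerable spaces the package computes the transition kernel exactly
(`exact_kernel`, `propagate_exact`); these are the oracles against which
both the simulator and the moment recursion are tested.

## Moment propagation and the matching loss

Exact likelihoods are intractable, so inference works on first- and
second-order codon marginals. A recursion propagates round-r marginals
to round r+1 through the mutation kernel and the landscape's own
marginals $\mu$; the pairwise version uses the product kernel over the
two positions and the landscape's pair marginal — no higher-order
terms. The recursion preserves normalization algebraically (asserted to
1e-9 on every call, tested at 1e-12) and is *exact* when the landscape
factorizes over sites, which the test suite confirms against exact
enumeration at machine precision. With couplings it is an
approximation; its quality degrades gracefully with interaction
strength.

The landscape marginals are parameterized at the amino-acid level by
per-site and per-pair softmax parameters $\gamma$; codon-level marginals
divide each amino acid's mass equally among its synonymous codons, so
synonymous uniformity holds by construction. Starting from a point mass
at the wild type (the experiment's round 0), the predicted marginals at
each sequenced round are matched to the observed frequencies with an
aggregated log-loss, plus:

* l2 penalties on $\gamma$ (defaults: 1e-3 for site terms, 1e-2 for
  pair terms). As with ridge strengths in direct coupling analysis, the
  pair regularizer must be scaled to the data regime: with a few
  thousand sequences per round and hundreds of candidate pairs, weak
  values (1e-4 is appropriate for much larger sequence sets) let the
  pair parameters absorb drift-generated linkage noise — on the planted
  fixtures this visibly destroys coupling recovery while the training
  loss keeps improving, whereas 1e-2 keeps recovery stable across
  hundreds of optimization steps,
* a local-consistency penalty with multiplier $\rho$ = 1e5 tying each
  site marginal to the average of its pair-marginal margins. The
  printed form of this penalty is a norm of a scalar residual per
  (site, amino acid); the package uses the *squared* residual so the
  analytic gradient is smooth everywhere — at a consistent optimum both
  forms vanish identically.

Gradients are derived by hand in reverse mode (the chain runs backward
through all rounds of the recursion, then through the softmax
reparameterization); a finite-difference check at relative 1e-4 is part
of the acceptance suite. The pairwise forward/backward pass is compiled
(RcppArmadillo) because it is the computational bottleneck: per
optimization step it performs a few thousand 61x61 matrix sandwiches.

The optimizer is Adam with learning rate 0.03; initialization is the log
of the last sequenced round's amino-acid frequencies plus a 1e-6
pseudocount. Stopping deserves a note. The training loss decreases
essentially monotonically for many hundreds of steps, but the pair
parameters begin absorbing per-round *sampling noise* long before that:
on the planted fixtures, coupling recovery improves for roughly the
first five hundred steps and then degrades sharply if training
continues, while the training loss keeps falling throughout. A plateau
rule on the training loss therefore stops far too late. The package
implements early stopping in its standard machine-learning sense: a
fraction (default 10%) of each round's sequences is held out, the
held-out log-loss is evaluated every 20 steps, optimization stops after
two consecutive evaluations whose relative improvement falls below
1e-4, and the best-validation parameters are returned. The step cap
(default 500) bounds the desk-scale fit to around ten minutes on one
CPU; on the planted fixtures the recovered interaction ranking is flat
from roughly step 150 onward under the default regularization, so the
cap is not a sensitive choice. When the fit is given
only frequency tables (no sequences to split), the training-loss
plateau rule is used instead. All of these are `inference_config()`
fields.

## From mean to canonical parameters

Canonical parameters come from regularized mean-field inversion: the
connected-correlation matrix over L x 19 non-reference amino-acid
dimensions gets `lambda_reg` (default 50) added to its diagonal and is
inverted; couplings are the negated off-diagonal blocks, fields follow
from the mean-field self-consistency relation. Two numerical choices
matter:

* **Reference state.** Each site's reference is its most probable amino
  acid under the fitted marginals, not the wild-type residue: at sites
  where the population has swept, the wild-type state can carry
  probability ~0.01 and anchoring the gauge there is badly conditioned.
  Score differences and mutation-effect maps are unaffected by this
  choice; the Frobenius ranking is measurably more stable.
* **Regularization scale.** `lambda_reg` should exceed (several-fold)
  the magnitude of the most negative eigenvalue of the estimated
  correlation matrix, which is not positive semidefinite because the
  fitted marginals are only approximately globally consistent. Large
  values shrink couplings toward (a gauge of) the raw connected
  correlations; the default 50 is deliberately conservative and the
  ranking-based analyses are insensitive to it over a wide range.

Interaction scores convert couplings to the zero-sum gauge (each block's
row and column sums vanish; gauge identities tested to 1e-10) and take
Frobenius norms. Only long-range pairs (sequence separation > 5) are
ranked; contact PPV is evaluated at the top floor(L/2) ranks against 5 Å
and 8 Å thresholds with the long-range contact density as the chance
baseline.

## Epistasis and adaptive walks

Double-mutant epistasis is classified from score differences: for
mutations at i and j, only the (i, j) coupling block distinguishes each
mutation's effect in the two backgrounds, so the classifier runs in one
19x19 block operation per coupled pair and uncoupled pairs are additive
by construction (a brute-force four-genotype enumeration is the test
oracle). Effects below a 1e-9 tolerance are treated as zero and never
count as sign flips — the field convention for "beneficial/deleterious"
gives no rule for exact ties, and strict flips on numerical zeros would
be noise.

Adaptive walks are deterministic steepest-ascent: evaluate all single
(or single and double) mutants via incremental score updates, accept the
best strictly improving move, stop at a local peak. Ties break toward
single moves, then the lowest position, then alphabetical amino acid.
Endpoints are verified locally optimal by exhaustive re-scoring in the
tests. Walks operate at the amino-acid level; codon accessibility is not
imposed, matching how such simulations are normally run.

## The synthetic fixtures: what they show and what they do not

`generate_landscape` plants a sparse truth: i.i.d. normal fields
(sd 0.3) and five long-range coupled pairs with zero-sum-gauged blocks
of graded strength (coupling scale 1.5 times multipliers 0.7–1.3). The
grading makes "is the relative order of planted strengths recovered?" a
well-posed question; equal strengths would be statistically tied. The
field scale was calibrated once, at the data level, so that the planted
couplings leave a visible covariation signal in samples of 2000
sequences per round: with stronger fields the population sweeps to the
field optimum at coupled sites and *no* method could see the couplings.
That calibration is recorded here and in the fixture manifest, and then
frozen. The wild type starts three substitutions off the additive
optimum, and the planted contact map assigns coupled pairs 4 Å and all
other long-range pairs 10 Å, so contact PPV has exact ground truth.

The default study conditions are desk-scale: L = 30 residues, 8 rounds,
population 5000, brood 100, 2000 sequences sampled per round, 4 DNA
substitutions per gene per round. A full-protein profile (L = 186,
rounds sequenced 1–5 and 15, 1e5 reads) is expressible with the same
functions but is deliberately not a default: the end-to-end fit at desk
scale takes a few minutes on one CPU, and the recovery statements in the
test suite are made at that scale only.

What passing the fixture tests does *not* show: real sequencing data
have read errors, indels, coverage bias and unknown mutation spectra,
none of which the generator emulates; real selection acts globally
across the population (the quasispecies regime), not only within broods;
and real landscapes are not five sparse planted blocks. The fixtures
validate the inference machinery against its own model assumptions —
they are necessary, not sufficient, for trust on real data.

## Known limitations

* The moment recursion is exact only for factorized landscapes; with
  strong couplings its bias propagates into the fitted marginals.
* The overall scale of the landscape is only weakly identified by
  trajectory data (dynamics change under rescaling, unlike equilibrium
  ensembles, but finite rounds constrain the scale loosely); all
  recovery claims are rank-based, and fitted coupling magnitudes are
  shrunk heavily by `lambda_reg`.
* Per-position mutation-kernel overrides are supported for the
  first-order machinery but not in the pairwise recursion, which assumes
  the shared kernel.
* Sequences with ambiguity codes are rejected, not imputed; indels are
  out of scope throughout.
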