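---
title: "Error-aware branch-site tests for episodic diversifying selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-aware branch-site tests for episodic diversifying selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Branch-site codon models detect episodic diversifying selection (EDS) by
asking whether some fraction of (branch, site) pairs in a protein-coding
alignment evolved with dN/dS (omega) above 1.  The likelihood-ratio test is
exquisitely sensitive to exactly the signal that alignment and assembly
errors produce: a handful of codons in one sequence that disagree wildly
with their column.  A non-homologous segment, a frame shift, or a stretch
of mis-called bases injects apparent non-synonymous substitutions at a rate
no biological process sustains, and the unbounded selection class of the
mixture happily absorbs them, producing confident false positives.

`bustede` implements the error-aware extension of the BUSTED family: the
omega distribution gains an "error-sink" class whose rate is bounded below
by a large constant and whose weight is capped at a small value.  The sink
gives abiological substitution patterns somewhere to go that is *not* the
selection class, which restores the interpretability of the EDS test; its
posterior footprint also identifies which codons look error-like, which
drives an explicit masking filter.

## The model

Codon substitution follows the MG94xREV parameterization over the 61 sense
codons of the universal code.  For a one-nucleotide change from codon `a`
to codon `b` (source nucleotide `i`, target `j`, codon position `k`), the
instantaneous rate is

* `alpha * theta_ij * pi_jk` if the change is synonymous,
* `alpha * omega * theta_ij * pi_jk` if non-synonymous,
* `0` for multi-nucleotide changes,

with five free symmetric nucleotide exchangeabilities (`theta_AG = 1` for
identifiability) and position-specific equilibrium frequencies `pi_jk`
estimated by the stop-codon-corrected F3x4 procedure: the 3x4 frequency
table is solved so that the stop-excluded codon distribution it implies
reproduces the observed position marginals (raw counts are biased because
stop codons never occur in frame).

Rate variation is two-dimensional:

* the synonymous rate `alpha(s)` varies across sites, following an
  M-bin general discrete distribution (GDD) constrained to unit mean
  (default `M = 3`);
* `omega(s, b)` is drawn independently for every (branch, site) pair from
  an N-bin GDD with ordering `omega_1 <= omega_2 <= 1 <= omega_3` (default
  `N = 4` including the sink).  The error-sink class obeys
  `omega_4 >= E` (default `E = 100`) and carries weight at most `p_e_max`
  (default 1%).

Because omega draws are independent across branches, the pruning recursion
can run on per-branch *marginal* transition matrices, the class-weighted
mixture of the per-class matrices.  This equivalence is the engine's
central correctness claim and is tested against an enumeration oracle
(ancestral states x per-branch class assignments, transition matrices from
`Matrix::expm`) on all tree shapes up to four taxa.

### Branch lengths and normalization

Branch lengths are expected nucleotide substitutions per site.  The
generator is rescaled by a single normalization constant per fit, computed
from the weighted-mean generator (expected omega, alpha = 1) and divided by
three to convert codon events to nucleotide-position units.  The reference
mean is frozen at the single-class (phase-3) estimate: recomputing it from
the current mixture mean would let a small-weight, extreme-rate class
rescale every branch simultaneously, which both distorts the likelihood
surface and (empirically) pushes the sink weight to zero even on corrupted
data.

Trees are treated as unrooted.  Because each branch carries its own omega
draw, the branch structure is part of the model: a degree-2 root (two
independent draws) is not equivalent to the merged unrooted branch (one
draw).  Input trees are therefore collapsed and unrooted on ingestion, after
which the likelihood is invariant to the computational root.

### Missing data

Any codon containing a gap or ambiguity character is treated as fully
missing: the likelihood marginalizes over all 61 states.  Partial
ambiguity resolution is out of scope.  In-frame stop codons are an input
error, reported with taxon and 1-based codon column.

## Fitting

Mixture likelihoods of this kind are riddled with local optima, so the fit
is staged:

1. nucleotide GTR fit (branch lengths, exchangeabilities);
2. single-class MG94 fit of the mean omega with phase-1 estimates fixed;
3. joint refinement of branch lengths, exchangeabilities, and the mean;
4. `K` Latin-hypercube draws of the two GDDs (default `K = 250`), with the
   omega mean pinned to the phase-3 estimate and the alpha mean to 1;
5. likelihood screening of all draws, keeping the best `P` (default 5);
6. "quick and dirty" Nelder-Mead polish of each survivor, stopping when an
   iteration improves the log-likelihood by less than
   `max(0.5, 1e-4 |logL(phase 3)|)`;
7. full joint optimization from the winner: coordinate-block ascent over
   (distributions | exchangeabilities | branch lengths), Nelder-Mead for
   the distribution block, a quasi-Newton step for the biases, and a
   Jacobi-style per-branch sweep (golden-section on each branch against an
   eigen-coefficient form of its 1-D profile likelihood) for the lengths.

When BUSTED-S and BUSTED-E are both fitted, the plain fit runs first and
its solution seeds half of the error-model's proposal set, with the sink
parameters drawn randomly.  Null fits (selection class pinned to
`omega = 1`) warm-start from their alternative; if a warm-started null
overtakes its alternative (possible under reduced optimizer budgets), the
alternative is re-polished from the null's solution so the nesting
inequality always holds.

Three further numerical choices matter:

* **Rate caps.** Selection and sink rates are capped at `1e4` above their
  lower bounds.  Transition probabilities saturate at the stationary rows
  far below that, so larger values are likelihood-indistinguishable but
  destroy the eigendecomposition numerically.
* **Basin probes.** The error-sink surface is label-degenerate: a
  saturated selection class fits error-like codons exactly as well as the
  sink does.  After the first block round the optimizer therefore polishes
  up to two extra candidates -- the incumbent with the sink loaded to its
  cap, and (when the fitted "selection" rate is itself `>= E/2`) the
  relabeling that demotes that mass into the sink, accepted within a
  0.1 logL tie.  Probes only ever replace the incumbent when the resulting
  likelihood justifies it, so genuine selection is never demoted.
* **Boundary snap.** The logistic weight parameterization cannot reach an
  exact zero, so fits that do not need the sink would otherwise report a
  spurious residue of order `1e-4`.  If removing the sink entirely costs at
  most 0.01 logL, the weight is snapped to numerical zero.  On clean data
  nearly all fits snap, reproducing the expectation that the error model
  usually collapses to the plain one.

## Testing and model averaging

The EDS test constrains `omega_3 = 1`, refits, and refers
`2 (logL_alt - logL_null)` to the conservative chi-squared distribution
with 2 degrees of freedom, whose tail is `exp(-LRT/2)`.  At `LRT = 0` the
reported p-value is capped at 0.5, the one-sided maximum; the raw
chi-squared tail (1 at zero) is also reported, since the two conventions
conflict only at the boundary.  The same machinery compares BUSTED-E
against BUSTED-S (nested via a zero sink weight), acknowledging that the
boundary-aware mixture distribution would be less conservative.

Because the extra error class costs power on clean data, the final
significance call averages the two models: Akaike weights
`w ~ exp(0.5 (min AICc - AICc))` computed from the small-sample AICc
(sample size = sequences x codon sites; the free-parameter ledger is
emitted with every fit so the counting convention is auditable), and
`p(MA) = w_S p_S + w_E p_E`.  In the worst case -- no log-likelihood gain
for two extra parameters and `p_E` at its maximum 0.5 -- the error model
contributes `0.5 exp(-2)/(1 + exp(-2)) ~ 0.0596 <= 0.06` to `p(MA)`.

## Error filtering

For every (branch, site) pair the site likelihood is recomputed `N` times
with that branch's omega forced to each class (everything else fixed at the
MLEs), via an inside-outside recursion whose total cost is about `N`
full-alignment likelihood passes.  Weighting by the fitted class priors and
normalizing gives empirical Bayes posteriors, from which two Bayes factors
are formed: `EBF_e` (error class against all others, posterior-to-prior
odds) and `EBF_s` (error against the selection class).  A pair is masked
when `EBF_e >= C1` (default 100) *and* `EBF_s >= C2` (default 20), both
inclusive.  Terminal branches mask the observed codon; internal branches
mask all observed codons in the smaller of the two leaf sets the branch
separates (ties broken toward the side away from the computational root,
recorded in the report).  If strictly more than `C3` (default 0.4) of a
site's observed codons end up masked, the whole column is masked.  A fitted
sink weight below `1e-8` means the error class is uninstantiated; empirical
Bayes factors against a vanishing prior are meaningless, so nothing is
masked.  Raising `C1`/`C2` or lowering `C3` can only shrink the masked set.

## The simulator

`simulate_alignment()` generates alignments under the same process the
likelihood assumes: per-site alpha classes, independent per-(branch, site)
omega classes, a root codon from the stationary distribution, and
transitions sampled down the tree in a deterministic preorder (children
ordered by smallest descendant label) from a single seeded RNG stream, so a
seed fully determines the FASTA bytes.  `inject_error_segment()` overwrites
a chosen taxon's segment with uniform random sense codons (or a
frame-shifted copy) and returns the truth mask; it deliberately models the
alignment-error modality that the filter targets and is not part of the
generating model.

What the simulator does *not* emulate: indels and alignment uncertainty,
multi-nucleotide mutations, site-to-site rate autocorrelation,
composition heterogeneity across lineages, and recombination.  Passing
tests on simulated data therefore validate the estimator and filter under
the model's own assumptions, not robustness to every real-data pathology.

## Study conditions used by the test suite

The statistical checks run at reduced but informative sizes, chosen once:

* constraint enforcement and type-I error: 100 null-profile replicates
  (omega = {0.1, 0.6, 1.0} with weights {0.6, 0.3, 0.1}, unit-mean
  three-class alpha), 8 taxa x 200 codons;
* power and model averaging: omega_3 = 5 at 5% weight, 16 taxa x 400
  codons, 25 replicates;
* filter end-to-end: 10-codon uniform-random segments injected into a
  taxon on a short (0.01 subs/site) terminal branch of a 16-taxon tree,
  400 codons, 10 replicates -- errors between close relatives are the
  conspicuous, realistically detectable modality, whereas junk on a long
  branch is genuinely confusable with saturation;
* generating-model recovery: 16 taxa x 2000 codons.

Optimizer budgets in the suite (`K`, simplex iterations, block rounds) are
reduced relative to the production defaults; every inequality asserted was
chosen from the model's properties, not tuned to a particular run.

## Limitations

* The error-class bounds `E` and `p_e_max` are fixed hyperparameters, not
  estimated.
* Branch-partitioned (foreground/background) omega distributions are not
  implemented.
* Multi-nucleotide substitution processes are out of scope; genuinely
  multi-hit biology can resemble error and will occasionally be flagged.
* The chi-squared(2) reference distribution is conservative at the
  boundary; no parametric bootstrap is provided.
* On data where a saturated selection class and the sink are exactly
  interchangeable, the reported labeling follows the probe tie-break
  described above.
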