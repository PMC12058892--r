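---
title: "Extracting transitive preference states: models and methods in korders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting transitive preference states: models and methods in korders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(korders)
```

## The data and their representation

A forced-choice paired-comparison (FCPC) experiment presents every
unordered pair of options exactly once and forces a choice, so a complete
respondent record is an asymmetric, complete binary relation on the option
set: one ordered pair per stimulus. `korders` encodes such a relation as a
0/1 vector over a fixed canonical pair order (lexicographic by option
index), with bit 0 meaning "the lower-indexed option was preferred". This
encoding is asymmetric and complete *by construction* — invalid relations
are unrepresentable — and the canonical distance $|X \Delta C|$ between two
relations is exactly twice the Hamming distance between their bit vectors.
A historical aside: the traditional tabulation of the eight relations on
three options uses an inconsistent orientation for its third bit; the
package applies the uniform reference-orientation rule everywhere and the
test fixtures therefore identify relations by their pair *sets*, never by
legacy vector labels.

Missing responses are out of scope: the clustering operates on complete
cases only, and `read_dataset()` rejects (and counts) incomplete rows.

## The clustering model

The population is assumed to be a finite mixture of *preference states*
(asymmetric complete relations; under the transitivity assumption, strict
linear orders). Dichotomous $k$-modes alternates (i) minimum-discrepancy
classification — each pattern's frequency split equally among its closest
centroids, which minimizes the overall discrepancy
$D_f = \sum_C \sum_X f(X,C)\,|X \Delta C|$ for fixed centroids — and (ii)
per-cluster centroid adjustment. The element-wise mode minimizes the
within-cluster distance over *all* relations, but aggregated pairwise
majorities can cycle even when every member of the cluster is transitive,
so modal centroids need not be orders.

The k-orders variants keep step (i) and replace step (ii):

* **Path-finding TCA.** Within a cluster $(\mathcal G, p)$ the average half
  distance of an order $L$ satisfies the pair-marginal identity
  $d(L,\mathcal G) = \sum_{(a,b) \notin L} p(a,b)$, so inverting a pair
  $(a,b) \in L$ changes $d$ by $p(a,b) - p(b,a)$: the flip helps exactly
  when $(a,b)$ is non-modal ($p(a,b) < 1/2$). TCA starts from the cluster's
  current centroid and repeatedly flips the *free* pair (one whose
  inversion keeps the relation in the admissible class) with the smallest
  marginal below 1/2, until all free pairs are modal. Each step strictly
  decreases $d$, so the procedure terminates at a local minimum.
* **Greedy TCA.** All $n(n-1)$ ordered pairs are processed in decreasing
  order of $p$, inserting a pair whenever the relation stays acyclic
  (reachability is maintained incrementally, $O(n^2)$ per insertion). The
  output is always a strict linear order and a local minimum. Unlike TCA it
  ignores the previous centroid, so it can jump between basins; the run
  driver therefore accepts an adjustment pass only if the overall
  discrepancy improves, keeping the recorded trace non-increasing.

**Free pairs.** The exported `free_pairs()` uses the generic membership
test (flip, then check transitivity and, under MA, pointwise-order
containment). The clustering inner loop uses the equivalent
characterization that the free pairs of a strict linear order are exactly
the adjacent transpositions of its ranking (minus the pointwise-order pairs
under MA); a property test asserts the equivalence, and the shortcut turns
each TCA step into an $O(n)$ scan.

**Monotonicity constraint.** For two-component designs the admissible class
is the linear extensions of the pointwise order $P_0$ (componentwise
dominance, "preferred = less severe", level 1 least severe). Following the
marginal-forcing prescription, $p$ is set to 1 on $P_0$'s pairs for both
adjustments; for greedy TCA the implementation additionally pre-inserts
$P_0$ itself. The two are equivalent when the forced marginals are the only
ones at 1, but data marginals can also reach exactly 1 (a unanimous
cluster), in which case a unanimous non-$P_0$ pair processed earlier could
block a $P_0$ pair and break the constraint; pre-insertion removes that
failure mode, which we observed in practice on clean two-component data.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` / `init` | — | number of initial centroids, or an explicit structure; k-orders inits are random orders (random linear extensions under MA), k-modes inits uniform random relations |
| `tol` | 0 | stop when the improvement of the integer-valued overall discrepancy is ≤ `tol`; 0 means "no improvement", which terminates because the discrepancy takes finitely many values |
| `max_iter` | 100 | cap on adjustment passes; runs converge in a handful of passes in all regimes we exercised |
| `interval` (betas) | — | half-open $(\beta_{lo}, \beta_{hi}]$ range of per-ordered-pair inversion probabilities, capped at .5 |
| `k_max`, `n_partitions`, `criterion` | —, 1, `"validation"` | incremental-extension depth, number of 2/3–1/3 partitions, and whether the max-distance criterion is computed on the validation or the training side |
| `n_boot` | 1000 | parametric-bootstrap replicates for the BLIM goodness of fit |
| EM `tol`, `max_iter` | 1e-6, 2000 | log-likelihood convergence of the BLIM fit |

Deterministic tie rules (reproducibility): TCA picks the lowest canonical
pair index among equally minimal marginals; greedy's processing order
breaks marginal ties by reference orientation first, then pair index
(making the order injective); k-modes resolves $\theta = 1/2$ by a fair
coin from the run's RNG stream, the only stochastic element of the
iteration itself. Selection ties in the max-distance criterion go to the
smallest cardinality (parsimony).

**Degenerate inputs.** A cluster that receives no mass keeps its centroid
during the run (flagged) and is dropped at termination if still empty;
duplicate adjusted centroids are merged, so extracted structures are sets.
BLIM error parameters are clipped to $[10^{-6}, .5 - 10^{-6}]$ — a rate
above 1/2 would re-encode the state — and an orientation appearing in no
state has zero expected denominator and keeps its current value.

## The synthetic-data generator

`generate_dataset()` reproduces the generative design used throughout: a
uniform (or user-specified) mixture over $c$ states; per *ordered* pair an
inversion probability $\beta_{ab}$ drawn uniformly in a half-open interval
and held fixed across respondents; independent inversions across stimuli.
One-component structures are uniform random permutations; two-component
structures are random linear extensions of $P_0$, built by repeatedly
adding a uniformly chosen admissible incomparable pair — a procedural
sampler that is *not* the uniform distribution over linear extensions
(documented deliberately: it mirrors the reference procedure rather than
uniform-extension sampling). Duplicated draws are redrawn so a structure of
cardinality $c$ has exactly $c$ distinct states.

What the generator does **not** emulate about real data: missing and
attrition patterns, correlated errors across stimuli (local independence is
assumed both in generation and in the BLIM), respondent-level error
heterogeneity, and order/context effects of stimulus presentation. Passing
recovery tests on this generator therefore demonstrates correctness of the
machinery under the stated model, not robustness to those violations.

## Model selection

`korders_select()` repeats: respondent-level 2/3–1/3 split; incremental
extension on the training side — the $k{+}1$-state candidate seeds the
previous solution plus the training pattern farthest from it, projected
into the admissible class by greedy TCA on its singleton cluster
(farthest-first seeding; the projection detail is our design choice where
the reference defers to earlier work, and any rule with the same signature
can be substituted); rescoring of every candidate by
$M = \max\{\delta(V, P), \delta(P, V)\}$ with the evaluation patterns
treated as a set of distinct patterns (a frequency-weighted variant is
available but off by default). The training-criterion variant
(`criterion = "train"`) mirrors the simulation protocol in which the
validation side is not used. Within-train discrepancy is provably
non-increasing in the candidate's cardinality because each candidate is
initialized at the previous solution plus one state and only improving
passes are accepted.

## The BLIM

States are latent classes; each ordered pair $(a,b)$ carries one error
parameter $\beta_{(a,b)}$ — the probability of observing $(b,a)$ given the
state contains $(a,b)$ — and the preference coupling
$\eta_{(a,b)} = \beta_{(b,a)}$ is structural (a single stored parameter per
orientation, $2\binom{n}{2}$ in total), so the free-parameter count is
$(|\mathcal P| - 1) + 2\binom{n}{2}$. EM runs on pattern frequencies with
closed-form M-steps; the log-likelihood trace is non-decreasing and is
asserted as such in the tests.

The Pearson goodness-of-fit statistic needs a cell scheme; the full
$2^{|Q|}$ table is unusable beyond toy sizes. The package uses each data
set's *own* distinct observed patterns plus one pooled cell for everything
else, applying the same rule to every bootstrap replicate. The rule-based
scheme matters: fixing the original data's cells for the replicates makes
the observed statistic stochastically larger than the bootstrap ones (the
original's pooled cell is zero-observed by construction) and pushes p
values toward 0; with the per-data-set rule the observed and replicate
statistics are identically constructed and the bootstrap p values are
calibrated, which the acceptance suite checks distributionally (20
replicates under a true model: mean p in [.3, .7], spread well above a
degenerate one).

## Evaluation indexes

$\delta(\mathcal A, \mathcal B)$ averages, over the states of
$\mathcal A$, the minimum canonical distance to $\mathcal B$; it is
asymmetric and 0 exactly when $\mathcal A \subseteq \mathcal B$. Its range
is $[0, 2\binom{n}{2}]$ (a half-distance variant normalizing the minimum
separation to 1 is available for comparison). The true-positive rate
counts exact (bitwise) state matches; `tpr()` defaults to the *truth*
denominator — the share of true states recovered — which is the reading
consistent with the reported recovery levels and with the index's verbal
definition, while the extracted-structure denominator remains available
(`denominator = "extracted"`). With over-extraction (selected structures
larger than the truth) the two differ materially, and the
extracted-denominator variant is arithmetically bounded above by
$|\mathcal P| / |\hat{\mathcal P}|$.

## Problem sizes used by the test suite

The suite exercises exhaustive oracles where enumeration is cheap (all
relations up to 4 options, all linear orders up to 5, brute-force global
minima on 24 orders) and scales the replication studies to run on one CPU:
the selection study at 20 replicates per error condition with `k_max = 50`
(five times the generating cardinality; the reference analyses used larger
caps and 100 replicates, so agreement is distributional, not exact), the
method-ordering comparisons at two replicates per error interval, and the
BLIM calibration at 20 replicates of 200 bootstrap samples. These sizes are
the package's choice of a representative, quickly reproducible design;
rerunning with larger counts only tightens the Monte-Carlo error.

## Known limitations

* Both TCA variants guarantee local, not global, optimality; cold-started
  runs are sensitive to initialization (the greedy variant less so, as its
  adjustment is start-independent). The brute-force comparison in the
  acceptance suite reports global-minimum hit rates rather than asserting
  a threshold, and the incremental-selection pipeline is the recommended
  way to spend extra computation.
* Ties, incomplete relations and weak orders are unsupported by design.
* The BLIM identifiability is not formally tested (the Jacobian grows with
  $2^{|Q|}$); fits report convergence and likelihood only.
* The graph export views a structure only through distance-2 adjacency;
  richer layouts are left to downstream tools.
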