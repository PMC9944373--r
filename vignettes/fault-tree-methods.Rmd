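---
title: "Fault-tree methods for sociotechnical risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fault-tree methods for sociotechnical risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpra)
```

## The model

Sociotechnical probabilistic risk assessment (ST-PRA) models an adverse
outcome — here, a patient fall in a psychiatric seclusion room — as the
*top event* of a fault tree: a directed acyclic graph of AND/OR logic
gates over *basic events*, the individual risk factors. An AND gate
fires only when all of its inputs occur; an OR gate when any input
occurs. Writing $x_e \in \{0,1\}$ for the state of risk factor $e$, the
tree defines a monotone (coherent) Boolean structure function
$\phi(x)$; the quantity of interest is
$P(\text{top}) = \Pr[\phi(X) = 1]$ under independent Bernoulli risk
factors $X_e \sim \mathrm{Bern}(p_e)$.

Under independence, gate-level combination is

$$P_\text{AND} = \prod_i p_i, \qquad
  P_\text{OR} = 1 - \prod_i (1 - p_i),$$

the OR form being exactly "add the probabilities and subtract the
overlap" by inclusion–exclusion. Gates are n-ary: a conjunction or
disjunction may span any number of factors. Single-input gates are
accepted with a warning because intermediate editing states need them.

### Repeated events and exactness

Bottom-up gate combination is exact only while no risk factor feeds more
than one branch. A *repeated event* makes sibling subtrees dependent, so
the engine switches to Shannon factoring (pivotal decomposition):

$$P(\text{top}) = p_e\,P(\text{top} \mid x_e = 1)
               + (1 - p_e)\,P(\text{top} \mid x_e = 0),$$

recursing until every remaining repeated event is pinned to a constant.
Repeats are detected by counting root-to-node paths, which also catches
sharing introduced by a gate with several parents. The pivot is the
most-shared event, ties broken by identifier, which makes the recursion
order — and hence the floating-point result — deterministic. The
recursion is exponential only in the number of *repeated* events; the
engine refuses models with more than 25 of them, a limit far above the
few repeats typical of elicited clinical models. Factoring was chosen
over inclusion–exclusion on cut sets because it is numerically stable
(no alternating sums) at the repeat counts these models have.

Two classical approximations are always co-reported from the minimal
cut sets $K_1,\dots,K_m$: the rare-event sum
$\sum_j \prod_{e \in K_j} p_e$, which may exceed 1 and is then flagged
rather than clamped so its failure is visible, and the min-cut upper
bound $\mathrm{MCUB} = 1 - \prod_j (1 - P(K_j))$. On coherent trees with
independent leaves, $\text{exact} \le \mathrm{MCUB} \le
\min(\text{rare-event sum}, 1)$; the test suite asserts this ordering on
every generated tree.

## Probability elicitation: low / average / high

Each risk factor carries a list of source values with provenance
`literature` or `expert`. Literature values take strict priority: if any
exist, expert values for the same factor are ignored (and surfaced as a
`shadowed_expert` validation warning), reflecting the view that
published estimates are the more reliable. From the retained values $V$:

* **average** = $\mathrm{mean}(V)$;
* **low** = mean of $V$ with one instance of the largest value removed;
* **high** = mean of $V$ with one instance of the smallest value removed.

A single value collapses all three. Ties remove exactly one instance —
"the highest reported value" is singular. The three derived numbers are
*never* stored in model files; they are recomputed on load so the
aggregation rule has a single source of truth. Factors with no source at
all are "unestimated": they block the probability engine and are
removed by `prune_unestimated()`, which errors rather than silently
rewriting the logic if removal would touch an AND gate.

`bound_analysis()` recomputes the exact top probability under all three
selectors; coherence guarantees the three rows are monotone.
`leave_out_analysis()` re-runs the model with named factors excluded
(for example, elderly patients and history of medical problems as risk
factors) and reports absolute deltas against the baseline — absolute
rather than relative, because the method's outputs are probabilities,
not risk ratios.

### Exclusion semantics

`exclude_events()` deletes a leaf from every parent's input list; an OR
gate emptied this way disappears from *its* parents recursively.
Removing a conjunct of an AND gate silently changes what the
conjunction means, so it is an error under the default `forbid` policy.
Under `neutralize`, the leaf is instead kept with probability pinned to
1 — a vacuous, always-true conjunct. The cascade case (an emptied OR
that feeds an AND) follows the same always-true reading under
`neutralize`: the vacuous conjunct is dropped from the AND's input
list. Exclusions that would eliminate the top gate are an "empty
model" error in every policy.

## Minimal cut sets

A *cut set* is a set of risk factors whose joint occurrence forces the
top event; a *minimal* cut set (a critical path) contains no smaller
cut set. Enumeration is top-down MOCUS: the working state is a list of
rows, each a conjunction implying the top event, starting from the top
gate; an AND gate is replaced in-row by its inputs, an OR gate splits
the row into one copy per input. Rows are duplicate-free sets
($\{B, B\} \to \{B\}$ applied eagerly, which bounds growth), and
Boolean absorption (superset removal) runs after expansion. Order
truncation, when requested, is applied *after* minimization — truncating
first could delete the low-order absorber of a redundant set and leave
a non-minimal result. Expansion follows declared input order and the
final sort (descending probability, ties lexicographic) is total, so
output is byte-stable. A configurable row cap (default $10^6$) turns
combinatorial explosion into a clear resource error instead of a hang.

`is_cut_set()` and `is_minimal()` are kept as independent Boolean
oracles; because the structure function is monotone, minimality only
needs the one-factor-removed subsets checked.

## Importance measures

For factor $e$ with probability $p_e$ and $P = P(\text{top})$:

* **Birnbaum** $B_e = P(\text{top} \mid x_e = 1) - P(\text{top} \mid
  x_e = 0)$, computed by the exact engine with $p_e$ pinned to 1 and 0
  (by multilinearity this equals $\partial P / \partial p_e$);
* **criticality** $C_e = B_e\,p_e / P$;
* **Fussell–Vesely** $FV_e = \Pr[\bigcup_{K_j \ni e} K_j] / P$, the
  union probability computed exactly by the same factoring idea applied
  to the cut-set conjunctions.

Reports default to ranking by criticality importance — the quantity
risk-analysis tools document under that name, interpretable as the
probability that the adverse event is due to the factor — but
Fussell–Vesely is always co-reported, because the two definitions
coincide only approximately on trees with repeated events and published
tables rarely say which one they used. On coherent trees
$C_e \le FV_e$; the suite asserts this, along with agreement of
Birnbaum with a central finite difference and invariance of all three
measures under serialization round-trips.

## Monte Carlo oracle

`monte_carlo_top()` draws $n$ independent Bernoulli assignments and
evaluates the structure function vectorized over chunks (bounding
memory at roughly `chunk_size` × events logicals), returning the hit
fraction with a normal-approximation 95% half-width
$1.96\sqrt{\hat p(1-\hat p)/n}$. It exists purely as a cross-check on
the Boolean algebra; it is seeded, reproducible, and leaves the
caller's RNG stream untouched.

## The seclusion-falls reconstruction

`load_seclusion_skeleton()` ships the critical-path architecture of the
published seclusion-falls model: a fall requires the conjunction of a
psychiatric disorder, a mechanism of fall, a reason for the fall
(psychological, or physical including medication side effects), and the
failure of fall prevention — itself the conjunction of a
risk-assessment failure and a prevention-intervention failure. That
yields exactly two AND gates and order-5 critical paths, one factor per
branch, which the tests verify mechanically via `is_minimal()`.

The reconstruction deliberately does **not** claim the full published
88-factor / 22-OR-gate topology, which the source article does not
print. Its leaf probabilities are synthetic, illustrative values of
published-plausible magnitude (disorder prevalences among secluded
patients, mechanism and physiological-reason rates, elicited
prevention-failure rates), stored in a separate overlay file —
`seclusion_probabilities_synthetic.json` — so structure and numbers are
versioned independently, and flagged `illustrative` in the model
metadata and in every report's provenance note. Replication of the
published numbers is delegated to `load_deposited_model()`, an adapter
entry point for the study's open-data deposit: native-format files load
directly, anything else raises an "adapter required" error carrying a
file fingerprint.

## The synthetic generator

`generate_tree()` exists so every stage is testable without downloads.
Generation is top-down: a random gate skeleton grows under the top gate
(guaranteeing reachability), basic events attach childless-gates-first
(guaranteeing no empty gate), and repeats are added afterwards by
giving a leaf a second parent with probability `repeat_rate`. Defaults
mirror the published tree's shape — 88 events over 24 gates of which 2
are AND (`and_fraction = 2/24`), 12 underdeveloped events — with leaf
probabilities uniform on $[0.01, 0.5]$: fall risk factors are
rare-to-moderate events, and the boundary values 0 and 1 are exercised
by dedicated edge-case fixtures rather than the generator. Sources per
factor default to 1–3 with a 30% expert fraction, enough to exercise
the shadowing and low/high rules.

What the generator does *not* emulate: correlated risk factors (the
analysis assumes independence throughout, as the source methodology
does), time-in-seclusion exposure effects (explicitly outside the
method's reach), and the semantic plausibility of gate groupings. A
green property suite therefore certifies the algebra and the
algorithms, not the clinical fidelity of any particular elicited model.

```{r example}
tr <- worked_example_tree()   # TOP = AND(OR(A,B), OR(B,C)), all p = 0.1
top_probability_exact(tr)
mocus_cut_sets(tr)
importance_all(tr)
```

## Numerical and testing choices

Exactness tests compare against $2^n$ truth-table enumeration at
tolerance $10^{-12}$ on trees of up to 12 events; cut sets compare
against minimal true points of the same truth table. The default
property suites use a few hundred seeded trees of 3–12 events and 1–4
gates, the Monte Carlo consistency check uses 20 trees at $10^6$ draws,
and the generator sweep validates 1000 seeded trees — sizes chosen so
the whole suite exercises every code path at enumeration-checkable
scale. Serialization keeps full floating-point precision (17
significant digits in YAML, unrounded JSON); human-readable report
output rounds to 6 decimals, matching the precision at which such
analyses are conventionally reported. The Open-PSA surface is lossy by
design: one point probability (the average) per factor, which reads
back as a single literature source so re-aggregation reproduces it.

## Known limitations

* Basic events are independent; no common-cause or correlation
  modelling.
* Static AND/OR logic only — no dynamic gates (PAND, SPARE), no event
  trees, no prime implicants for non-coherent structures.
* Exact computation is exponential in the number of repeated events
  (limit 25); models with massive replication would need a BDD engine.
* The packaged seclusion model is a structural reconstruction with
  illustrative probabilities; its absolute numbers carry no clinical
  meaning, only its architecture and the methods do.
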