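# stpra — sociotechnical probabilistic risk assessment with fault trees

`stpra` implements the quantitative core of sociotechnical probabilistic
risk assessment (ST-PRA): prospective modelling of an adverse health-care
event — the motivating application is a patient fall in a psychiatric
seclusion room — as the top event of a fault tree. Risk factors are
basic events with occurrence probabilities elicited from literature and
expert panels; AND/OR gates encode how they combine. It is written for
patient-safety and reliability analysts who want the analysis layer
(cut sets, probabilities, importance, sensitivity) as scriptable,
auditable R instead of a GUI tool.

## What it computes

With independent risk factors $X_e \sim \mathrm{Bern}(p_e)$ and a
coherent structure function $\phi$ built from AND (product) and OR
(complement-product, i.e. "sum minus overlap") gates:

* **Minimal cut sets** — the critical paths: inclusion-minimal factor
  combinations that force the top event, enumerated by top-down MOCUS
  expansion with Boolean absorption.
* **Top-event probability** — exact, via bottom-up combination or
  Shannon factoring $P = p_e P(\cdot\,|\,x_e{=}1) + (1-p_e)
  P(\cdot\,|\,x_e{=}0)$ when a factor feeds several branches, plus the
  rare-event sum and min-cut upper bound approximations and a seeded
  Monte Carlo oracle.
* **Importance** — Birnbaum $B_e = P(\mathrm{top}|x_e{=}1) -
  P(\mathrm{top}|x_e{=}0)$, criticality $B_e p_e / P_{\mathrm{top}}$
  (the probability the event is due to that factor), and Fussell–Vesely
  $P(\bigcup_{K \ni e} K)/P_{\mathrm{top}}$.
* **Sensitivity** — low/average/high elicitation bounds (the low/high
  estimates drop one extreme source value before averaging) and
  leave-out scenarios that re-run the model without selected factors.

Models live in a small JSON dialect (YAML as a 1:1 alternate, plus a
lossy Open-PSA MEF XML surface); per-factor probability sources carry
literature/expert provenance, and literature values take priority. A
seeded generator of random coherent trees backs the property-based test
suite, and the package ships a structural reconstruction of a published
seclusion-falls model with clearly flagged illustrative probabilities.

## Worked example

`TOP = AND(OR(A, B), OR(B, C))` with every probability 0.1 — the
smallest tree with a repeated event:

```r
library(stpra)
tr <- worked_example_tree()
top_probability_exact(tr)
#> top event probability (average estimates, factoring): 0.109000
#>   rare-event sum 0.110000 | MCUB 0.109000 | 2 minimal cut sets
mocus_cut_sets(tr)
#> 2 minimal cut set(s) (average estimates)
#>   {B}  p = 0.100000
#>   {A, C}  p = 0.010000
```

The exact value is $P(B \cup (A \cap C)) = 0.1 + 0.01 - 0.001 = 0.109$;
naive bottom-up combination would give $0.19^2 = 0.0361$, which is why
the engine factors on the repeated event `B`. The rare-event sum
$0.1 + 0.01 = 0.11$ overshoots, as an upper bound should.
`importance_all(tr)` attributes $FV(B) = 0.1/0.109 \approx 0.917$ of
the risk to `B` alone.

The packaged seclusion reconstruction runs the same pipeline end to
end:

```r
skel <- load_seclusion_skeleton()
build_report(skel, top_k = 3)
#> analysis report: model 'seclusion-falls-reconstruction' (hash 69e627c0e2e3)
#>   provenance: reconstruction — illustrative probabilities
#>   25 basic events, 10 gates
#>   top event [low]: exact 0.116544 | rare-event 0.630152 | MCUB 0.467640 (bottom_up)
#>   top event [average]: exact 0.148630 | rare-event 0.899248 | MCUB 0.593379 (bottom_up)
#>   top event [high]: exact 0.185259 | rare-event 1.247531 (>1) | MCUB 0.713166 (bottom_up)
#>   minimal cut sets (average): 1296 total, top 3:
#>     {fall_risk_not_screened, no_prevention_intervention, obesity, schizophrenia, seated_to_standing}  p = 0.005457
#>     ...
```

Every critical path has order 5: one disorder, one mechanism of fall,
one reason, one risk-assessment failure and one intervention failure —
the model's defining architecture (a fall needs all five conjuncts).
The probabilities are synthetic illustrations, so the absolute numbers
carry no clinical meaning; the report says so in its provenance line.

A thin command-line front end over the same functions is included at
`inst/cli/stpra.R` (`cutsets`, `analyze`, `simulate`, `importance`,
`sensitivity`, `report`, `skeleton`, `generate`).

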