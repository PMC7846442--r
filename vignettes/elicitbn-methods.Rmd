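---
title: "Building expert-elicited Bayesian networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building expert-elicited Bayesian networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(elicitbn)
```

## The problem

Clinical decision support for conditions like low back pain lacks the large,
outcome-labelled datasets that purely data-driven models need. An
alternative is to elicit the model from a panel of domain experts: a
discrete Bayesian network (BN) whose variables, structure and conditional
probability tables (CPTs) are aggregated from individual expert answers
using structured consensus methods in the Delphi / RAND-appropriateness
family — individual anonymous scoring alternating with facilitated
discussion of contested items.

`elicitbn` implements that pipeline end to end:

1. **Stage 1 — variables.** Experts place candidate variables into one of
   three skeleton categories (risk factors → judgement factors → signs and
   symptoms) and rank each category list by importance.
2. **Stage 2 — structure.** Experts score the strength of every allowed
   category-respecting relationship on a 0–3 scale in a grid; consensus
   cells are frozen, contested ones go to a workshop round; the strongest
   surviving relationships become the DAG.
3. **Stage 3 — probabilities.** Experts answer automatically generated
   probability questions; answers are screened for outliers, pooled, and
   compiled into CPTs via parsimonious models (leaky noisy-OR, ranked
   nodes).
4. **Stage 4 — validation.** The finished network is interrogated with
   clinical scenarios and its qualitative behaviour compared with expert
   expectation ("face validity"), plus quantitative recovery metrics
   against simulated ground truths.

Because real elicitation data are confidential and scarce, the package
ships a first-class simulator (`make_ground_truth()`, `simulate_stage1()`
… `simulate_stage3()`) that emulates a noisy expert panel answering about
a known network, so the whole pipeline is testable by parameter recovery.

## Consensus statistics

All aggregation uses the panel **median** and the **80% interpercentile
range** IPR80 = P90 − P10, the disagreement measure of RAND
appropriateness panels. Percentiles interpolate linearly between order
statistics (rank `r = 1 + q(n-1)/100`, the common "type 7" convention),
stated explicitly so results are bit-reproducible.

Stage 1 includes a variable in a category only when **strictly more than
80%** of the experts who placed it chose that category — 0.8 exactly is
excluded, following the strict reading of a "more than 80%" rule. The
preference score is the median normalized rank (1 = top of list, 0 =
bottom; a singleton list scores 1) penalized by disagreement:

    adjusted = max(0, median − λ · IPR80),   λ = 0.5 by default.

The penalty form is a package choice: the requirement is only that more
consensus yields less adjustment, and a linear penalty is the simplest
monotone option. Ties at the selection cap (default 50 variables) break by
higher allocation fraction, then by name — never by input order.

Stage 2 fixes a grid cell when its IPR80 ≤ 1 (consensus reached; the cell
cannot be edited in the workshop) and re-aggregates the rest from workshop
responses. An edge survives when its final median strength is ≥ 2 —
"medium or stronger" on the 0–3 scale, where a score of 1 means only a
sometimes-small effect. A top-k alternative is exposed
(`build_dag(..., top_k = )`) for teams who prefer a budget to a threshold.
Blank cells count as score 0 (a blank grid cell means "no relationship")
with a logged warning. Variables left with no incident edge are discarded.

## Outlier screening (Stage 3)

Each elicited scalar is screened against the band
`median ± 1.5 · IPR80` computed from the **other** experts' answers
(leave-one-out), and screening repeats with the worst offender removed so
aberrant answers cannot widen or mask each other's bands. The
leave-one-out form matters: a single wild answer inflates a panel-wide
IPR80 enough to place itself inside the band, so the panel-wide version of
the same rule fails to reject exactly the answers it exists to catch.
Three safeguards bound the behaviour: a unanimous panel rejects nothing;
the reference set must keep at least three answers (panels smaller than
four are retained wholesale); and at most ⌊n/2⌋ answers are ever removed
for one question. Retained slider answers are pooled by per-state median
and renormalized — median pooling keeps Stage 3 consistent with the
median-based consensus of Stages 1–2 and is what makes the aggregate
robust to a biased minority (a property the test suite demonstrates with
a 2-of-9 biased bloc).

## CPT models

**Leaky noisy-OR** (binary children). Each parent in a non-baseline state
is an independent cause; a background leak `l` covers unmodelled causes:

    P(present | config) = 1 − (1 − l) · Π_active (1 − p_parent,state)

The baseline state is each parent's first listed state, and the child's
"present" state is its second — stated because the model needs a
distinguished baseline and the elicitation interface does not supply one.
Eliciting only the baseline plus each single-parent-active configuration
makes the fit closed-form and exact (`p = (q − l)/(1 − l)`) and shrinks
the question burden from `Π |states|` to `1 + Σ(|states| − 1)` per child —
on the 30-variable networks used in the acceptance checks that is roughly
a 3–4× reduction, the difference between a feasible and an infeasible
elicitation. When fuller data are elicited, the closed-form values seed a
bounded least-squares refinement; when the noisy-OR residual exceeds 0.1,
a logistic-link regression on (parent, state) indicators takes over for
that child. Elicited values below the baseline (non-monotone answers) are
clamped to zero activation with a warning rather than silently fitted.

**Ranked nodes** (ordinal children). A ranked variable's states map to
equal-width sub-intervals of [0, 1] in listed order. Experts give the most
likely value `m` and the extent of variation `h`; the package reads `h` as
the half-width of a central 90% interval, so `σ = h / 1.645`, and builds a
doubly truncated normal on [0, 1] whose interval masses become the state
probabilities. For conditional ranked children the generator-side
construction is the classic weighted mean of parent interval midpoints
(`ranked_child_mean()`); on the elicitation side each parent configuration
gets its own mode-and-spread question, so σ is per-configuration — the
spread answer is already part of every question, and pooling it per child
would discard elicited information to save no questions.

Degenerate cases are defined, not accidental: `h = 0` (or σ below 1e-12)
yields a point mass in the interval containing the mode, and a truncation
window that numerically excludes all mass falls back to the nearer
boundary interval.

## Inference

Exact posteriors by variable elimination over table factors, with hidden
variables eliminated in min-degree order (deterministic tie-break by
name). Elicited networks are small — tens of nodes, strictly layered — so
heuristic order-optimality is irrelevant; correctness is instead enforced
by a second, independent route: full joint enumeration via the chain rule,
which the test suite compares against variable elimination to 1e-9 on a
hundred random layered networks. Evidence with zero marginal probability
raises an error rather than returning NaN, so modelling errors cannot
masquerade as data. Networks export to XMLBIF 0.3 and the textual BIF
dialect (category/kind metadata ride along as properties; probabilities
print at 17 significant digits so round trips are exact to well below
1e-9).

## The simulated panel

`panel_config()` controls one noise dial per elicitation failure mode:

| parameter | meaning | default |
|---|---|---|
| `n_experts` | panel size (workshops typically 7–15) | 10 |
| `category_confusion` | P(mis-placing a variable's category) | 0 |
| `rank_noise_sd` | Gaussian noise on importance before ranking | 0 |
| `strength_noise_sd` | rounded, clipped noise on 0–3 grid scores | 0 |
| `prob_noise_sd` | logit/log-scale noise on probability answers | 0 |
| `outlier_rate` | P(an answer is replaced by a random aberrant one) | 0 |
| `bias` | per-expert systematic offset (logit/rank scale) | none |

Probability noise acts on the log/logit scale and renormalizes, so
simulated answers stay valid distributions and are symmetric around the
truth in log-odds; biases are additive constants on that scale, the form
against which median aggregation's robustness is meant to be shown. All
randomness derives from one master seed through named substreams (one per
expert per stage), so any single response file is reproducible in
isolation.

Ground truths guarantee no isolated variables (every child has a parent,
every risk factor a child) because an isolated variable is *correctly*
discarded by Stage 2 — it would make perfect recovery undefined rather
than hard. True strengths are drawn 2–3 for present edges and 0–1 for
absent pairs, so the keep-threshold rule can in principle recover the
structure exactly; whether it does under noise is what the tests measure.

What the simulator does **not** model: workshop convergence dynamics
(opinion change between rounds), question-order and fatigue effects,
semantic disagreement about variable definitions, and correlated expert
errors from shared training. Passing recovery tests therefore show the
aggregation machinery is sound, not that a real panel of clinicians will
behave like the noise model.

## Problem sizes in the shipped checks

The test suite and the acceptance script size their simulations to
exercise every code path while staying quick: oracle-equivalence runs use
100 random 8-node networks; noise-free end-to-end recovery uses a
30-variable truth (10 risk, 8 judgement, 12 sign variables, edge density
0.3, 7 experts); the panel-growth trend uses an 8-node truth at logit
noise 0.3 with panels of 3, 7 and 15 over 30 seeds; outlier screening uses
a 12-variable truth, 10 experts, 20% injected aberrant answers. These are
the package's chosen study conditions; all reported numbers are computed
at run time by those scripts, never stored.

## Known limitations

* Within-category edges (judgement → judgement) are excluded by the
  default skeleton; the skeleton is configurable but the layered form is
  what guarantees acyclicity without a cycle check.
* Treatment variables and treatment-response prediction are out of scope;
  the pipeline predicts judgement factors prior to treatment.
* Free-text deduplication of suggested variables is manual by design; the
  package only applies a supplied alias map.
* The logistic-link fallback is a least-squares fit on transformed pooled
  values, not a maximum-likelihood fit on raw answers; with the default
  noisy-OR route it only engages when the noisy-OR family fits poorly.

## A worked miniature

```{r example}
truth <- make_ground_truth(n_risk = 3, n_judgement = 2, n_sign = 3,
                           edge_density = 0.5, seed = 7)
cfg <- panel_config(n_experts = 9, seed = 7, prob_noise_sd = 0.2,
                    outlier_rate = 0.1)
dir <- tempfile()
paths <- write_simulated_panel(truth, cfg, dir)
res <- run_pipeline(paths$model, paths$stage1, paths$stage2,
                    paths$sliders, paths$spreads,
                    out_dir = file.path(dir, "out"), cap = 100)
structure_recovery(res$network$edges, truth$network$edges)$f1
cpt_recovery(res$network, truth$network)$max_abs_error

# diagnostic reasoning: observing a sign moves its judgement parents
sign_edge <- res$network$edges[grepl("^sign", res$network$edges$to), ][1, ]
sign <- sign_edge$to; judge <- sign_edge$from
posterior(res$network, judge)
posterior(res$network, judge,
          stats::setNames(res$network$variables[[sign]]$states[2], sign))
```
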