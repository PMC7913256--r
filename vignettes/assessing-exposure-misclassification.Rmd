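---
title: "Assessing exposure misclassification across alternative control windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing exposure misclassification across alternative control windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 8, fig.height = 6)
library(ccwindows)
library(dplyr)
```

## The problem

The case-crossover design estimates the effect of an intermittent exposure on
an acute outcome by comparing each subject's exposure just before the event
(the *case window*) with the same subject's exposure at an earlier reference
time (the *control window*). Every case is its own control, so stable
within-person confounders cancel. The price is sensitivity to the placement of
the control window: only *discordant* subjects — exposed in exactly one of the
two windows — contribute to the estimate, and moving the control window can
change who is discordant. In dispensing-claims studies of medicines such as
tricyclic antidepressants and hip fracture, a control window placed too far
from the case window can misclassify long-term users as intermittent users
(*persistent user bias*), inflating the odds ratio.

`ccwindows` implements a deterministic, auditable version of a visual
workflow for diagnosing this problem when a sensitivity analysis with two
alternative control windows yields conflicting results:

1. classify every subject's exposure status under each control window,
2. stratify subjects by how the status changes between windows,
3. apply boundary-distance rules per stratum to decide which window's
   classification looks correct,
4. estimate the discordant-pair odds ratio per window, and
5. draw the stratified per-subject dispensing timeline that makes the
   decision inspectable.

## Coordinates, windows and exposure status

All timing is expressed in whole days pre-event: day 1 is the day immediately
before the event, and a dispensing on the event day itself is excluded
(it cannot precede the outcome). Windows are closed integer intervals. The
default design is the one used in the worked example throughout this
vignette — chosen in the original analysis so that each window spans the time
within which 75% of patients had a repeat dispensing:

```{r design}
design <- cc_design()   # case 1-50, CW1 101-150, CW2 151-200, horizon 200
design
```

The washout paired with a control window is the derived gap between the case
window and that control window (51–100 days for CW1, 51–150 for CW2); the
washout absorbs carry-over exposure but dispensings inside it count as
exposure in *neither* window. `suggest_window_length()` recovers the
window-sizing heuristic from data: the smallest whole-day gap covering a given
percentage of patients' first repeat dispensings (no interpolation, so the
answer is always an observed gap). Because the source text does not pin down
which refill gap enters that computation, the extraction policy is explicit:
`"first"` (first-to-second dispensing, the default and the natural reading of
"repeat dispensing"), `"all"`, or `"median"`.

Each subject is one of four statuses per control window: **intermittent**
(exposed in the case window only), **recent stopper** (control only),
**continuous** (both), **non-user** (neither). Exposure in the case window is
a single fact, so the CW1/CW2 statuses are jointly constrained; the eight
admissible pairs define strata **A–F** (status changes relevant to
misclassification, plus the two stable discordant strata C and F) and the
unassessed concordant strata **G** (continuous under both) and **H** (non-user
under both). Strata A–F are exactly the subjects discordant under at least
one window — the denominator for all misclassification percentages.

## The rule engine

The original workflow determined misclassification by consensus among human
reviewers inspecting the figure; the rules they codified are implemented here
as a deterministic engine, one rule per stratum, each with the form "if a
strict majority of members satisfy a geometric condition, issue verdict pair
(CW1, CW2)". The geometry is boundary distance on a timeline drawn with the
event at the right: a window's *RHS* is its boundary nearer the event (its
`start` in days pre-event), its *LHS* the farther boundary. The reference
dispensing is the **latest** one (smallest offset) for strata A, B, C — whose
members are unexposed in the case window, so what matters is how recently
they last filled — and the **earliest** (largest offset) for D, E, F, whose
members are unexposed in the control windows, so what matters is how far back
their use plausibly started. The source table is ambiguous between
per-member and per-dispensing counting for one stratum; the engine counts
one reference dispensing per member uniformly, which keeps every rule a
majority vote over subjects.

| Stratum | Change (CW1 → CW2) | Condition (per member) | If met | If not met |
|---|---|---|---|---|
| A | stopper → non-user | latest closer to RHS than LHS of CW1 | correct / miscl. | miscl. / correct |
| B | non-user → stopper | any dispensing in washout 51–100 | miscl. / correct | correct / miscl. |
| C | stopper → stopper | latest closer to RHS of CW1 than LHS of CW2 | correct / correct | miscl. / miscl. |
| D | intermittent → continuous | earliest closer to RHS than LHS of CW2 | miscl. / correct | correct / miscl. |
| E | continuous → intermittent | earliest closer to LHS than RHS of CW1 | correct / miscl. | miscl. / correct |
| F | intermittent → intermittent | earliest inside the case window | correct / correct | miscl. / miscl. |

Three design choices were genuinely open and are fixed as follows:

* **Complement branches.** The codified rules state only the "if" branch.
  The mirrored complements above are part of the method — observed data have
  exercised stratum B's complement (no washout dispensings, CW1 correct) —
  and for C and F the complement is "misclassified under both", emitted with
  a warning because it signals a cohort unlike any the rules were written
  for. Under the default design C's complement is in fact geometrically
  unreachable (the latest dispensing of a both-window stopper is always
  nearer CW1's RHS than CW2's LHS); it can fire under designs with a very
  wide first control window.
* **Ties.** "Closer to" is a strict inequality: a dispensing equidistant from
  both boundaries is *not* closer, and an exactly-half split fails the strict
  majority. Both choices are conservative and both are recorded in the
  per-subject metric table each decision carries for audit.
* **Group verdicts.** Verdicts apply to a stratum as a whole, never to
  individuals — the method assesses whether the *window choice* systematically
  misclassifies a group, not whether any one subject is misclassified.

Percentages then aggregate stratum sizes over the A–F denominator:
each stratum contributes its whole size to the verdict its rule issued for
that window, and correct + misclassified + indeterminate = 100 per window
(indeterminate arises only from empty strata).

## The effect estimate

For 1:1 self-matched binary exposure, the conditional-logistic maximum
likelihood estimate has a closed form: with `b` subjects exposed in the case
window only and `c` in the control window only,

$$\widehat{OR} = b/c, \qquad
  CI_{1-\alpha} = \exp\!\left(\log(b/c) \pm z_{1-\alpha/2}\sqrt{1/b + 1/c}\right).$$

`odds_ratio()` implements exactly this; the test suite checks it against a
brute-force maximiser of the conditional likelihood (`b + c` Bernoulli trials
with success probability $OR/(1+OR)$, maximised by golden-section search)
over the full grid $1 \le b, c \le 30$ to $10^{-6}$ relative error, and
against the published worked example (127/108 → 1.18, 95% CI 0.91–1.52;
150/105 → 1.43, CI 1.11–1.83). Zero discordant cells are an error unless the
Haldane–Anscombe +0.5 correction is explicitly requested — never silent.
Estimates are returned unrounded; two-decimal formatting is presentation.

## The synthetic cohort generator

No public claims data exist for this setting (the motivating data are
restricted administrative records), so `generate_cohort()` fabricates
dispensing and event tables with known structure from archetypes:

* `continuous_refiller` — refill gaps drawn from a positive-truncated normal
  (default mean 30 days, the typical one-month script; sd 0 gives a
  deterministic arithmetic sequence). With a `course_window`, the subject is
  a *recent starter*: the earliest dispensing is planted in that window and
  refills run forward to the event. Recent starters whose first dispensing
  falls in the half of CW1 nearer its far boundary (days 126–150) are the
  persistent-user-bias mechanism by construction: continuous under CW1,
  intermittent under CW2, stratum E, rule E verdict (correct, misclassified).
  A start uniform over all of CW1 satisfies rule E's distance condition only
  about half the time, so the demonstration fixtures plant the clustered
  pattern the bias actually produces.
* `intermittent_case_user`, `recent_stopper`, `washout_only_user` — short
  courses of 1–2 dispensings planted in the case window, a designated control
  window, or the washout respectively, with optional uniform jitter.
* `non_user` — no dispensings.

The truth table records statuses **recomputed from the emitted offsets**,
never from the archetype label, so jitter that genuinely moves a subject's
status cannot make the generator lie; `verify_truth()` then checks the
claims-file round trip (dates → offsets → statuses) reproduces that truth
exactly. Event dates are distinct civil dates drawn uniformly over a span of
at least four years; calendar structure is irrelevant to the method, so no
seasonality is modelled. All randomness flows through one seed.

What the generator does **not** emulate: days-supply and adherence (exposure
is a binary dispensing marker, as in the source method), stockpiling,
indication, demographic structure (self-matching removes it), or realistic
marginal rates of use. Passing tests on these cohorts therefore demonstrate
the *machinery* — classification, stratification, rules, estimation, layout —
not epidemiological realism.

## Worked example

```{r pipeline}
cohort <- generate_cohort(list(
  archetype_spec("intermittent_case_user", 127),
  archetype_spec("recent_stopper", 108),
  archetype_spec("continuous_refiller", 40, refill_gap_sd = 5),
  archetype_spec("non_user", 25)), design, seed = 1)

histories <- build_histories(cohort$dispensings, cohort$events, design)
classifications <- classify_cohort(histories, design)
odds_ratio(discordant_counts(classifications, "cw1"))
```

The stratified timeline, with rule verdicts in the panel headers:

```{r figure}
demo <- generate_cohort(list(
  archetype_spec("recent_stopper", 15, course_window = cc_window(101, 125)),
  archetype_spec("recent_stopper", 10, course_window = cc_window(151, 200)),
  archetype_spec("intermittent_case_user", 20),
  archetype_spec("continuous_refiller", 20, refill_gap_mean = 30,
                 refill_gap_sd = 3, course_window = cc_window(126, 150))),
  design, seed = 2)
h <- build_histories(demo$dispensings, demo$events, design)
rules <- evaluate_rules(h, design)
summarize_misclassification(rules)
autoplot(build_panels(h, design, decisions = rules))
```

## Numerical and scale choices

* Day offsets, distances and window bounds are integers throughout; the only
  floating-point quantities are percentages and the OR/CI.
* Layout sorting tie-breaks on `subject_id` lexicographically, so
  `build_panels()` + `export_layout()` are byte-identical across runs and
  input orderings — the TSV export, not the rendered image, is the testable
  surface; marker glyphs and band colours are styling.
* Problem sizes in the test suite are deliberately modest — grids to
  $30 \times 30$ for the likelihood oracle, planted cohorts of 60–345
  subjects, one 10,000-subject discordant cohort for ratio recovery — which
  keeps the full suite under a few seconds while exercising every branch of
  every rule.
* The visualisation targets cohorts of a few hundred discordant subjects;
  with tens of thousands of rows the per-subject timeline stops being
  discriminable (a stated limitation of the approach, not of this
  implementation).

## Limitations

The rule engine codifies what was originally a consensus judgement; the rules
are faithful but necessarily sharper than the judgement they replace, and the
group-level verdicts say nothing about individual subjects. Non-adherence,
days supply and carry-over beyond the washout are outside the model. The
percentages the engine produces on synthetic cohorts recover planted
compositions exactly, but real-data percentages depend on the dispensing
patterns of the actual population and cannot be inferred from simulations.
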