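---
title: "Measuring intervention dose in health promotion programmes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring intervention dose in health promotion programmes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irgdose)
library(dplyr)
```

## The problem

Health promotion programmes — a diet and physical activity campaign across
high schools, say — are rarely implemented uniformly. Some settings deliver
every planned activity; others deliver almost none; some control settings run
similar activities on their own initiative. Outcome analyses that ignore this
variability risk the *type III error*: concluding that a programme does not
work when it was simply never implemented as planned. `irgdose` provides the
constructs and computations needed to quantify implementation as an
**intervention dose** and to carry that dose into comparative analyses.

## Constructs

**Intervention-related group (IRG).** The unit of dose measurement is one
(setting, intervention) cell. A setting assigned an intervention forms an
*IRG-Active* for it; every other setting is an *IRG-Control* of that
intervention. A programme with $S$ settings and $K$ interventions always has
$S \times K$ IRGs. `enumerate_irgs()` builds the table; the bundled
`pralimap_programme()` preset (24 settings, 3 strategies with 12 active
settings each, 2 periods) reproduces a published cluster-randomised
application with 72 IRGs, 36 active and 36 control.

**Evaluation objects.** Implementation is observed through two domains
(delivery, participation), each in two declensions (quantity, quality), for
each category of programme actor: supervisors, anchor personnel (in their
receiver and provider roles), and targets. That makes $4 \times 2 \times 2 =
16$ evaluation objects. Four are structurally empty — targets do not perform
interventions, and supervisors do not work in the field — leaving 12 eligible.
The exact four excluded cells are not uniquely determined by those two
exclusion reasons alone; `evaluation_grid()` defaults to excluding
target × delivery (both declensions) and supervisor × participation (both
declensions), which realises both reasons and yields exactly 12 eligible
cells. The mask is data, not code: pass an alternative `ineligible` table
for programmes with a different actor structure.

**Activity classes.** Doses are computed separately for *programme-driven
activities* (PDA: planned by the programme's frame of reference; defined only
for active IRGs) and *non-programme-driven activities* (NPDA: relevant
activities performed independently of the programme; defined for every IRG,
including controls). `plan_report_sheets()` therefore plans one NPDA
indicator report sheet per IRG plus one PDA sheet per active IRG.

## The scoring protocol

Indicators — participation rates, activity reports, literal descriptions —
cannot be scored automatically, so consolidated scores come from a
nominal-group expert process:

1. IRGs are distributed fairly and anonymously among expert groups
   (`distribute_irgs()`: seeded shuffle + round-robin, sizes within one).
2. Each expert independently scores every cell (period × domain ×
   declension) of their IRGs on a 0–`mas` scale (`mas` = common maximal
   assignable score, 20 by default).
3. Per cell, the mean, *sample* standard deviation and range are computed
   (`summarize_scores()`). We use the $n-1$ denominator deliberately: panels
   are small (six experts) and the sample SD flags debates more readily.
4. A cell is debated when SD > 2.5 **or** range > 6 (`flag_for_debate()`).
   Both inequalities are strict — "higher than" the threshold — so a cell
   sitting exactly on a threshold is not debated.
5. Debated cells are re-scored; the round-2 mean *replaces* the round-1 mean
   entirely (it is not averaged with it), and mean scores are retained even
   without consensus (`consolidate_cell()`, `consolidate_scores()`).

### Calibration via a fictitious IRG

With several expert groups, a *fictitious IRG* scored by every group
measures the between-group effect. `compute_group_offsets()` defines a
group's offset as its mean over all fictitious cells minus the grand mean of
the group means. Two design choices deserve note:

* **Reference point.** Only adjustment magnitudes are observable from a
  completed study, not the anchor they were computed against. Using the
  across-group grand mean preserves the overall score level and makes the
  offsets sum to zero by construction.
* **Granularity.** The offset is additive per group, applied uniformly
  across cells (a per-cell calibration is possible by computing offsets on
  subsets, but the default assumes a group-level severity/leniency effect).

`apply_calibration()` subtracts each group's offset, clamps to $[0, mas]$
(calibration must not push scores off the scale), and drops the fictitious
rows: they exist only to estimate the offsets. By construction, applying the
offsets to the very scores they were computed from equalises the group means
on the fictitious IRG exactly (absent clamping) — a property the test suite
asserts.

## The dose formula

The four consolidated scores of an (IRG, activity class, period) — DQt
(delivery quantity), DQl (delivery quality), PQt and PQl (participation
quantity and quality) — are nested rather than independent: participation is
subject to delivery, quality to quantity. The dose weights delivery quantity
by the mean of the other three, normalised by `mas`:

$$\mathrm{Dose} = DQt \times \frac{\mathrm{mean}(DQl,\, PQt,\, PQl)}{mas}$$

The weighting factor lies in $[0,1]$, so $0 \le \mathrm{Dose} \le DQt \le
mas$, and the dose is nondecreasing in each score and scale-equivariant
(multiplying all scores and `mas` by $c$ multiplies the dose by $c$). The
mean is the unweighted arithmetic mean of exactly those three scores; no
alternative weighting is implemented because none has been validated, and
this weighting is known to compress dose variability somewhat — a limitation
to keep in mind when interpreting between-IRG spread. Doses are stored
unrounded; round only for display.

Because the formula is nonlinear, the dose of mean scores is not the mean of
doses: applied to published year-1 education mean scores (13.6, 12.2, 12.2,
11.4) it gives 8.1147, close to but not identical with the corresponding
published mean dose of 8.2 — the residual is rounding of printed means plus
the mean-of-doses/dose-of-means gap. The acceptance checks assert this
agreement at a tolerance of 0.15.

Doses are collective: `assign_doses_to_targets()` copies every IRG dose,
verbatim, to every target person of the setting, for use in later
on-treatment outcome analyses. No individual-level dose is modelled.

## Analysis

`describe_doses()` produces the standard implementation-description table
(N, mean, sample SD, median, quartiles, min, max) per strategy ×
activity-class × period. Quartiles use linear interpolation between order
statistics (`stats::quantile` type 7) — the most common convention; nothing
in the method dictates another. A single-dose group reports SD 0 with
`n = 1` flagging the degeneracy.

**Contrasts.** `compare_active_control()` compares mean doses between the
settings assigned a strategy and its controls. NPDA doses are contrasted by
default because they are the only class defined on both arms. Inference is a
two-sided permutation test shuffling active/control labels at the setting
(cluster) level: with 12-versus-12 clusters we prefer a design-based test
over distributional assumptions. The p-value uses the add-one rule
$(b+1)/(n_{perm}+1)$, so it is never exactly zero and the test is valid
(conservative) at any permutation count.

**Interactions.** When a setting is active for two strategies at once, their
doses may not add. `interaction_analysis()` classifies settings into the
four factorial cells (neither, A-only, B-only, both) and estimates

$$I = \bar d_{both} - (\bar d_{A} + \bar d_{B} - \bar d_{neither}),$$

negative $I$ meaning sub-additivity (antagonism). The permutation null
shuffles strategy B's labels within the strata of strategy A, preserving A's
main effect. The significance procedure behind the original study's bolded
contrasts was not reported; permutation inference here is a principled
replacement, not a replication.

## The synthetic expert panel

Because per-IRG expert scores of any real study are unpublished, validation
rests on a generator with known truth:

* **True scores** (`generate_true_scores()`): per cell,
  $\mathcal N(\mu_{class} - decay \cdot (period-1),\ \sigma_{true}^2)$
  clamped to $[0, mas]$. Defaults ($\mu_{NPDA} = 11.5$, $\mu_{PDA} = 12.5$,
  $\sigma_{true} = 2.5$, decay 1) were chosen once so that implied mean doses
  fall in the 5–9 range and score-level SDs in the 1.5–2.6 range that
  published application tables report, with a lower second period. A
  configurable `interaction` parameter shifts the generating means of a
  strategy pair in settings active in both, making the truth depart from
  additivity by construction.
* **Expert scores** (`generate_expert_scores()`): round-1 score =
  truth + group offset + $\mathcal N(0, \sigma_{rater}^2)$, clamped. Default
  $\sigma_{rater} = 2$ sits just under the SD debate threshold so that some,
  not all, cells are debated; default offsets $(-2, 0, +2)$ straddle the
  0.8–2.8-point adjustment range reported in the field application. Cells
  the debate rule flags receive round-2 scores drawn with $\sigma_{rater}/2$
  around truth + offset — debates seek consensus, so round 2 shrinks toward
  the target; no behavioural model of deliberation is attempted.
* **Factorial dose generator** (`simulate_factorial_doses()`): draws doses
  directly as cell mean + noise on a $2\times2$ design. Interaction
  recovery and permutation-size checks use this dose-scale generator rather
  than the score-level one: the score-to-dose map is nonlinear, so a
  score-scale shift of $-2$ does not correspond to a dose-scale interaction
  of $-2$; a dose-scale generator is the right instrument for validating the
  analysis stage against a configured dose-scale effect.

What passing these tests shows — and does not show. The generator is
normal-with-clamping and its raters are exchangeable within groups; real
expert panels have correlated judgements, anchoring on the first sheet
scored, and indicator-specific difficulty. Recovery of offsets and
interactions under the generator validates the *computations*, not the
behavioural assumptions of any particular panel.

## Numerical choices and degenerate inputs

* Sample SD everywhere a dispersion is reported; SD of a single value is
  reported as 0 alongside `n = 1`.
* Threshold comparisons are strict; permutation p-values use add-one;
  permutation comparisons of $|stat|$ use a $10^{-12}$ slack so ties under
  exact arithmetic count as ties.
* Scores are clamped to $[0, mas]$ after calibration and after every
  generator draw; clamping can bias calibration when true scores sit near
  the scale ends — keep fictitious-IRG difficulty mid-scale.
* Incomplete (IRG, class, period) triples — fewer than four cells — are
  skipped, reported in the `incomplete` attribute of `build_score_sets()`,
  and never silently imputed. PDA score sets on control IRGs are an error,
  not a warning.
* Empty inputs return empty tables; empty arms or empty factorial cells are
  errors (`irgdose_insufficient_group`, `irgdose_degenerate_design`).

## Problem sizes used in the validation suite

The bundled checks run the full published-scale configuration (72 IRGs, 216
doses) for the structural and exactness checks; 200 replicates of a small
two-intervention programme for offset recovery (tolerance
$2\sigma_{rater}/\sqrt{6 \times 8}$, the Monte-Carlo SE implied by 6 experts
scoring 8 fictitious cells); 100 replicates for interaction recovery; and
500 replicates × 999 permutations for the size of each permutation test —
sizes chosen so the whole suite completes in about a minute on a laptop
while keeping Monte-Carlo error well below the tolerances asserted.

## Limitations

* The dose is collective; within-IRG heterogeneity between target persons is
  invisible to it.
* The calibration model is additive per group; a group that is severe only
  on, say, participation quality needs the per-cell variant.
* The published application's dose tables derive from unpublished per-IRG
  expert scores, so they cannot be reproduced; the package validates
  structure, formula consistency and parameter recovery instead.
* Covariate-adjusted (multivariate) dose analyses are deliberately out of
  scope — once doses are computed, any regression framework can consume
  them.
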