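---
title: "Methods: sexual isolation indices, hydrocarbon compositions and desiccation survival"
author: "isopair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sexual isolation indices, hydrocarbon compositions and desiccation survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopair)
```

# Scope

`isopair` implements the three quantitative analyses that recur in pairwise
premating-isolation studies of *Drosophila* pheromone polymorphism: sexual
isolation statistics on 2x2 mate-choice contingency tables, compositional
analysis of cuticular hydrocarbon (HC) profiles quantified by gas
chromatography, and median survival duration under desiccation stress. A
fourth module generates synthetic data with the statistical structure the
analyses assume, so every estimator can be exercised and calibrated without
external data. The bundled fixtures describe three African *D. simulans*
strains — Eg (Egypt, 7-tricosene-rich), ST (São Tomé, intermediate) and Cam
(Cameroon, 7-pentacosene-rich).

# Sexual isolation statistics

## Model

A mate-choice experiment with strains $A$ and $B$ yields a 2x2 table of
copulation counts $o_{ij}$ indexed by (female strain, male strain), female
first, with total $T$. Expected counts under random mating come from one of
two null models:

* **marginal product** (default): $e_{ij} = r_i c_j / T$, preserving the
  observed sex-specific margins and thereby discounting differences in
  mating propensity;
* **uniform**: $e_{ij} = T/4$, the fully symmetric null.

The pair sexual isolation coefficients are $\psi_{ij} = o_{ij}/e_{ij}$; the
pair total index (PTI) is the observed/expected frequency ratio
$(o_{ij}/T)/(e_{ij}/T)$, numerically identical for a single table but
answering a different question (total deviation, combining sexual selection
and isolation). The joint index is

$$I_{PSI} = \frac{\psi_{AA} + \psi_{BB} - \psi_{AB} - \psi_{BA}}
                 {\psi_{AA} + \psi_{BB} + \psi_{AB} + \psi_{BA}} \in [-1, 1],$$

with $-1$ complete disassortative, $0$ random, $+1$ complete assortative
mating. Which null the original isolation software used per design is not
documented; we default to the marginal product, which reproduces seven of
the nine bundled design/pair estimates within $\pm 0.005$, and expose
`model = "uniform"` as a switch rather than baking a guess in. Two bundled
rows (ST/Cam female-choice and multiple-choice) are *not* reproduced by
either null from their own counts — the published $-0.110$ corresponds to
$+0.111$ and the published $0.124$ to an exactly-random table scoring $0$ —
and are carried as documented discrepancies, not as checks.

```{r}
tabs <- matingChoiceTables()
round(sapply(tabs, ipsi), 3)
```

## Bootstrap inference

Uncertainty comes from resampling the $T$ observed copulations
multinomially at the observed pair frequencies (per-trial outcomes beyond
the copulating pair are not recorded in such tables, so trials cannot be the
resampling unit). Each replicate re-estimates $I_{PSI}$; the replicate SD is
the reported standard deviation, and the p-value for deviation from random
mating is the two-tailed sign-crossing proportion
$2\min(\Pr(I^* \le 0), \Pr(I^* \ge 0))$, capped at 1. Replicates that draw
an empty margin (possible for sparse tables such as (6, 44, 4, 46)) are
recomputed under the uniform null rather than discarded, so the replicate
count is exact and the SD is not biased by selective dropping. Results are
bit-reproducible given the recorded seed.

With 10,000 replicates the Monte-Carlo SE of a p-value near 0.05 is about
0.002, which matters for the two bundled rows whose p sits at 0.045–0.048:
single runs occasionally flip across 0.05, so reproducibility checks in the
test-suite aggregate a fixed bank of seeded runs by their median p.

## Latency comparisons

Courtship/copulation latencies across pair types are compared by the
Kruskal–Wallis test (tie-corrected H via midranks), followed by the
rank-mean-difference criterion: groups $i, j$ differ at family level
$\alpha$ when
$|\bar R_i - \bar R_j| \ge z_{1-\alpha/(k(k-1))}
\sqrt{\tfrac{N(N+1)}{12}(\tfrac1{n_i} + \tfrac1{n_j})}$ — a Bonferroni-style
correction over the $k(k-1)/2$ pairs. This is the standard large-sample
criterion; exact agreement with any particular convenience implementation
is not claimed. Decisions are summarised as a compact letter display
(insert-and-absorb): groups sharing no letter differ.

# Hydrocarbon profiles

## Quantification

Each fly's chromatogram is reduced to peak areas over a declared panel plus
an internal standard of known mass (default 500 ng n-hexacosane). Absolute
amounts follow the area-ratio rule
$ng_n = (area_n / area_{std}) \times mass_{std}$; relative abundances are
each peak's share of the summed HC area. Both exclude the standard. The map
is homogeneous — rescaling all areas leaves the profile unchanged — which is
what makes between-sample comparison meaningful despite injection-volume
variation.

## Compositional statistics

Proportions carry a unit-sum constraint, handled two ways:

* **arcsine-square-root transform** $t = \arcsin\sqrt p$ (radians) before
  per-HC one-way ANOVA — the variance-stabilising convention for
  proportion responses;
* **log-contrasts** $\log_{10}(p_n / p_{denom})$ against a designated
  denominator HC, removing the constraint and reducing the trait count by
  one. Differences of log-contrasts between two HCs are
  denominator-invariant, so the denominator choice is a presentation
  convention, not a modelling one.

The male denominator defaults to 2-Me-C24. Field descriptions sometimes
name a "2-Me-C22" denominator, but no such peak occurs in the bundled
panel; 2-Me-C24 is the only C24 methylalkane present and is used instead,
with the discrepancy noted here. Compositional zeros are a hard error by
default; `zeroPolicy = "replace"` imputes half the smallest observed
nonzero proportion (multiplicative replacement) for screens where dropping
flies is worse than imputing.

Per-HC inference is a one-way ANOVA (`stats::aov`) with Tukey's HSD
(`stats::TukeyHSD`) over all group pairs on the transformed values,
flagging at 0.05/0.01/0.001. The Tukey procedure is itself the
multiple-comparison correction across group pairs; no additional family
correction is applied across the panel's HCs, since each HC is reported as
a separate trait. Note that a mean shift confined to a single HC is only
well-defined in log-contrast space: in raw proportion space the unit-sum
constraint redistributes any shift across all components.

Two scalar summaries mirror the field's reporting: the phenotype ratio
(7-tricosene over 7-pentacosene proportion), which orders the bundled
strains Eg (12.7) > ST (0.59) > Cam (0.38), and the percent difference of
total HC loads, $100(ref - other)/ref$.

# Desiccation survival

Mortality is recorded at fixed inspections (default every 0.5 h) for a
group of $n_0$ flies; a death recorded at inspection $k$ occurred within
$(t_{k-1}, t_k]$, so the survival step function drops at $t_k$. The median
survival duration (MSD) is the time the curve crosses the 0.5 level, in
decimal hours: we interpolate linearly between the bracketing inspections
(an "intercept" of a plotted curve implies interpolation; a pure step rule
is available via `method = "step"`), return grid times hit exactly, and
raise an explicit censored-median error for records never reaching 50%
mortality rather than extrapolating — the assays emulated here run to
extinction. Confidence intervals resample the $n_0$ individual
death-interval assignments multinomially (survivors past the last
inspection form a censored category) and take percentile bounds; censored
replicates are excluded, and more than 50% censoring aborts with an
unstable-estimate error.

# Synthetic data generators

The generators define the study conditions under which the pipeline is
validated:

* **Mate-choice trials** (`simMatingTrials`): per trial, with probability
  $1 - p_{no}$ one pair copulates, chosen proportionally to a 2x2
  propensity matrix restricted to the design's available pairs. In
  male-choice trials the tested male's strain alternates between trials
  (mirroring the balanced ~50/50 margins of the emulated experiments);
  female-choice is symmetric. The homotypic-advantage parameterisation
  $w_{homo} = 1+s$, $w_{hetero} = 1-s$ makes the multiple-choice expected
  $I_{PSI}$ equal $s$ exactly, which is what the parameter-recovery and
  coverage checks exploit. The non-mating probability for emulating a
  bundled design is taken from its replicate/mating counts (e.g.
  $1 - 100/108$).
* **Peak tables** (`simPeakTables`): per-fly compositions are
  Dirichlet($c \cdot \bar p$), totals lognormal, areas back-computed
  against a unit internal standard. `profileModelFor()` calibrates $c$
  from the bundled mean ± SEM summaries ($n = 10$) as the median over HCs
  of $p(1-p)/SD^2 - 1$ (about 600 for Eg males), and the total CV as
  $SEM\sqrt{n}/mean$ (0.15–0.16). A single concentration cannot match
  every per-HC SEM simultaneously; the median is the one-number compromise
  and is chosen once, not refit per experiment.
* **Death records** (`simDesiccation`): Weibull death times with the
  stated median; the shape defaults to 6, a steep die-off typical of acute
  desiccation assays (the emulated study prints only medians, 6.4–11.5 h,
  not raw counts, so the shape is a modelling choice, stated here once).

What the generators deliberately do *not* emulate: courtship
microstructure, correlations between HCs beyond the Dirichlet's negative
coupling, temperature dependence, and non-Weibull mortality. Passing tests
therefore certify the estimators under these stated conditions, not the
full biology of real assays. Latencies for exercising the Kruskal–Wallis
path are exponential per pair type — synthetic only.

# Numerical choices and problem sizes

Counts must be whole numbers (no continuity corrections anywhere);
degenerate margins, censored medians and compositional zeros are errors
naming the offending margin/record/component rather than silent fixes.
Validation uses exhaustive enumeration of all 2x2 tables with $T \le 12$
against a first-principles oracle (agreement to $10^{-12}$), 200-simulation
coverage experiments at $T = 500$ per isolation level, 100-replicate MSD
round trips at $n_0 = 100$, and 10,000-replicate null calibrations of the
ANOVA and Kruskal–Wallis type-I error — sizes at which Monte-Carlo error is
a small fraction of each tolerance while the whole suite stays quick.

# Limitations

Strictly pairwise (2x2) designs; no mating-propensity asymptotics beyond
PTI; each log-contrast is analysed separately (no multivariate ordination);
no parametric survival fitting beyond the generator's internal Weibull; and
the two discordant bundled isolation rows are reported as discrepancies
rather than resolved, since their printed values cannot be derived from
their own printed counts under either null.
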