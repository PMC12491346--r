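---
title: "Decision-tree cost-effectiveness of FET PET for treatment-related changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-tree cost-effectiveness of FET PET for treatment-related changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetcea)
```

## The clinical problem and the model

After radio- and chemotherapy, treated CNS lesions in children and
adolescents frequently develop imaging changes — pseudoprogression and other
treatment-related changes (TRC) — that mimic tumor relapse on MRI. Amino-acid
PET with [18F]FET discriminates neoplastic from treatment-related tissue and
can spare patients unnecessary salvage therapy, but it costs money. This
package asks the health-economic question: what does each *additional
correctly identified TRC lesion* cost when FET PET is added to (or replaces
reliance on) conventional MRI?

Two decision trees cover two clinical scenarios:

* **Model 1** — PET and MRI are read together from the outset, and the
  combined reading is compared with MRI alone on the same 83 lesions
  (92 scans). Chance nodes: N1/N2 give the probability that the combined
  reading / MRI alone rates a lesion as relapse; N3–N6 give the probability
  that a rated-relapse or rated-TRC call is confirmed (by neuropathology or
  clinicoradiological follow-up) for each strategy.
* **Model 2** — routine MRI was already suspicious for relapse and PET is the
  adjudicator (22 lesions). N1 is PET's rated-relapse probability; N2/N3 the
  confirmation probabilities of its two calls.

### The effectiveness statistic

The primary outcome is the probability that a lesion whose confirmed
diagnosis is TRC was *rated* TRC by the strategy — recall on confirmed-TRC
lesions. Walking the tree with rated-relapse probability $p_1$,
relapse-confirmation probability $p_r$ and TRC-confirmation probability
$p_t$:

$$\mathrm{eff} \;=\; \frac{(1-p_1)\,p_t}{\,p_1(1-p_r) + (1-p_1)\,p_t\,}$$

The numerator is the mass of lesions rated TRC and confirmed TRC; the
denominator adds the confirmed-TRC lesions hiding in the rated-relapse
branch. This is the unique simple statistic that reproduces every headline
value at once: with the model-1 count ratios the combined strategy scores
$100\%$ (every rated-relapse call was confirmed, $p_r = 1$, so no TRC lesion
can be misfiled), MRI alone scores $10/21 \approx 48\%$, the incremental
effectiveness (IE) is $11/21 \approx 52\%$, and model 2 scores exactly
$9/10 = 90\%$:

```{r basecase}
fit1 <- cea_model(study_fixture("model1"), model_id = "model1")
fit2 <- cea_model(study_fixture("model2"), model_id = "model2")
fit1
fit2
```

A structural consequence worth knowing: when $p_r = 1$ the statistic equals
1 *independently of* $p_1$ and $p_t$. That is why varying model-1 N1 or N4
in the sensitivity analysis leaves the ICER untouched.

### Costs and ratios

Per-scan costs are exact sums of itemized German fee-schedule (GOÄ) entries,
held as integer cents: EUR 1,566.33 per FET PET and EUR 987.80 per MRI scan.
Because 92 scans were performed on the 83 model-1 lesions, per-lesion costs
carry the scan factor $92/83$; model 2 uses one PET scan per lesion. The
ratios are

$$\mathrm{ICER} = \frac{C_{\mathrm{PET+MRI}} - C_{\mathrm{MRI}}}{\mathrm{eff}_{\mathrm{PET+MRI}} - \mathrm{eff}_{\mathrm{MRI}}},
\qquad
\mathrm{CER} = \frac{C_{\mathrm{PET}}}{\mathrm{eff}_{\mathrm{PET}}}.$$

The model-1 ICER numerator reduces to the PET scan cost times the scan
factor. Division by the *unrounded* IE of $11/21$ gives EUR 3,314.51; feeding
in the display-rounded node percentages instead drifts by a few euros (e.g.
CER 1,744.24 vs 1,740.37 in model 2), which is why the count ratios are the
canonical base-case inputs and rounding happens exactly once, at display
time.

## The reconstructed cohorts

The per-lesion counts behind the node values are not published as a table.
They are recovered as the unique small-integer contingency tables consistent
with the rounded node percentages (65/82/100/72/84/67 and 46/90/75), the
headline effectiveness values and the cent-level ratios; the test suite
re-verifies uniqueness by brute-force enumeration over all integer tables.
Two aspects of `study_fixture()` are arbitrary and documented as such: which
9 of the 83 lesions carry the second scan (costs depend only on the 92/83
total), and the cross-tabulation of the two strategies' ratings within a
confirmed class (the analysis only uses the per-strategy margins; the
fixture maximises rating agreement).

## One-way deterministic sensitivity analysis

Each chance node in turn is set to the ends of its interval, everything else
held at base, and effectiveness and the ratio are recomputed through the
same code path as the base case (`one_way()` simply re-fits `cea_model()` at
the endpoint). Published interval endpoints are display-rounded; the bundled
configurations carry the exact intervals — base value ± 15 percentage points
for the SD-8 nodes and ± 7.5 points for the SD-4 nodes, i.e. ± 1.875 SD —
around the unrounded count ratios. With these, the package reproduces the
published one-way ratio cells essentially exactly (most to the cent; the
test suite asserts 1.5 percentage points on effectiveness and 2.5% on
ratios, the slack published rounding can introduce):

```{r dsa}
cfg1 <- read_model_config(example_config("model1"))
base1 <- cea_model(cfg1$nodes, costs = cfg1$costs)
tornado_table(base1, cfg1$dsa)
```

The model-1 N3 upper endpoint (107.5%, printed 108%) is *theoretical*: the
base value is already 100%, so the varied value and the resulting
effectiveness leave $[0,1]$. Such rows are computed and flagged, never
clamped. Tornado bars are ordered by the ratio range they induce; no
ordering rule is published, and by this rule model 2's N2 bar (CER range
261 EUR) narrowly beats N1 (228 EUR) even though N1 has the widest
effectiveness range.

## Probabilistic sensitivity analysis

`run_psa()` draws, per iteration, every chance node independently from a
normal distribution with the base value as mean and the published SD
(8 points for rating nodes, 4 for confirmation nodes), *conditioned on being
positive by rejection* — redrawing at $\le 0$ rather than clipping or taking
absolute values, which preserves the normal shape where its mass lies (the
truncated mass is negligible for all study parameters). Draws above 1 are
retained and flagged theoretical; with N3 centred at 100% about half the
model-1 draws push the combined effectiveness past 100%, which is exactly
how the published Monte Carlo table shows a mean combined effectiveness of
101% and a negative minimum for the MRI column (a node drawn above 1 makes
one branch mass negative). Costs are drawn from a gamma distribution
parameterized by mean and coefficient of variation (default 0.5, i.e. SD =
50% of the mean): shape $1/\mathrm{cv}^2 = 4$, scale $\mathrm{mean}\cdot
\mathrm{cv}^2$.

Numerical choices:

* Draws whose effectiveness denominator is within $10^{-12}$ of zero are
  excluded and counted; more than 1% exclusions aborts. Per-draw
  cost/effectiveness quotients with $|\text{denominator}| < 10^{-9}$ are
  likewise excluded from the mean-of-ratios with a count. In practice no
  draw is excluded at the study parameters.
* The headline "mean ICER/CER" is the **ratio of means** (mean cost divided
  by mean IE or effectiveness); the mean of per-draw ratios is reported
  alongside but is a different, heavier-tailed statistic. Only the ratio of
  means reproduces the published Monte Carlo CER.
* Percentiles interpolate linearly between order statistics (the default
  quantile rule); none is published.
* Node draws are mutually independent; no correlation structure is
  described, and the latent-truth coupling used by the *generator* is a
  statement about lesions, not about parameter uncertainty.
* Default 10,000 draws (the published setting; a few seconds of runtime).
  Reproducibility is exact: one seed governs the node and cost draws in a
  fixed order, so identical configuration and seed give a bit-identical
  draw table.

```{r psa}
psa1 <- run_psa(base1, psa_config(n_draws = 10000, seed = 42))
psa1
```

The published 95% CI strings accompanying these Monte Carlo means are
internally inconsistent (the source itself notes the point estimates fall
outside them) and are deliberately not reproduced; the percentile columns
above are the distributional summary.

## The synthetic cohort generator

`generate_cohort()` emulates lesion-level data with the tree's statistical
structure: model 2 draws each rating Bernoulli($N1$) and the confirmed
diagnosis conditionally on it; model 1 draws a shared latent truth first
(both strategies rate the *same* lesion), with per-strategy rating
probabilities given truth back-solved via Bayes' rule and ratings
conditionally independent given truth. A specification whose two strategies
imply different confirmed-TRC prevalences is rejected with both implied
values, as are back-solved conditionals outside $[0,1]$.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: scan timing and longitudinal follow-up, reader
correlation beyond the shared truth, patient-level clustering of multiple
lesions, and any covariate structure (age, histology, prior therapy).
Parameter-recovery tests (estimates within 3 binomial SEs of the generating
values at $n = 10^5$) validate the estimator/generator pair, not the
clinical transportability of the node values.

## Limitations

Costs are a single-payer fee-schedule snapshot (no discounting, no currency
conversion, no downstream treatment costs); effectiveness is a per-lesion
diagnostic quantity, not survival or quality-adjusted life; and the node
probabilities rest on two modest cohorts, which is precisely why the
deterministic and probabilistic sensitivity machinery is the larger half of
the package.
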