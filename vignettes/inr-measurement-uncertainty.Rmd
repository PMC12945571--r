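---
title: "Measurement uncertainty of INR results in a thromboplastin reference measurement system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement uncertainty of INR results in a thromboplastin reference measurement system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inrmu)
```

## The measurement model

Oral-anticoagulation monitoring reports the prothrombin time (PT) as an
International Normalized Ratio,

$$\mathrm{INR} = \left(\frac{\mathrm{PT}}{\mathrm{MNPT}}\right)^{\mathrm{ISI}},$$

which normalizes clotting times across thromboplastin reagents. The MNPT
(mean normal PT) is the geometric mean of the PTs of about 20 healthy
donors; the ISI (International Sensitivity Index) is assigned to each
thromboplastin/measurement system by calibration against a WHO
international reference preparation (IRP). At the top of this traceability
chain sits a reference measurement system (RMS): a small network of
calibration laboratories running a harmonized manual tilt-tube technique
with the primary IRP. This package quantifies the standard measurement
uncertainty (MU) that the RMS itself contributes to an INR.

A mechanistic kinetic model of the clotting cascade is not realistic —
too many coagulation factors with unknown concentrations interact — so the
MU is estimated empirically in log space. Because the INR is a power of a
ratio, everything becomes additive on the natural-log scale,
$\ln \mathrm{INR} = \mathrm{ISI}\,(\ln \mathrm{PT} - \ln \mathrm{MNPT})$,
and first-order (GUM/EURACHEM-style) error propagation over the three
independent input quantities gives

$$SD_{\ln INR} = \sqrt{\frac{(\mathrm{ISI}\cdot SD_{\ln PT})^2}{n}
  + \frac{(\mathrm{ISI}\cdot SD_{\ln MNPT})^2}{m}
  + (\ln R \cdot SD_{ISI})^2}, \qquad R = \mathrm{PT}/\mathrm{MNPT}.$$

The three addends are the components of a classic precision hierarchy:

* **PT repeatability** — same operator, $n$ replicate measurements of the
  same (lyophilized) plasma;
* **MNPT intermediate precision** — same operator across $m$ calibration
  studies over time;
* **ISI reproducibility** — the between-laboratory SD of the assigned ISI
  across the calibration network.

Covariance terms are deliberately omitted. The ISI is an external,
assigned quantity; the MNPT derives from prior calibration studies; the
control-plasma measurements are taken independently of both. The three
inputs are therefore treated as uncorrelated, and `inr_uncertainty()`
returns the three variance contributions (`term_pt`, `term_mnpt`,
`term_isi`) so the dominance structure is always visible — in practice the
ISI reproducibility dominates everywhere except at $R \approx 1$, where
$\ln R \to 0$ annihilates the ISI term entirely.

Derived quantities, all on the natural-log scale (no base-10 option is
offered; the log base is part of the reporting convention, not a tunable):

* **Expanded interval**: $\exp(\overline{\ln INR} \pm k\,SD_{\ln INR})$
  with coverage factor $k = 2$ by default (~95% under log-normality). The
  interval is geometrically symmetric: the geometric mean of its bounds is
  the mean INR.
* **Relative uncertainty**: $\%ru \approx 100 \times SD_{\ln INR}$, the
  small-SD log-normal approximation used for reporting; the exact
  conversion $100(e^{SD}-1)$ is available (`mode = "exact"`) and always
  exceeds the approximation by at most $100\,SD^2$ for $SD \le 0.2$.

### Conventions for the summary statistics

The "mean PT" of a replicate set is taken as the **geometric** mean, and
`sd_log_pt` as the sample SD of $\ln PT$ with the $n-1$ denominator —
consistent with the log-space model and with the MNPT's own definition.
The mean log INR is computed from the summary geometric means,
$\mathrm{ISI}(\ln \overline{PT} - \ln \mathrm{MNPT})$, not by averaging
per-replicate INRs. $n = 1$ or $m = 1$ is allowed (early in a reference
preparation's life $m$ is genuinely small, e.g. $m = 2$), but the
corresponding SD must then be supplied externally — a log-scale SD is
never estimated from a single value. Internal computation is never
rounded; `render_report()` applies the conventional display rounding
(INR 2 decimals, $SD_{\ln INR}$ 3, interval bounds 2, %ru 1), and per-IRP
medians are computed on unrounded values before any rounding.

## Tunable parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `k` | coverage factor for the expanded interval | 2 | ~95% coverage under log-normality, the metrological convention |
| `ru_mode` | %ru conversion | `"approximate"` | matches how reference-system MU is reported; exact mode for sensitivity checks |
| `domain` (profile) | INR validity interval of the power fit | [1.0, 4.0] | prediction is endorsed only over the fitted range; outside it a domain error is raised unless `extrapolate = TRUE` |
| `total_ru_percent` | end-user MU budget | 10 | outcome-based performance specification: ±0.5 INR at a target of 2.5 gives a 20% expanded (10% standard) limit |
| `scheme` | budget split | `"thirds"` / `"half_reference"` | equal thirds (calibration labs / IVD manufacturers / end users, 3.3% each) is the rule of thumb; half to the reference thromboplastins is the pragmatic split once primary and secondary preparations coexist. Shares are linear in the CV, following the field's arithmetic; `budget_quadrature()` reports the root-sum-of-squares combination for context only |

## The precision profile

`fit_power_profile()` fits $\%ru = a\cdot \mathrm{INR}^b$ by ordinary
least squares on the log-log transformed pairs — the standard,
deterministic, closed-form choice for a power function (no iterative
nonlinear fit is needed, and with only four support points a two-parameter
closed form is all the data can carry). Noise-free power-law points are
recovered to machine precision, which the test suite asserts. The fitted
coefficients for the bundled IRP 24/114 points are checked against an
independent normal-equations oracle, not against any published value —
the profile's coefficients are derivable only from the per-plasma table.

## The Monte Carlo oracle

`simulate_log_inr()` draws the sampling counterpart of the propagation:

$$\ln INR^* = \mathrm{ISI}^* (\ln PT^* - \ln MNPT^*)$$

with $\ln PT^* \sim N(\ln\overline{PT},\, SD_{\ln PT}/\sqrt n)$,
$\ln MNPT^* \sim N(\ln MNPT,\, SD_{\ln MNPT}/\sqrt m)$ and
$\mathrm{ISI}^* \sim N(\mathrm{ISI},\, SD_{ISI})$ truncated below at zero.
Normality on the log-time scales follows from the log-normal working model
for clotting times; for the ISI error no distributional law is standard,
and a (truncated) normal is adopted as the conventional default for an
assigned quantity. `validate_delta_method()` compares the empirical SD of
the draws with the analytic value using the normal-theory standard error
of an SD, $SE \approx sd/\sqrt{2N}$ (adequate for $N \ge 10^4$), passing
at $|z| \le 3$.

Numerical design choices:

* one master seed drives three deterministic sub-streams, one per
  uncertainty source, so zeroing one SD never shifts another source's
  draws (the test suite exploits this additivity directly);
* the first-order formula omits the variance of the
  $\mathrm{ISI}\times\ln R$ product, so the empirical SD slightly exceeds
  the analytic one; at the realistic SDs of the bundled table the excess
  is far below the Monte Carlo resolution at $N = 10^5$. Inflating
  $SD_{ISI}$ to implausible values (e.g. 0.5) makes the omission visible:
  at $R = 1$ the analytic ISI term is exactly zero while the simulated
  spread is not, and the validator flags the breakdown. Away from $R = 1$
  an inflated ISI SD also interacts with the zero-truncation, which can
  push the empirical SD *below* the analytic value — a reminder that the
  validator tests the whole distributional model, not just the
  second-order term.

## The synthetic multicenter study generator

`generate_study()` emulates the design of a reference-system calibration
exercise: **4 calibration laboratories × 2 operators**, each operator
measuring **n = 10** replicate PTs per lyophilized plasma, determining an
MNPT as the geometric mean of a **20-donor** panel, and working with an
ISI realization drawn around the assigned value with the
between-laboratory SD. Replicate and donor PTs are log-normal around
their generating truths; operator ISI realizations are independent (no
lab-level random effect is added, since the between-operator SD is pooled
over the whole network without a published variance decomposition).

The per-plasma replicate noise defaults to `sd_log_pt = 0.016` and the
ISI spread to `sd_isi = 0.030`, the magnitudes observed with the current
primary IRP. The donor-level spread defaults to `donor_log_sd = 0.05`, a
typical healthy-donor PT dispersion; with a 20-donor panel this puts the
MNPT's own SD at $0.05/\sqrt{20} \approx 0.011$, the same magnitude as the
observed MNPT intermediate precision ($0.016/\sqrt 2$) — the generator
exposes both knobs because only the latter is observable in summary data.

`estimate_parameters()` recovers exactly the summaries the bottom-up
analysis consumes ($n-1$ denominators throughout; the sample SD of 8
operator ISIs carries the usual $c_4(8) \approx 0.965$ small-sample bias,
which the parameter-recovery tests account for). `between_operator_cv()`
computes the top-down counterpart: each operator's INR from their own
geometric-mean PT, MNPT and ISI realization, then $100\times SD/\text{mean}$
across operators on the INR scale — the convention in which multicenter
between-operator CVs are reported. The package's headline stochastic
property, asserted in the test suite over 500 seeded studies, is that this
top-down CV tracks the bottom-up analytic %ru for a therapeutic-window
plasma within 15% relative — the two independent routes to the same
uncertainty agree.

What the generator does **not** emulate: the manual tilt-tube measurement
process itself (timing, duplicate readings, operator harmonization),
lab-level clustering of ISI errors, commutability differences between
lyophilized and fresh plasmas, or drift over calibration studies. Passing
tests therefore validate the statistical machinery under the stated noise
model, not the behaviour of any particular laboratory's raw data.

## Degenerate inputs and edge behaviour

* All-zero SDs propagate to an exactly zero $SD_{\ln INR}$, a zero-width
  interval, and Monte Carlo draws identical to the mean — useful as exact
  fixtures.
* $R = 1$ (PT equal to MNPT) forces INR = 1 regardless of the ISI and
  removes the ISI contribution exactly.
* Budget checks use a strict inequality (`ru < share`), matching the
  "< 3.3%" form of the specification; ties fail.
* CSV validation reports the first offending row and column; a
  `replicates` column of semicolon-joined raw PTs may replace the summary
  columns and is reduced with the same estimators used everywhere else.

## Problem sizes

The worked-example analyses are deterministic and instantaneous. The
stochastic checks in the test suite use $10^5$ Monte Carlo draws per
parameter set (SD resolution $\approx 0.2\%$ relative) and 100–500
synthetic studies per property, sizes at which the sampling bounds quoted
above are comfortably discriminating; `scripts/acceptance.R` recomputes
the headline table-derived quantities from the packaged inputs.

## Known limitations

* The MU quantified here is the contribution of the reference measurement
  system measured with lyophilized, non-commutable plasmas; it does not
  quantify the MU of INR results on patient samples in routine
  laboratories.
* The first-order propagation understates the spread when $SD_{ISI}$ is
  large relative to $\mathrm{ISI}$; the Monte Carlo validator exists
  precisely to detect when that regime is entered.
* With $m = 2$ MNPT determinations the intermediate-precision component is
  itself estimated from minimal data; the formula propagates the supplied
  SD but cannot correct for its sampling error. The same caveat applies to
  an ISI SD estimated from eight operators.
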