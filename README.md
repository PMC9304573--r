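# ktcua

Lifetime cost-utility analysis of kidney transplantation strategies for
adults with end-stage kidney disease (ESKD), built for health economists
and nephrology policy analysts. The package re-implements, as a tested R
pipeline, the Thai three-way comparison of **preemptive living-related
kidney transplantation (P-LRKT)**, **non-preemptive living-related KT
(NP-LRKT)** and **non-preemptive deceased-donor KT (NP-DDKT)**.

## The model

A decision tree assigns a closed cohort (entry age 50) to a strategy; a
five-state Markov model — dialysis, transplant year, 1-year post-KT,
subsequent-years post-KT, death — then runs annual cycles to a lifetime
horizon. Key mechanics:

* Dialysis patients receive a transplant with annual probability 0.36
  (living-related) or 0.18 (deceased-donor) while aged ≤ 65; the
  preemptive cohort enters directly at the transplant state. Graft loss
  (0.04 in year 1, 0.01/yr after) returns patients to dialysis, with
  retransplantation allowed up to age 65.
* Mortality: a general-population life table scaled on the hazard scale
  by age-banded standardized mortality ratios (8.6 / 4.6 / 1.9 / 7.8 for
  50–59 / 60–69 / 70–79 / 80+), divided by 2.19 in the transplanted
  states: `q_state(x) = 1 − exp(−(−log(1 − q(x))) · SMR(x) / ratio)`.
* Discounted accumulation at rate r = 3%/yr:
  `Total = Σ_t (1+r)^(−t) Σ_s occ_s(t) · x_s`, where `x_s` is the state's
  annual cost or utility (dialysis 0.68, KT year 0.781, post-KT 0.889),
  plus one-off transplant-event and waiting costs. All costs 2020 USD.
* Comparison: ICER = ΔCost/ΔQALY against a willingness-to-pay of 5,113
  USD/QALY; a cheaper, no-less-effective strategy is *cost-saving*; net
  monetary benefit NMB = WTP·QALY − Cost drives the acceptability curves.
* Uncertainty: one-way DSA over 95% CIs (±15% fallback) with tornado
  output, and 1,000-draw probabilistic sensitivity analysis with
  moment-matched beta (probabilities, utilities) and gamma (costs)
  distributions, summarized on the cost-effectiveness plane and as CEAC.
* A synthetic patient-level cohort generator (40/50/50 patients, 10-year
  follow-up) and person-year estimators close the data-to-model loop for
  end-to-end testing.

See `vignettes/kidney-transplant-cua.Rmd` for assumptions, attachment
rules, numerical choices and calibration status.

## Worked example

```r
library(ktcua)
params <- load_parameters()        # packaged Thai base-case inputs
cua <- run_base_case(params)
print(cua)
```

```
Lifetime cost-utility analysis (discount 0.03, WTP 5113 USD/QALY)

 strategy     cost    ly  qaly cost_per_ly
   P-LRKT 160279.4 13.38 11.55    11979.60
  NP-LRKT 169283.9 12.78 10.68    13247.38
  NP-DDKT 160528.9 12.05  9.73    13322.23

Pairwise comparisons:
P-LRKT vs NP-DDKT (WTP 5113 USD/QALY)
  incremental cost -249.5 USD, QALYs gained 1.8204, ICER -137.06 USD/QALY -> cost-saving
P-LRKT vs NP-LRKT (WTP 5113 USD/QALY)
  incremental cost -9,004.51 USD, QALYs gained 0.8654, ICER -10,405.18 USD/QALY -> cost-saving
NP-LRKT vs NP-DDKT (WTP 5113 USD/QALY)
  incremental cost 8,755.01 USD, QALYs gained 0.9550, ICER 9,167.62 USD/QALY -> not cost-effective
```

Reading: each row gives a strategy's lifetime discounted cost (USD),
life-years, QALYs and cost per life-year. Preemptive LRKT yields the most
QALYs at the lowest cost — it is *cost-saving* against both alternatives —
while non-preemptive LRKT is strictly dominated, and its ICER against
NP-DDKT (9,167.62 USD per QALY gained) exceeds the Thai willingness-to-pay
threshold, so it is not cost-effective.

Uncertainty analyses:

```r
psa <- run_psa(params, n = 1000, seed = 1)
ce_plane(psa, "P-LRKT", "NP-DDKT")   # quadrant and WTP-line fractions
plot(ceac(psa))                      # acceptability curves
plot(one_way_dsa(params))            # tornado diagram
```

Synthetic-cohort round trip:

```r
coh <- generate_cohort(params, seed = 1)   # 140 patient-level records
est <- estimate_inputs(coh)
params2 <- apply_estimates(params, est)    # re-estimated inputs
```

A thin command-line wrapper lives at `inst/scripts/ktcua.R`
(verbs `run`, `dsa`, `psa`, `ceac`, `simulate-cohort`, `report`).

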