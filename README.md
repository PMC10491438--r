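# dtascea

Decision-analytic cost-effectiveness modelling of **direct transfer to the
angiography suite (DTAS)** versus **initial transfer to the emergency room
(ITER)** for patients with suspected large-vessel-occlusion (LVO) stroke.

For LVO strokes treated with endovascular thrombectomy, door-to-puncture
time drives outcome. Sending suspected-LVO patients straight to the
angiography suite shortens that delay for true LVOs but spends invasive
work-up and suite time on false positives. This package is for health
economists and stroke-care researchers who want to price that trade-off: it
implements a one-year decision tree over 90-day modified Rankin Scale (mRS)
outcomes coupled to a nine-year, five-state Markov cohort model
(mRS 0–1, 2–3, 4, 5, death), with age- and disability-dependent mortality

    q(s, a) = 1 − (1 − q0(a))^HR_s,

Dutch-guideline discounting (4% costs, 1.5% QALYs), and the standard
decision outputs

    ΔC = C_DTAS − C_ITER,   ΔE = E_DTAS − E_ITER,
    ICER = ΔC / ΔE,         NMB(λ) = λ·ΔE − ΔC,

plus scenario analyses, one-way (tornado) sensitivity analysis, Monte Carlo
probabilistic sensitivity analysis (PSA), and cost-effectiveness
acceptability curves. A synthetic parameter-set generator and an
independent patient-level microsimulation oracle make every stage testable
without any external data.

## Worked example

The packaged parameter file mixes publicly stated quantities (LVO
confirmation rate 147/174, entry age 74, discount rates, EUR 50,000/80,000
thresholds, scenario overrides) with clearly flagged *synthetic
placeholders* for everything only available in supplementary evidence
tables (outcome distributions, transitions, utilities, costs, mortality).
Numbers below therefore illustrate the machinery, not any real setting.

```r
library(dtascea)
params <- example_parameters()
base <- run_cea(params)
base
#> <cea_result: DTAS vs ITER>
#>   incremental cost 699.95, incremental QALY 0.4869
#>   ICER 1438 per QALY
#>   at threshold 50000/QALY: NMB 23646 -> cost-effective
#>   at threshold 80000/QALY: NMB 38253 -> cost-effective
```

DTAS buys 0.49 discounted QALYs per suspected-LVO patient for an extra
EUR 700, an ICER of EUR 1,438 per QALY — far below both Dutch
willingness-to-pay thresholds, so DTAS is cost-effective under this
(synthetic) parameterization. The canonical per-patient table across
scenarios (scenario 1: RACE>4-only triage, p_LVO = 0.42; scenario 2:
FAST-only all-comers, p_LVO = 0.12; scenario 3: 4-year Markov horizon), in
USD at the fixed 2021 rate of 1.1827:

```r
report_table(list(base = base, "1" = run_scenario(params, "1"),
                  "2" = run_scenario(params, "2"),
                  "3" = run_scenario(params, "3")), currency = "USD")
#>   scenario strategy  cost qaly delta_cost delta_qaly   icer
#> 1     base     DTAS 90764 2.56        828       0.49  1,700
#> 2     base     ITER 89936 2.07         NA         NA   <NA>
#> 3        1     DTAS 46669 1.27       1304       0.24  5,385
#> 4        1     ITER 45365 1.03         NA         NA   <NA>
#> 5        2     DTAS 15530 0.36       1640       0.07 23,707
#> 6        2     ITER 13891 0.29         NA         NA   <NA>
#> 7        3     DTAS 73042 1.64        420       0.31  1,359
#> 8        3     ITER 72623 1.33         NA         NA   <NA>
```

Costs and QALYs shrink with p_LVO because non-LVO patients contribute only
their diagnostic cost (their downstream care is strategy-independent and
cancels in the increments). Sensitivity analyses:

```r
tor <- tornado(params)                           # one-way, widest first
psa <- sample_psa(params, n = 10000, seed = 20230905)
curve <- ceac(psa)                               # acceptability curves
plot_ce_plane(psa); plot_ceac(curve); plot_tornado(tor, base_icer = base$icer)
```

See `vignette("stroke-triage-cea")` for the model's assumptions,
conventions (accrual timing, half-cycle, mortality/transition ordering),
the PSA distribution families, and the microsimulation validation.

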