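# cytotwin

Digital-twin simulation of cytarabine consolidation scheduling in acute
myeloid leukemia (AML).

After remission induction, AML patients receive consolidation cycles of
cytarabine (Ara-C) — on cycle days 1, 2, 3 (**AC-123**) or days 1, 3, 5
(**AC-135**), at high (HDAC, 3 g/m²) or intermediate (IDAC, 1 g/m²) dose,
optionally followed by lenograstim (G-CSF). The choice matters mainly
through two quantities:

* **kpiL** — WBC recovery time: days from cycle day 1 until the white
  blood cell count is back at ≥ 1×10⁹/L after the leukopenic nadir
  (shorter = less infection risk);
* **kpiB** — blast ratio: leukemic blast burden at cycle end divided by
  the burden at the start of consolidation (below 1 = net reduction).

`cytotwin` is an analysis workflow for comparing these schedules *in
silico*. It couples a Friberg-type transit-compartment model of
granulopoiesis (baseline $B$, feedback exponent $\gamma$, transit rate
$k_{tr}$) with one-compartment Ara-C kinetics and a linear-capped
proliferation effect $E=\min(\mathrm{slope}_w\,c,\,0.999)$, a
two-compartment leukemic blast population under a shared feedback signal
$s = 1/(1+k_s x_{\mathrm{wbc}})$, and subcutaneous G-CSF with
WBC-mediated clearance. Each virtual patient ("digital twin") is the
shared model plus six individual parameters
($B, \gamma, k_{tr}, \mathrm{slope}_w, p_l, l_0$). The package
enumerates the study's 334 treatment settings (111 lenograstim
start×duration schedules at fixed 42-day cycles, plus 28 alternative
cycle lengths × 2 G-CSF settings, for both dose cohorts), simulates
three consecutive cycles per twin and arm, extracts the KPIs, and
compares the arms with paired statistics and a Wei–Lin–Weissfeld (WLW)
marginal Cox model with cluster-robust variance (hazard ratio > 1 =
faster recovery).

The per-twin parameter tables of the underlying clinical studies are not
redistributed here; `make_virtual_trial()` generates synthetic cohorts
(30 HDAC + 35 IDAC twins, log-normal parameter spread, median age
58.5 y) with the same structure, and `load_cohort()` accepts an external
table in the documented layout.

## Worked example

Simulate one high-dose twin under both arms with the clinical G-CSF
block (start 5 days after the last Ara-C day, 5 days duration):

```r
library(cytotwin)
tw <- digital_twin("pt1", "HDAC", age = 58, bsa = 1.9,
  theta = individual_parameters(B = 7, gamma = 0.15, k_tr = 1.0,
                                slope_w = 1.5, p_l = 0.35, l0 = 1))
for (arm in c("AC123", "AC135")) {
  plan <- treatment_plan(arm, 3, gcsf_offset = 5, gcsf_duration = 5,
                         cycle_length = 42)
  print(kpi_records(simulate_course(tw, plan, schedule_id = "g55")))
}
#>   twin_id schedule_id   arm cycle kpiL leukopenia_d     nadir     kpiB eligible
#> 1     pt1         g55 AC123     1   12            3 0.6313618 1.986047     TRUE
#> 2     pt1         g55 AC123     2   12            3 0.6332665 4.133910     TRUE
#> 3     pt1         g55 AC123     3   12            3 0.6332679 8.604519     TRUE
#>   twin_id schedule_id   arm cycle kpiL leukopenia_d     nadir     kpiB eligible
#> 1     pt1         g55 AC135     1   14            5 0.3165898  2.135871    TRUE
#> 2     pt1         g55 AC135     2   14            5 0.3167768  4.846132    TRUE
#> 3     pt1         g55 AC135     3   14            5 0.3167828 10.995409    TRUE
```

This twin recovers on cycle day 12 under AC-123 versus day 14 under
AC-135, with a shallower nadir (0.63 vs 0.32 ×10⁹/L), shorter
leukopenia (3 vs 5 days) and a slightly smaller blast ratio — the
paired advantage the full study quantifies across twins and schedules.

## The analysis workflow

Numbered drivers under `analysis/` write tab-separated tables to
`results/`:

```sh
Rscript analysis/01_build_cohorts.R --seed 1      # virtual cohorts -> cohort table
Rscript analysis/02_grid_study.R    --seed 1      # KPI table + kpiL/kpiB heat grids
Rscript analysis/03_cycle_length.R  --seed 1      # cycle-length sweep curves
Rscript analysis/04_wlw.R           --seed 1      # paired comparison + WLW fits
```

`02` defaults to a documented 20-schedule reduction of the lenograstim
grid (`--grid full` runs all 111×2 settings; hours). On the default
synthetic cohorts, `04` prints:

```
kpiL reduced under AC-123 in 100.0% of 3064 paired cycles (median 2.0 d)
kpiB lower under AC-123 in 91.1% of 3900 paired cycles

Simulated records:
Wei-Lin-Weissfeld marginal Cox fit (6686 records, 62 subjects)
      factor   hr        ci      p
      arm123 2.64 2.35-2.98 <2e-16
        gcsf 1.91 1.74-2.08 <2e-16
 age_decades 1.10 0.90-1.35  0.332
```

i.e. AC-123 shortened recovery in every paired cycle (median 2 days),
without a blast penalty in 91% of cycles, and the marginal Cox model
attributes hazard ratios of ~2.6 (arm) and ~1.9 (G-CSF) to faster
recovery.

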