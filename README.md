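# fishplasma

Screening-level environmental risk assessment of pharmaceuticals relies on
the **Fish Plasma Model (FPM)**: under continuous aqueous exposure, the
steady-state concentration of an active pharmaceutical ingredient (API) in
fish blood plasma is predicted from the water concentration *W* by
blood:water partitioning,

    F_ss,PC = W × P_Blood:Water,        P_Blood:Water = 10^(0.73 · LogD_ow − 0.88)

and the water concentration expected to reach the human therapeutic plasma
level C_max — the **therapeutic water concentration (TWC)**, the trigger for
prioritising an API for in vivo fish testing — is

    TWC = C_max / P_Blood:Water.

This read-across assumes fish and humans not only share drug targets but
also share plasma protein binding. They often do not: only the unbound
fraction f_u of an API is pharmacologically available, and for anionic
drugs (e.g. NSAIDs) f_u can be more than an order of magnitude higher in
fish than in humans. `fishplasma` implements the refinement that corrects
for this using the **relative unbound fraction**

    Rf_u = f_u,fish / f_u,human          (median rule: f_u,median,fish / f_u,median,human;
                                          worst case:  f_u,max,fish / f_u,min,human)

    TWC_refined = (C_max / Rf_u) / P_Blood:Water(fish-pH LogD).

The package is aimed at ecotoxicologists and regulatory scientists running
FPM-based prioritisation, and covers the full path from raw assay data to
the screening table:

* **Dialysis analysis** — f_u from rapid-equilibrium-dialysis plasma/buffer
  concentration pairs (`compute_fu`), correction of diluted-plasma assays
  (`correct_dilution`, f_u10/(10 − 9·f_u10) at 10% plasma), total-recovery
  QC (`compute_recovery`), and replicate/laboratory aggregation into
  min/median/max summaries (`aggregate_fu`).
* **Interspecies ratios** — median and worst-case Rf_u (`rfu_summary`),
  prioritisation flags at the inclusive thresholds Rf_u,median ≥ 3 and
  Rf_u,max ≥ 10 (`classify_rfu`), per-speciation-group counts
  (`speciation_summary`).
* **Screening** — original and refined TWC, their ratio, and conservatism
  against chronic fish early-life-stage NOEC/LOEC values (`fpm_screen`,
  `assess_conservatism`).
* **Molecular predictors** — a penalized-spline additive model of
  (fourth-root) f_u on molecular weight, LogD, pKa and charge with a
  gamma/log-link family (`fit_fu_gam`), normality-driven transform
  selection (`transform_ladder`) and basis diagnostics
  (`check_basis_dimension`).
* **Synthetic assays** — a seeded generator of API panels and dialysis
  measurements with known latent f_u (`synthetic_config`,
  `generate_api_panel`, `simulate_dialysis`) for end-to-end validation.
* **Fixture** — a packaged 44-API rainbow-trout screening table with
  printed LogD(7.4)/LogD(7.9), C_max, worst-case Rf_u and effect
  concentrations (`load_fixture`), plus species plasma-pH/temperature
  contexts (`species_contexts`).

## Worked example

Screen the packaged 44-API table for rainbow trout with the worst-case
Rf_u rule:

```r
library(fishplasma)
fx  <- load_fixture()
twc <- fpm_screen(fx$apis, species = "rainbow_trout",
                  rfu = fx$rfu$rfu_trout_max_human_min, rfu_rule = "max")
subset(twc, api_name %in% c("Ibuprofen", "Phenylbutazone", "Propranolol"))
```

```
       api_name speciation p_bw_original p_bw_refined rfu_used twc_original
      Ibuprofen          A          1.19        0.569       55      12.5832
 Phenylbutazone          A          5.89        4.811      100       2.1238
    Propranolol          C          0.38        0.852        3       0.0526
 twc_refined twc_ratio
     0.47932     26.25
     0.02598     81.73
     0.00783      6.72
```

Reading the ibuprofen row: at LogD(7.4) = 1.31 the original model predicts
a TWC of 12.6 mg/L, but ibuprofen is 55-fold freer in trout plasma than in
human plasma (worst-case Rf_u), so the refined model lowers the
trout-specific TWC to 0.48 mg/L — a 26-fold higher priority. For the
cationic propranolol the correction is small (Rf_u = 3). Group-level
prioritisation counts:

```r
speciation_summary(fx$apis, fx$rfu$rfu_trout_max_human_min, threshold = 10)
```

```
        group n_flagged n_total  denominator
      anionic         8      14 measured_rfu
    unionized         2       8 measured_rfu
     cationic         1      19 measured_rfu
 zwitterionic         0       1 measured_rfu
```

Eight of the anionic APIs, but only one cationic API, exceed the 10-fold
worst-case threshold — the anionic bias that motivates the refinement.

A thin command-line wrapper over the same functions is installed at
`inst/cli/fpm.R` (subcommands `fu`, `screen`, `gam`, `simulate`,
`fixture`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fpm.R", package="fishplasma"))')" \
    screen --input fixture --species rainbow_trout --rfu-rule max \
    --out twc.csv --report report.txt
```

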