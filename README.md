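# iolpost

Intraocular lens (IOL) power calculation for eyes that have undergone myopic
laser refractive surgery (LASIK/PRK), built around the **refraction-derived
corneal power (Krd)** method.

## The problem

After myopic laser vision correction, standard keratometry misreads the
cornea: the anterior surface has been flattened while the posterior surface
is untouched, so index-based K readings overestimate total corneal power.
Feeding those readings into an IOL formula at cataract surgery produces the
classic *hyperopic surprise*. Scheimpflug tomography measures both corneal
surfaces (total corneal refractive power, TCRP, and total refractive power,
TRP), but even those values benefit from an empirical correction.

## The method

The package implements the Haigis thin-lens vergence formula with effective
lens position (ELP)

    d = a0 + a1·ACD + a2·AL        (a-constants per IOL model)

and the vergence chain (lengths in metres, n = aqueous index)

    z   = n / (d + n / (n/(L−d) − P))      required corneal-plane power
    R_c = z − D_c                          corneal-plane refraction
    R_x = R_c / (1 + R_c·dx)               spectacle-plane refraction

Because the Haigis ELP does not depend on K, the chain inverts in closed
form in every direction: predicted refraction for an implanted power,
IOL power for a target refraction, and — the core of the method — the
**refraction-derived K**: the corneal power that, with the implanted lens,
reproduces the achieved postoperative refraction exactly
(`back_calculated_k()`). Regressing Krd on measured Scheimpflug K over a
calibration cohort gives a correction formula

    Krd.TCRP = 0.989·K_TCRP + 0.179        (r = 0.873)
    Krd.TRP  = 0.974·K_TRP  + 0.882        (r = 0.898)

(shipped as `krd_paper_regression()`); applying it to a new eye's measured K
before the Haigis formula removes the post-refractive bias. The package also
provides the standard benchmarking layer (numeric/absolute prediction error,
percentage of eyes within ±0.5/±1.0 D, paired t/F/Friedman/Wilcoxon/McNemar
comparisons with Bonferroni control) and a seeded synthetic post-LASIK
cohort generator so the whole chain is testable without patient data.

## Worked example

Calibrate on a synthetic 50-eye cohort (the calibration-group study size),
then check what the correction does at simulation scale:

```r
library(iolpost)
cst <- example_iol_constants()

g1  <- generate_cohort(cohort_spec(n = 50, seed = 42), cst)
fit <- calibrate_from_cohort(g1$cohort, cst, "tcrp4")
fit
#> Krd regression [tcrp4]: Krd = 1.02482 * K -1.29913
#>   Pearson r = 0.8668, n = 50
#>   provenance: fitted by OLS on 50 eyes
```

At n = 50 the fitted line scatters around the generating line
(0.989, +0.179) with OLS standard errors of roughly 0.08 on the slope; the
parameter-recovery tests run the same chain at n = 20,000 where the
uncertainty collapses. Applying the shipped published correction to a large
independent validation cohort shows the bias it removes:

```r
g2 <- generate_cohort(cohort_spec(n = 5000, seed = 7, preset = "group2"), cst)
ps <- cohort_predictions(g2$cohort, cst, "tcrp4")                 # raw K
pk <- cohort_predictions(g2$cohort, cst, "tcrp4",
                         regression = krd_paper_regression("tcrp4"))
rbind(summarize_errors(ps$pe_d, "K"), summarize_errors(pk$pe_d, "Krd"))
#>   method_label    n mean_numeric_pe sd_numeric_pe ...
#> 1            K 5000          0.2126          1.65
#> 2          Krd 5000         -0.0537          1.65
```

Entering the measured K directly leaves a mean hyperopic error of +0.21 D;
the Krd correction centres it (−0.05 D). The spread (SD ≈ 1.65 D) is the
generator's irreducible calibration scatter, so at a clinical 30-eye sample
this bias shift sits inside the noise — which is exactly why the paired
statistical battery (`compare_methods()`) exists.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "iolpost.R", package = "iolpost"))')
Rscript $CLI simulate  --n 50 --seed 42 --out cohort.csv
Rscript $CLI calibrate --cohort cohort.csv --k-source tcrp4 --out reg.json
Rscript $CLI predict   --cohort cohort.csv --krd --out predictions.csv
Rscript $CLI evaluate  --predictions predictions.csv --out summary.csv
```

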