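# nercontrol

Kinetic modelling of nucleotide-excision repair (NER) and the collective
control of its rate.

NER removes bulky UV-induced DNA lesions (6-4 photoproducts) through an
ordered sequence of steps — recognition, unwinding, dual incision, repair
synthesis, re-chromatinization — each catalysed by a multi-protein
complex whose components (XPC, TFIIH, XPG, ERCC1-XPF, XPA, RPA, PCNA)
exchange at damage sites within seconds to minutes. Yet the pathway as a
whole repairs lesions over hours, following slow first-order kinetics
$EdU(t) = EdU_{\max}\,(1 - e^{-\lambda t})$. This package is for
quantitative biologists who want to dissect that paradox: it shows how
slow exponential kinetics emerge from fast, *reversible* complex
assembly, and how, as a consequence, no single factor is rate-limiting —
the repair rate is controlled collectively, with response coefficients
$R_i = \partial \ln v / \partial \ln C_i$ that are uniformly small.

The package implements, as tested and reusable components:

* **Assembly theory** — continuous-time Markov chains for sequential and
  random repair-complex assembly; exact mean first-passage repair times;
  completion curves; mono-exponential diagnostics; matching of
  irreversible to reversible schemes; Gillespie sampling.
* **Pathway model** — a mechanistic ODE model with five DNA intermediates
  and seven reversibly, independently binding repair factors (compiled
  right-hand side); observables for factor accumulation, EdU
  incorporation, FLIP and the incised fraction.
* **Inference** — Gaussian maximum likelihood with multi-start
  optimisation in log space, profile-likelihood confidence intervals and
  identifiability verdicts, prediction profiles, and the standalone
  first-order EdU fit.
* **Control analysis** — response coefficients by central differences,
  finite perturbation scans, and propagation of expression/lesion
  variability to the repair-rate CV:
  $CV_v^2 = \sum_i R_i^2 CV_i^2 + R_L^2 CV_L^2$.
* **Population simulation** — lognormal cell-to-cell variability in
  factor levels and lesion dose, per-cell pathway solves, bootstrap
  correlations, variance decomposition by source, and an error-ellipse
  estimator of two-channel measurement error.
* **Synthetic data** — seed-reproducible generators for every input the
  pipeline consumes (bulk time courses with replicate noise, first-order
  EdU curves, paired two-channel measurements).

See the vignette (`vignettes/ner-kinetics.Rmd`) for the models, parameter
choices and their rationale.

## Worked example

```r
library(nercontrol)

# 1. Hour-scale repair from minute-scale molecular rates: nine components
#    exchanging at ~1/min, catalysis at 10/s
mean_repair_time(assembly_scheme(9, "random", k_on = 1, k_off = 1, rho = 600))
#> [1] 68.3073

# 2. The full pathway model: emergent first-order repair kinetics
p <- ner_parameters()
traj <- ner_simulate(p, seq(0, 240, 10))
edu <- observe(traj, "edu", normalize = TRUE)
fit_first_order(edu$time_min / 60, edu$value)
#> First-order repair fit: lambda = 1.412 h^-1 (95% CI 1.374-1.450)
#>   half-time = 0.49 h, plateau = 1.01, rmse = 0.00974

# 3. Collective rate control: every response coefficient is small
rep30 <- response_coefficients(p, "repair_rate", t_eval = 30)
rep30
#> Response coefficients of the repair rate at t = 30 min:
#>    XPC  TFIIH    XPG    XPF    XPA    RPA   PCNA
#> -0.009  0.288  0.261  0.260  0.262  0.256 -0.005
#>   R_L (lesions) = 0.993; step-halving change 0.0084%

# 4. Propagate natural cell-to-cell variability (expression CV 0.25,
#    lesion-dose CV 0.32) to the repair rate
propagate_cv(rep30, cv_factors = 0.25, cv_lesions = 0.32)
#> Propagated repair-rate CV: 0.351
#>   contributions (variance share):
#>     XPC   TFIIH     XPG     XPF     XPA     RPA    PCNA lesions
#>   0.000   0.042   0.035   0.034   0.035   0.033   0.000   0.821

# 5. Measurement-error estimation from paired two-channel data
pairs <- generate_paired_measurements(332, signal_cv = 0.3,
                                      relative_error = 0.11, seed = 1)
error_ellipse(pairs$channel1, pairs$channel2)$relative_error
#> [1] 11.46284
```

Reading the output: the mono-exponential fit to the simulated repair
curve is near-perfect (RMSE ~1% of the plateau) although the model
contains no slow molecular step — first-order kinetics are emergent. The
response coefficients show distributed control shared by the pre-incision
factors, with the repair rate essentially proportional to the lesion dose
($R_L \approx 1$); propagated to a cell population, the lesion dose
dominates the repair-rate variability. The error-ellipse estimator
recovers the generative 11% per-channel measurement error.

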