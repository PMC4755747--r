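# gengrad

Trial-by-trial modelling of **stimulus generalization** in
intradimensional discrimination learning, with the full statistical
pipeline used to compare generalization breadth between treatment groups:
pooled maximum-likelihood fitting, similarity-kernel comparison,
permutation inference on model parameters, Pearson type VII kurtosis
analysis of gradient shape, and leave-one-out individual-difference
scores. A synthetic-cohort generator reproduces the study design
(discrimination training with probabilistic reward, then a generalization
test in extinction), so the entire pipeline is validated end to end by
parameter recovery without any subject-level data.

## The model

Subjects learn that one Gabor orientation (CS+, 39°) predicts reward while
a neighbour (CS−, 51°) does not, then respond to 15 novel orientations
(17°–73°) in extinction. Each experienced orientation *k* holds excitatory
and inhibitory associations *E<sub>k</sub>*, *I<sub>k</sub>*. The value of
the presented stimulus aggregates all associations, weighted by a
similarity kernel over orientation distance:

&nbsp;&nbsp;*V<sub>t</sub>* = Σ<sub>j</sub> *E<sub>t,j</sub>*·<sup>e</sup>S<sub>j</sub><sup>k</sup> − *I<sub>t,j</sub>*·<sup>i</sup>S<sub>j</sub><sup>k</sup>,
&nbsp;&nbsp;<sup>e</sup>S<sub>j</sub><sup>k</sup> = exp(−(x<sub>j</sub>−x<sub>k</sub>)² / 2s<sub>e</sub>²) (Gaussian; an exponential form is also available)

A prediction error δ<sub>t</sub> = R − V<sub>t</sub> updates only the
presented orientation — excitation when positive, inhibition when negative
— with separate learning rates for training and test (extinction), and
responses follow a biased logistic P(+) = 1/(1+exp(−β(V−a))). The kernel
widths *s<sub>e</sub>*, *s<sub>i</sub>* are the model's measure of
generalization breadth; the analysis asks whether they differ between a
D2R-blockade group (PA) and placebo (PP).

## Worked example

Simulate the default synthetic cohort (25 PA + 21 PP agents generated from
the group parameter sets, full study trial counts) and run the two-stage
fit:

```r
library(gengrad)
coh <- simulate_cohort(cohort_spec(seed = 1))
subjects <- coh$subjects
groups <- vapply(subjects, `[[`, character(1), "group")

cfg <- fit_config(n_starts = 4, seed = 2)
stage1 <- fit_alpha_train(subjects, "gaussian", cfg)    # shared training rate
fit_pa <- fit_group(subjects[groups == "PA"], stage1$alpha_train, "gaussian", cfg)
fit_pa
#> Pooled ML fit (gaussian kernel, 5 free parameters, n = 5250)
#>   LLE = -2634.403   AIC = 5278.8   BIC = 5311.6
#> Model parameters (gaussian kernel)
#>   s_i = 21.9  s_e = 17.86  beta = 7.427  a = 0.2719
#>   alpha_train = 0.02613  alpha_test = 0.001698

peak_shift_statistic(subjects)$statistic
#> [1] 25.79
grad <- behavioral_gradient(subjects)
kurtosis_of_fit(fit_pearson7(grad, "PA")); kurtosis_of_fit(fit_pearson7(grad, "PP"))
#> [1] 4.81
#> [1] 3
```

The recovered excitatory width for the PA group (17.86°) sits close to its
generating value (17.599°), and the PA group's gradient is more peaked
(kurtosis 4.81 vs 3.00) — the narrower-generalization signature the
pipeline is built to detect. The large positive peak-shift t confirms that
responding concentrates on the side of the CS+ away from the CS−. (The
slope β and the training learning rate trade off along a known
identifiability ridge — see the methods vignette — which is why group
inference is based on the width parameters, with the training rate fixed
from the stage-1 fit.)

## Analysis workflow

The `analysis/` scripts run the pipeline stage by stage, writing
tab-separated tables under `results/`:

| script | writes |
|---|---|
| `01_simulate_cohort.R` | per-subject trial TSVs + manifest |
| `02_fit_model.R` | `fit_parameters.tsv` (group-wise estimates) |
| `03_compare_kernels.R` | `kernel_comparison.tsv`, `kernel_slopes.tsv` |
| `04_group_inference.R` | `gradient.tsv`, `loo_scores.tsv`, `inference_summary.json` |
| `05_parameter_recovery.R` | `recovery_estimates.tsv`, `recovery_summary.tsv` |

`run_pipeline()` exposes the same stages programmatically from a single
(YAML-serializable) configuration.

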