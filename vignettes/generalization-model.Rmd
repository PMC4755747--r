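---
title: "Similarity-based stimulus generalization: model, fitting and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based stimulus generalization: model, fitting and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gengrad)
```

## The problem

In intradimensional discrimination learning, a subject learns that one
orientation of a Gabor patch (the CS+, say 39°) predicts reward while a
nearby orientation (the CS−, 51°) does not. When novel orientations are then
probed in extinction, responding traces out a *generalization gradient*: a
bell-shaped curve over orientation whose width measures how far learned
value spreads to similar stimuli, and whose maximum is typically displaced
away from the CS− (the *peak shift*). Pharmacological manipulations — here,
dopamine D2-receptor blockade in one of two groups — can alter the width
and peakedness of this gradient. `gengrad` implements a trial-by-trial
computational model of this process, the machinery to fit it to choice
data, and the group-level inference used to compare fitted parameters and
gradient shape between groups. Because no subject-level behavioural data
are distributed with the package, a synthetic-cohort generator reproduces
the study design end to end, so every stage of the pipeline is validated by
parameter recovery and oracle equivalence rather than by re-analysis of the
original sample.

## The model

Each orientation $k$ that has been experienced holds two association
strengths: excitatory $E_k \ge 0$ and inhibitory $I_k \ge 0$. When
orientation $k$ is presented on trial $t$, its net associative strength
(predicted reward) aggregates all stored associations, weighted by
similarity:

$$V_t = \sum_j E_{t,j}\, {}^eS_j^k - I_{t,j}\, {}^iS_j^k$$

The similarity (generalization) coefficients are Gaussian,

$$ {}^iS_j^k = \exp\!\left(-\frac{(x_j - x_k)^2}{2 s_i^2}\right), \qquad
   {}^eS_j^k = \exp\!\left(-\frac{(x_j - x_k)^2}{2 s_e^2}\right), $$

or exponential,

$$ {}^iS_j^k = \exp\!\left(-\frac{|x_j - x_k|}{2 s_i^2}\right), \qquad
   {}^eS_j^k = \exp\!\left(-\frac{|x_j - x_k|}{2 s_e^2}\right). $$

The exponential form keeps the $2s^2$ denominator of the Gaussian — an
unusual scaling (the distance is not squared, yet the width enters
squared), but it is the model's definition and is implemented exactly as
stated; only the comparison between the two *shapes* is of interest, and
each kernel's width parameter is free, so the scaling convention does not
restrict the family.

The outcome $R \in \{0, 1\}$ generates a prediction error
$\delta_t = R - V_t$, which updates only the presented orientation:

$$E_{t+1,k} = E_{t,k} + \alpha\,\delta_t \;\text{ if } \delta_t > 0,
\qquad I_{t+1,k} = I_{t,k} - \alpha\,\delta_t \;\text{ if } \delta_t < 0.$$

Both strengths are therefore non-decreasing; a zero prediction error
changes nothing. Separate learning rates apply during training
($\alpha_{train}$, with feedback) and during the extinction test
($\alpha_{test}$; all outcomes are 0 there, so $\delta_t = -V_t$ and test
updates implement extinction learning). Responses follow a biased logistic
(softmax) read-out with slope $\beta$ and offset $a$:

$$P(+)_t = \frac{1}{1 + \exp(-\beta\,(V_t - a))}.$$

Free parameters: $s_i, s_e$ (degrees), $\beta$, $a$ (value units),
$\alpha_{train}, \alpha_{test} \in [0,1]$, plus the kernel form.

Associations are stored only at orientations that have been presented;
never-presented orientations provably hold zero associations, so this
sparse bookkeeping is exact. Initial associations are zero — the unique
choice that makes pre-training values vanish. The trial loop is implemented
in C++ (via Rcpp) with numerically stable log-probabilities, so that
pooled-likelihood optimization, permutation refits and recovery studies run
at interactive speed; `run_trials()` exposes it with both a likelihood mode
(score observed responses) and a generative mode (sample responses).
Responses never feed back into learning, so the value trace is identical in
the two modes — a property the test suite asserts, alongside exact
equivalence with an independently coded naive trace.

## Likelihood and the two-stage fit

The model is fit by maximizing the pooled log-likelihood of responses
*during the generalization test*: training trials drive the associative
state (their outcomes are experienced) but their responses are not scored.
Three-way responses (+ / − / unsure) are reduced to "+" versus "not +",
since the model defines only $P(+)$; `unsure_policy = "exclude"` drops
unsure trials from the likelihood instead. Missed trials carry no response
and contribute no likelihood term, but by default still trigger the value
computation and update, because the stimulus and outcome were experienced
(`update_invalid = FALSE` reverses this).

Fitting is two-stage: $\alpha_{train}$ is first estimated with all six
parameters free on the combined sample (both groups are drug-free during
training, so one training rate is shared), then held fixed while the five
remaining parameters are fit per group. Pooling sums each subject's
log-likelihood under one shared parameter set, with every subject's state
initialized fresh and carried from training into test.

The optimizer is bounded multi-start L-BFGS-B: kernel widths and learning
rates are searched on a log10 scale (widths in [1, 100]°, rates in
[10⁻⁴, 1]), slope in [0.1, 20] and offset in [−1, 2] on their natural
scale; starts are drawn log-uniformly/uniformly accordingly (20 by
default), the best objective across starts wins, and ties break to the
first start index. The convergence factor corresponds to an absolute
objective tolerance far below one trial's likelihood resolution. AIC and
BIC use $k$ free parameters and, for $n$, the number of valid trials that
entered the likelihood. Kernel comparison (`compare_kernels()`) fits both
kernel forms to the combined cohort with all six parameters free, compares
AIC/BIC, and additionally regresses each subject's observed test responses
on the modelled $P(+)$ (logistic, with intercept), pairing the slopes
across kernels.

## Gradients, peak shift and kurtosis

The CS+ orientation is counterbalanced across subjects (39° or 51°);
`mirror_normalize()` reflects orientations about the CS+/CS− midpoint where
needed so the CS+ always lies on the low side of one canonical axis, and
`behavioral_gradient()` then aggregates per-subject "+" proportions into
group means. The peak-shift statistic compares, per subject, mean
responding over canonical orientations below the CS+ (the side away from
the CS−) against those above it, with a one-tailed paired t-test — the
hypothesis is directional.

Gradient shape is summarized by the kurtosis of a Pearson type VII curve

$$f(x) = A \left(1 + \left(\tfrac{x - \mu}{\sigma}\right)^2\right)^{-m}$$

fitted to the group-mean gradient by least squares (the gradient is a mean
response curve, not a sample, so density maximum likelihood does not
apply). The direct sample kurtosis of the gradient itself would be biased
by the bounded, off-centre support (17°–73°), which is why the parametric
summary is used. A small deterministic grid of scale/shape starts guards
the Levenberg–Marquardt fit against local minima. The kurtosis
$\mathrm{kurt}(X) = E[(X-\mu)^4]/\sigma_X^4$ of the fitted curve, viewed as
a normalized density, is computed by quadrature; the family is a rescaled
Student-t with $\nu = 2m - 1$ degrees of freedom, giving the closed form
$3(\nu-2)/(\nu-4)$ used as an independent oracle in the tests, the Gaussian
limit 3 as $m \to \infty$, and a finite fourth moment only for $m > 2.5$ —
below that boundary the kurtosis is flagged infinite rather than reported
as a quadrature artefact. Near-Gaussian gradients produce a well-known
ridge in $(\sigma, m)$ (many large-$\sigma$, large-$m$ pairs fit almost
equally well); the kurtosis is insensitive along the ridge's Gaussian end,
which is exactly why it, and not $m$ alone, is the shape summary.

## Permutation inference and leave-one-out scores

Group differences in fitted parameters and in kurtosis are tested by
permutation: subjects are reassigned at random into two groups of the
original sizes and the full estimation pipeline is rerun on each
relabelling (for parameters, both group fits; for kurtosis, the gradient →
Pearson VII → kurtosis chain). $\alpha_{train}$ is not re-estimated inside
permutations — it is fixed before group-wise fitting, mirroring the
two-stage logic; a flag enables refitting. P-values use the
$(\text{count} + 1)/(n_{perm} + 1)$ convention and a *fixed* a-priori
direction (narrower generalization, i.e. negative width differences, and a
positive kurtosis difference), not the observed sign — this keeps the test
valid and its null p-values uniform, which the acceptance suite checks by
meta-simulation. Permutations on which a refit fails (or the kurtosis
difference is undefined because both sides are infinite) are redrawn and
counted.

Individual-difference scores use leave-one-out refits: a subject's score
for a parameter is the full-group estimate minus the estimate with that
subject removed, so a subject carrying a large latent parameter receives a
positive score. (The opposite sign convention is available behind a flag.)
Groups are compared on the scores by one-tailed two-sample t-tests.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` reproduces the study design exactly: 25 + 21 subjects,
100 CS+ and 100 CS− training trials with 50% CS+ reinforcement, 15 test
orientations (17°–73°, 4° steps) × 14 repetitions in extinction,
alternating counterbalance, and behaviour generated by the model itself
with the published group parameter sets (`default_group_params()`):
PA $s_i = 20.121$, $s_e = 17.599$, $\beta = 3.093$, $a = 0.370$,
$\alpha_{test} = 0.002$; PP $s_i = 30.587$, $s_e = 24.584$,
$\beta = 3.124$, $a = 0.361$, $\alpha_{test} = 0.006$.

Reinforcement is an exact count by default — exactly half of the CS+
trials are rewarded, in shuffled positions — because that guarantees the
stated contingency in every cohort and makes fits comparable across seeds;
an i.i.d. Bernoulli mode is available. Pseudorandom order is an
unconstrained seeded shuffle. Per-subject seeds derive deterministically
from the master seed, so cohorts are reproducible and extensible.

The training learning rate is not part of the published group parameter
sets, so the generator needs a default. It is fixed at
$\alpha_{train} = 0.15$, chosen for consistency with the reported
behaviour: acquisition of the discrimination within the first ~50 trials,
and group-mean gradients whose fitted Pearson VII kurtosis is finite with
the PA group clearly more peaked — markedly smaller values push the
simulated gradients' fits below the $m = 2.5$ fourth-moment boundary,
a qualitatively different shape regime than the published gradients.

The generator does **not** emulate reaction times, unsure responses,
attention lapses, perceptual noise, or pharmacokinetics; misses can be
injected (`p_miss`) but default to none. Passing recovery tests therefore
show that the estimation machinery is correct and well-calibrated *under
the model's own assumptions at the study's scale* — they cannot certify
robustness to the ways real subjects deviate from the model.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to exercise each
claim meaningfully: parameter recovery runs 20 replicate cohorts at the
full study design (the median recovered kernel widths must fall within 20%
of the generating values, and the sign of the excitatory-width group
difference must be recovered in ≥90% of replicates); likelihood values are
checked against an independent naive trace on 100 random schedules to
10⁻¹⁰; kernel-comparison self-consistency uses 20 cohorts of 8+8 subjects
per generating kernel; permutation-test calibration runs 200
meta-replicates at 200 permutations each, on 3+3-subject cohorts with
shortened schedules for the parameter test and 8+8-subject cohorts at full
training length for the kurtosis test — scaled-down designs with the
estimation settings reduced in proportion, so the meta-simulation stays a
faithful miniature of the production procedure.

## Known limitations

- $\alpha_{train}$ is identified only through its footprint on the
  associative state at the start of the test (training responses are not
  scored), so its estimate is noisy; the two-stage design exists precisely
  to keep this noise out of the group comparison.
- The Pearson VII scale and shape are jointly weakly identified for
  near-Gaussian gradients (the $(\sigma, m)$ ridge); kurtosis is the
  stable summary, individual $\sigma$ or $m$ values should not be
  over-interpreted.
- Permutation p-values are mildly conservative by construction (the
  $+1/(n_{perm}+1)$ convention).
- With few subjects or few test repetitions, noisy gradients can drive the
  Pearson VII fit into the infinite-kurtosis regime; such results are
  flagged, and the group comparison should then be read as "heavier than
  representable" rather than as a number.
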