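---
title: "Classifying two-class motor-imagery EEG with CSSD and kernel ELMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying two-class motor-imagery EEG with CSSD and kernel ELMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A motor-imagery brain-computer interface (BCI) asks a user to imagine one
of two movements (say, right hand vs right foot) and decodes the imagined
class from multichannel EEG. The physiological signature is event-related
desynchronization (ERD): imagining a movement suppresses the power of the
mu rhythm (8–13 Hz) over the corresponding sensorimotor areas. Because
every session begins with a tedious calibration recording, the practical
question is how little labelled training data still supports accurate
classification.

`cssdelm` implements a four-stage pipeline aimed at exactly that
small-training-sample regime:

1. **Band-pass filtering** of each epoch into 8–31 Hz, where ERD lives.
2. **Channel selection** by a relative-distance score on class-conditional
   mu-band power.
3. **CSSD spatial filtering** (common spatial subspace decomposition):
   whitening plus simultaneous diagonalization of the two class
   covariances, then normalized log-variance features.
4. **Classification** by a kernel extreme learning machine — a closed-form
   kernel ridge-type solve — or by a basic random-hidden-layer ELM.

Everything downstream of the raw epochs is deterministic given a seed, and
a synthetic generator with known ground truth makes each stage testable
without any external recordings.

## The model, stage by stage

### Preprocessing

Each channel of each trial is filtered with a 4th-order Butterworth
band-pass (default 8–31 Hz) applied forward and backward, so the filter is
zero-phase and trial-internal variance timing is untouched. Two numerical
details matter on short epochs:

* the trial is odd-reflected about its end points by one transient length
  per side before filtering, which suppresses boundary ringing;
* each pass starts from the filter's steady state for a constant input at
  the first padded sample. With an 8 Hz low edge at 250 Hz sampling the
  zero-state transient decays over hundreds of samples — longer than the
  padding — and would otherwise leak into the epoch; state initialization
  removes it exactly (a constant trial filters to below 1e-12 of its
  amplitude).

Filtering is per-epoch because the package's data model only contains
epochs; continuous-recording filtering before epoching is out of scope.

### Channel selection

Let $P_{i,k}(f)$ be the PSD of channel $k$ under class $i$, averaged over
that class's trials. The relative distance of channel $k$ over the mu band
$f_T = [8, 13]$ Hz is

$$h(k) = \frac{\left|\sum_{f \in f_T} P_{1,k}(f) - \sum_{f \in f_T} P_{2,k}(f)\right|}
              {\sum_{f \in f_T} P_{1,k}(f) + \sum_{f \in f_T} P_{2,k}(f)},$$

a normalized band-power contrast in $[0,1]$: 0 for identical class
spectra, 1 when one class carries all band power. The absolute value in
the numerator is deliberate — without it the quantity can be negative and
the $[0,1]$ codomain claim fails — and makes the score symmetric under
class exchange. The top `channels_m` channels (default 25) are kept; ties
break toward the lower channel index so selection is deterministic.

PSDs come from a Burg autoregressive model per channel and trial (default
order 16, evaluated on a 0.5 Hz grid), the field's usual choice for short
epochs; a Welch estimator (Hann window, `samples/4` segments, 50%
overlap) is available as a cross-check. Class PSDs average per-trial
spectra rather than concatenating trials, which is robust to inter-trial
phase discontinuities. Channel selection is computed on training trials
only and the selected set is frozen before any test trial is touched —
the package never lets label information leak across the split.

### CSSD

For class covariances the package trace-normalizes per trial,
$R = XX^\top / \mathrm{tr}(XX^\top)$, and averages within class, so
high-amplitude trials cannot dominate. CSSD then:

1. eigendecomposes $R_A + R_B = U \Sigma U^\top$ and forms the whitening
   map $P = \Sigma^{-1/2} U^\top$ (eigenvalues below $10^{-10}$ of the
   largest are dropped, so $P$ acts on the effective-rank subspace);
2. diagonalizes the whitened class-A covariance
   $S_A = P R_A P^\top = U_A \Sigma_A U_A^\top$. Since $S_A + S_B = I$,
   both classes share eigenvectors and $\Sigma_A + \Sigma_B = I$: a
   direction that captures much class-A variance captures little class-B
   variance and vice versa;
3. keeps the $J$ eigenvectors with the largest class-A eigenvalues as
   $W_A$ (and the $J$ largest class-B ones, i.e. the smallest class-A
   ones, as $W_B$) and maps them back: $SF_A = W_A^\top P$,
   $SF_B = W_B^\top P$.

Eigenvector signs are fixed (largest-magnitude entry positive) so results
are identical across linear-algebra backends.

A trial $X$ is featurized through **both** banks,
$v' _j = \log\!\big(\mathrm{var}(v_j) / \sum_{k=1}^{J}\mathrm{var}(v_k)\big)$
within each bank, giving a $2J$-vector whose blocks each satisfy
$\sum_j e^{v'_j} = 1$. Using both banks is forced by the test-time
situation: a bank-per-class rule would need the label it is trying to
predict. Variances are population variances (denominator $n$); any common
scale cancels in the normalization. A zero filtered variance is floored at
`1e-300` before the log, preserving order while avoiding $-\infty$.

**A sharp edge worth knowing.** Normalized log-variance CSSD features are
often described as invariant to invertible spatial mixing of the sensors.
With per-class trace normalization that is exactly true only for mixings
that preserve the class-A/class-B trace ratio — scaled rotations in
particular. A general invertible mixing rescales the two classes'
covariances unequally, which re-normalizes each generalized eigenvector
differently and moves the features at the percent level. The test suite
asserts exact invariance (to 1e-6) under scaled rotations and approximate
invariance under arbitrary invertible mixings.

### Classifiers

Targets use a one-of-two coding: class 1 $\mapsto (+1,-1)$, class 2
$\mapsto (-1,+1)$; predictions decode by argmax with ties going to
class 1.

The **basic ELM** draws hidden-layer weights and biases uniformly on
$[-1,1]$ from a seeded generator, forms the sigmoid hidden-layer output
matrix $H$, and sets the output weights to the minimal-norm least-squares
solution $\beta = H^{\dagger} T$ via an SVD pseudo-inverse. Hidden-node
count defaults to 100; the activation and distribution defaults are the
canonical ELM choices (the underlying theory only requires an infinitely
differentiable activation).

The **kernel ELM** replaces the random hidden layer with a Mercer kernel
and solves

$$\alpha = \left(\tfrac{I}{C} + K\right)^{-1} T, \qquad
  f(x) = k(x, X_{\text{train}})\,\alpha,$$

with regularization factor $C$ (default 10) and an RBF kernel
$k(x,y) = e^{-\gamma\|x-y\|^2}$. This is kernel ridge regression with
ridge $1/C$ on the $\pm 1$ targets; it is solved by Cholesky
factorization of the symmetric positive-definite system, never by an
explicit inverse, and involves no randomness — which is why its accuracy
is exactly reproducible while the basic ELM's varies across seeds. The
RBF width defaults to the median heuristic
$\gamma = 1/(2\,\mathrm{med}^2)$ of pairwise training distances, a
scale-free choice; both $\gamma$ and $C$ are configuration keys.

### The experiment harness

`fit_pipeline()` runs the stages strictly in order on training data and
freezes every fitted object; `predict_pipeline()` only ever applies frozen
state. `sweep_eigenvalues()` varies $J$ on one shared stratified split;
`sweep_train_fraction()` draws stratified splits per seed and refits
everything — including channel selection — inside each training part, so
sweep results reflect honest small-sample behavior. Splits are stratified
by class (balance within one trial) because at 10 trials per class an
unlucky unstratified split would dominate the variance.

## The synthetic generator

`simulate_recording()` emulates the statistical structure the pipeline
exploits, with ground truth attached:

* narrowband Gaussian sources (4 Hz band around 10 Hz) on a configured
  set of active channels — noise, not sinusoids, so AR and Welch
  estimators behave as on real EEG;
* class 2's source power is `erd_ratio` (default 0.4) times class 1's:
  ERD modeled as a whole-trial power reduction, which is the only aspect
  the pipeline's variance-based features can see;
* independent broadband noise (sd 1) on every channel, sources at sd 2 on
  the strongest active channel;
* a full-rank spatial mixing. The default is a *leakage* matrix
  ($I$ plus small seeded off-diagonal coupling): volume conduction smears
  locally but does not delocalize, and sensor-space localization is
  precisely what channel selection exploits. A fully random orthogonal
  mixing (available as `mixing = "orthogonal"`) spreads the contrast over
  all sensors and makes the configured active set unrecoverable by any
  per-channel score — useful as a stress test, wrong as a default;
* a fixed geometric amplitude profile (0.1–1) across the active channels.
  This heterogeneity is physiological — ERD strength varies strongly
  across the scalp — and it is also what gives the normalized
  log-variance features their information: if every active source had
  identical power, a uniform class scaling would cancel inside each
  bank's normalization and leave essentially nothing to classify.

What the generator does **not** model: volume-conduction head geometry,
eye/muscle artifacts, nonstationarity across a session, and the broadband
1/f background of real EEG. Passing tests on this generator therefore
demonstrate the algebra and the statistical mechanics of the pipeline at
realistic SNR, not performance on any particular recording system.

`simulate_null_recording()` forces `erd_ratio = 1`, removing all class
information; the pipeline must then classify at chance, and the test
suite checks that it does (mean accuracy within the 99% binomial band
[0.38, 0.62] at 100 test trials).

## Default parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `band_low_hz`, `band_high_hz` | 8, 31 Hz | ERD-relevant band |
| `filter_order` | 4 | Butterworth order (per pass) |
| `channels_m` | 25 | channels kept after ranking |
| `select_band_hz` | 8–13 Hz | mu band scored by $h(k)$ |
| `ar_order` | 16 | Burg AR order for the ranking PSDs |
| `J` | 10 | spatial filters per class bank (20 features) |
| `C` | 10 | kernel-ELM regularization factor |
| `gamma` | median heuristic | RBF width |
| `n_hidden` | 100 | basic-ELM hidden nodes |

`J = 10` is read as ten filters *per bank*: the two banks and two feature
blocks make $2J = 20$ features per trial, the only label-free way to
featurize an unlabelled trial.

## Problem sizes used in the tests

The shipped test-suite and `scripts/acceptance.R` work at desk scale,
chosen so each experiment still has the statistical resolution its claim
needs: 200 random covariance pairs for the CSSD algebra; 100 random
problems per classifier-oracle comparison; 3 seeds × 50 trials/class for
channel recovery; 10 seeds × (20 training + 260 test trials) for the
small-sample experiment; 5 seeds for the $J$ and training-fraction
trends. The headline small-sample setting deliberately mirrors the
regime of interest: 10 labelled trials per class.

## Known limitations

* Two classes only; no multi-class CSSD or one-vs-rest extension.
* No artifact handling, re-referencing or montage logic; epochs in,
  epochs out.
* MATLAB container reading is not included; recordings arrive through the
  delimited text format or the generator.
* The mixing-invariance of the features is exact only up to the class
  trace-ratio caveat above.
* On genuinely homogeneous ERD (all active sources equally strong) the
  per-bank normalization removes most class information by construction;
  the strongest discriminative signal then lives in the overall band
  power, which the normalized features discard.
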