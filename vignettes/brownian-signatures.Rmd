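---
title: "Brownian signatures of motor control: models, analysis and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian signatures of motor control: models, analysis and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brownmotor)
```

## The scientific question

Human position records in very different motor tasks — turning a crank at a
constant speed, holding the hand still, standing quietly — all show the
signature of a Brownian (Wiener) process at low frequencies: across-trial
position variance that grows linearly with time, and a power spectral density
falling at −20 dB/decade on a log–log Bode magnitude plot (with the power-dB
convention used throughout, $10\log_{10}$ of the PSD, a $1/f^2$ process gives
exactly −20 dB/dec). A Brownian process in position arises naturally if the
nervous system issues motion commands at the *velocity* level and those
commands carry stationary white noise: integrating a noisy velocity command
once yields a random walk in the position reference. `brownmotor` implements
this descriptive architecture, its two rivals, and the analysis pipeline that
discriminates among them, entirely in simulation.

## The closed-loop model

A single-degree-of-freedom plant receives joint torque and returns position:

$$G_{\mathrm{arm}}(s) = \frac{1}{mL^2 s^2 + \beta s}, \qquad
  G_{\mathrm{stance}}(s) = \frac{1}{mL^2 s^2 + \beta s - mgL},$$

a point mass $m$ at lever arm $L$ with viscous damping $\beta$; upright
stance adds the destabilizing gravitational stiffness $mgL$ (inverted
pendulum about the ankle; distributed inertia neglected). The default
parameter sets are the arm ($m = 1.5$ kg, $L = 0.35$ m, $\beta = 30$
N·m·s/rad, $k_c = 65$ N·m/rad) and stance ($m = 75$ kg, $L = 1$ m,
$\beta = 226$ N·m·s/rad, $k_c = 883 > mgL = 735.75$ N·m/rad). Feedback
passes through a pure sensor delay of 100 ms.

Three architectures can generate Brownian position behavior inside such a
loop, and the package simulates all three:

* **model i** — a position servo whose torque disturbance is white noise
  shaped by a first-order *leaky integrator* (unity DC gain, time constant
  $\tau_{\mathrm{leak}}$). Position variance grows approximately linearly for
  $t \ll \tau_{\mathrm{leak}}$ and saturates beyond it, so a single time
  constant cannot simultaneously bound postural variance within seconds and
  keep a 26 s crank record Brownian.
* **model ii** — a loop whose net stiffness is exactly zero (gravitational
  stiffness cancelled for stance, no position feedback for the arm), leaving
  a *free integrator* in the closed loop: white torque noise then integrates
  into Brownian position noise. Velocity is tracked by proportional velocity
  feedback with no integral action, so the tracked speed is
  $k_v/(k_v + \beta)$ of the reference — a steady-state velocity error.
* **model iii** — the descriptive model: the reference position is the
  running integral of a *forward-path velocity command* corrupted by white
  noise $d_\omega$, tracked by a proportional controller $k_c$ with white
  torque noise $d_f$ at the plant input. Postural tasks add an intermittent
  controller in the forward path.

### The intermittent controller

Within the do-nothing region $|x_m| \le x_{th}$ the corrective command is
identically zero. When the (delayed) measurement crosses the threshold, a
Gaussian velocity pulse

$$v(t) = -\operatorname{sgn}(x_m)\, v_{\max}\,
  e^{-(t - t_{\mathrm{trig}} - t_0)^2 / (2c^2)}$$

is added to the velocity command. Two conventions had to be fixed. First, the
sign: the pulse opposes the displacement (pushes the plant back toward the
origin); `peak_velocity` is stored as a magnitude. Second, the timing offset
$t_0$ is set to $4c$ so the pulse ramps up continuously from ≈ 0 at the
trigger instant; a pulse runs to completion ($4c$ past its center) before
the threshold is reassessed, consistent with treating each correction as a
discrete submovement.

## Numerical choices

* **Discretization.** The linear plant is advanced by *exact*
  zero-order-hold discretization (matrix exponential of the augmented system
  per step), so integration error is limited to the piecewise-constant
  approximation of the inputs. The internal step is chosen to resolve the
  fastest closed-loop pole ($\mathrm{d}t \le 0.1/|p_{\max}|$); with the arm
  loop's fast pole at −161 rad/s the default is $\mathrm{d}t = 0.5$ ms.
  Output is decimated to 100 Hz. The feedback delay is an integer-length
  circular sample buffer (200 samples at the default step), zero-filled at
  the start.
* **Noise convention.** All white-noise sources are continuous-time
  intensities: a source of strength $\sigma$ contributes per-step samples
  $N(0, \sigma^2/\mathrm{d}t)$, equivalently random-walk increments of
  variance $\sigma^2\,\mathrm{d}t$. Results are therefore invariant to the
  integration step; this convention is asserted by the step-halving test.
* **Stability guards.** The simulator refuses configurations whose
  closed-loop poles (ignoring the delay) have positive real part — e.g. a
  stance gain $k_c \le mgL$ — and model ii additionally requires
  $k_v < \beta$: with delayed feedback the proportional velocity loop is
  robustly stable only while its loop gain stays below unity at all
  frequencies. A model ii run uses a finer step (0.1 ms) because the
  velocity loop adds a fast pole at $-(\beta + k_v)/mL^2$.

## Calibrated defaults

The plant parameters and feedback gains above are published values; the
noise intensities and intermittent-pulse parameters are not, so they were
calibrated once against the reported low-frequency slopes of the simulated
conditions and then frozen as package defaults:

| condition | $\sigma_\omega$ (rad/√s) | $\sigma_f$ (N·m·√s) | $x_{th}$ (rad) | $v_{\max}$ (rad/s) | $c$ (s) | band (Hz) |
|---|---|---|---|---|---|---|
| crank | 0.01 | 0.25 | — | — | — | 0.01–1 |
| hand posture | 0.01 | 0.25 | 0.05 | 0.1 | 0.1 | 0.01–1 |
| quiet standing | 0.001 | 0.2 | 0.05 | 0.0167 | 0.1 | 0.01–0.1 |

Two effects shape these numbers. The fitted band slope is insensitive to the
absolute noise scale but not to the $d_f/d_\omega$ ratio: the torque-noise
floor flattens the spectrum near the top of the fit band, balancing the
steepening caused by closed-loop roll-off above the tracking bandwidth
(≈ 0.35 Hz for the arm). And the stance loop has closed-loop DC gain
$k_c/(k_c - mgL) = 6.0$ — reference-path signals are amplified six-fold in
position — so the stance velocity noise and pulse amplitude are scaled down
accordingly (one pulse carries about one threshold of position displacement
*after* amplification; the earlier unscaled choice produced a pulse-driven
limit cycle rather than a bounded sway). The quiet-standing threshold,
0.05 rad ≈ 2.9° of ankle sway, is in the physiological range.

Trials last 400 s: the analysis drops the three lowest spectral bins, so a
record of length $T$ retains frequencies from $4/T$ upward, and 400 s puts
that edge exactly at the 0.01 Hz lower edge of the fit bands.

## The analysis pipeline

* **Ensemble variance** is the unbiased across-trial variance at each time
  step, on trials aligned to the origin; a linear OLS fit (with $R^2$
  clamped at zero, so a flat postural curve reports $R^2 = 0$) estimates the
  diffusion rate.
* **Breakpoint detection** fits a continuous ramp-then-plateau model by
  exhaustive search over candidate break times (OLS on the folded regressor
  $\min(t, t_{bp})$), guarded by a BIC comparison against the plain line —
  a pure ramp reports "no plateau" — and by a rule that no break may precede
  the first time variance exceeds 5% of its final level. The detection
  method is the package's own construction; only the break times it should
  recover are externally anchored.
* **Spectra** use Welch's method with the entire trial as a single window —
  i.e. a boxcar periodogram with one-sided density scaling — to reach the
  lowest resolvable frequency; trial averaging replaces segment averaging,
  which is why no taper is needed. Crank records are detrended by removing
  the across-trial mean trajectory (the common ramp); postural records by
  each trial's own mean. The three lowest bins are removed, and the slope is
  the OLS regression of $10\log_{10}$ power on $\log_{10}$ frequency with a
  classical t-interval for its 95% CI. PSDs are averaged in linear power,
  not in dB.

## Reference processes as oracles

`generate_process()` supplies ensembles with known closed forms, which is
how the pipeline is tested without any experimental data: Wiener
($\sigma^2 t$ variance, −20 dB/dec), Ornstein–Uhlenbeck (exact AR(1)
discretization, stationary variance $\sigma^2/2\theta$, Lorentzian spectrum
— flat well below the corner $\theta/2\pi$, −20 dB/dec above it, the
boundedness-induced flattening seen in postural spectra), $n$-fold
integrated noise (−20·n dB/dec; order 2 is the acceleration-command
counterexample), a bounded walk (Wiener increments plus the same
intermittent law acting on the walker — mechanistically aligned with model
iii rather than a reflecting barrier), and a ramp-plus-Wiener crank
surrogate.

```{r example, eval = FALSE}
cond <- crank_condition(n_trials = 200, seed = 1)
ens  <- simulate_ensemble(cond$plant, cond$controller, cond$task)
analyze_ensemble(ens, cond$band, cond$detrend)
#> PSD slope -19.68 dB/dec, 95% CI [-19.75, -19.61], R^2 = 0.995 over 0.01-1 Hz
```

## What the tests do and do not show

The synthetic generators emulate the *stochastic structure* of the
experimental records — unbounded Brownian crank angles, postural walks that
plateau after a breakpoint — under ideal conditions: perfectly aligned
trials, exactly uniform sampling, Gaussian noise, a single mechanical degree
of freedom. Passing tests therefore validate the simulation and analysis
machinery, not claims about real data, which add measurement noise,
two-dimensional coupling, non-stationarity across trials, and subject
variability. Reproducing the *experimental* slope values would require the
public experimental datasets and is deliberately out of scope; the package
reproduces the simulated-model results and the model-exclusion arguments.

Problem sizes throughout (200 trials × 400 s at 100 Hz for the headline
conditions; smaller ensembles for unit tests) keep a full reproduction under
two minutes on a single core.

## Known limitations

* Single degree of freedom only; no $(x, y)$ coupling, muscle dynamics, or
  signal-dependent noise (additive stationary noise is the modelling
  assumption under test).
* The breakpoint estimator assumes one transition from growth to plateau.
* The exclusion demonstrations are qualitative reproductions of the stated
  conclusions (the rival models' exact simulation settings are not
  published): they exhibit the leak-time-constant trade-off, the
  steady-state velocity error, and the −40 dB/dec order-2 signature, not
  specific printed numbers.
* Model i's leaky-integrator and model ii's stiffness cancellation are
  idealized (the cancellation uses the undelayed state, as exact
  plant knowledge is that architecture's premise).
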