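---
title: "Methods: fiber mechanics, cross-bridge kinetics and cardiac analysis in musclemech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fiber mechanics, cross-bridge kinetics and cardiac analysis in musclemech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemech)
```

# Scope and models

musclemech implements the quantitative core of an integrative muscle study:
oscillatory fiber mechanics and the three-process complex-modulus model,
work-loop energetics, saturating and linear dose–response fits, M-mode
cardiac metrics, flight behavior indices, salt-bridge geometry, and the
cohort statistics that tie them together.  A stochastic cross-bridge
ensemble simulator and parametric generators supply every input, so the
pipeline is fully exercisable without recordings.

## Sinusoidal analysis

A skinned fiber oscillated at strain amplitude $\varepsilon_0$ (default
0.00125, i.e. 0.125% of muscle length) and frequency $f$ responds, in the
linear regime, with stress
$\varepsilon_0\,(E'(f)\sin\omega t + E''(f)\cos\omega t)$.
`extract_complex_modulus()` projects stress onto $\{1, \sin\omega t,
\cos\omega t\}$ by least squares over an integer-cycle window and refers
the stress phasor to the strain phasor, which makes the estimate exact for
pure sinusoidal strain, robust to a strain phase offset, and identical to
the DFT-bin estimate on integer-cycle windows (a property the test suite
asserts).  The first two cycles are discarded as transient settling; this
window length is a package choice, exposed as `drop_cycles`, since
published protocols rarely state their rejection window.

Work and power per unit volume follow the sinusoidal-strain identities
$W(f) = -\pi \varepsilon_0^2 E''(f)$ (positive when the viscous modulus is
negative, i.e. the fiber does work on the apparatus) and $P = W f$.  Moduli
are carried in kN/m² and converted to Pa inside the energy formulas, so
$W$ is in J/m³ and $P$ in W/m³.  Source tables in this literature often
print amplitudes without units, so no unit-level agreement with any
specific published table is claimed for $A$, $B$, $C$ or the tensions;
rate-constant ratios and round-trip recovery are the quantitative surface.

`summarize_spectrum()` reports $f_{max}$ (argmax of power) and $f_{Wmax}$
(argmax of work) at a measured grid frequency with no interpolation —
matching the discrete 50-frequency protocol — and flags maxima on the
boundary of the measured range.  A dense-grid oracle is used only in
tests.  The 500 Hz stiffness is read at the measured frequency nearest
500 Hz and must lie within 10% of it.

## The three-process model and its fit

$$Y(f) = A\,(2\pi i f/\alpha)^k \;-\; B\,\frac{if}{b+if} \;+\;
C\,\frac{if}{c+if}$$

The power-law A-process captures passive viscoelasticity; the B-process
(note its sign) produces work, the C-process absorbs it.  The apparent
rate constants are $2\pi b$ and $2\pi c$ (s⁻¹).  Fitting choices:

* $\alpha$ is fixed at 1 Hz and not fitted: with $k$ free, $A$ and
  $\alpha$ are jointly unidentifiable ($A' = A(\alpha/\alpha')^{-k}$ gives
  an identical curve).
* $k$ is bounded to $[0, 0.5]$ and initialized at 0.12, typical of the
  A-process in insect-fiber work; source tables rarely print $k$.
* The default fit range is 5–650 Hz, dropping the lowest frequencies where
  the power law dominates and slow drift corrupts phase in real
  recordings; tests and the acceptance script widen it to the full
  measured range for noiseless round trips.
* Residuals are the unweighted stacked real and imaginary parts; no
  weighting scheme is published for this fit.
* Multi-start: one heuristic start ($b$ from the frequency of the viscous
  minimum, $c = 5b$, $A$ from the high-frequency mean modulus) plus
  `n_starts` log-uniform random starts, all polished with bounded
  Levenberg–Marquardt (`minpack.lm::nls.lm`).  The lowest-SSE converged
  solution wins; solutions with $b \le c$ are preferred (the fiber
  convention that the work-producing process is the slower one), with
  near-ties (relative SSE difference $< 10^{-9}$) broken toward the
  smallest $c$ for determinism.  `enforce_order = FALSE` disables the
  ordering preference for systems (such as the two-state ensemble below)
  whose work-producing mode is the faster one.
* Amplitudes collapsing to the lower bound set the `unidentifiable` flag
  rather than failing, covering degenerate (flat) spectra.

A Monte-Carlo calibration of this estimator at 2% multiplicative spectrum
noise on 50 frequencies puts the sampling standard deviation of the
recovered $2\pi b$ near 2.5% and of $2\pi c$ near 4.5%; the stochastic
recovery test therefore uses a 10% bound met in at least 18 of 20 seeded
runs.  Noiseless round trips recover all six parameters to well under 1%.

## Work loops

`integrate_loop()` delimits cycles by strain zero-crossings with positive
slope, converts to absolute length (m) and force (N), and integrates
trapezoidally: work generated over shortening samples ($dL < 0$), work
absorbed over lengthening samples ($dL > 0$), samples with $dL = 0$
counting toward neither.  Net work equals the signed loop area
($-\oint F\,dL$), counter-clockwise positive, and is normalized by fiber
volume; power is net work times frequency.  The generated/absorbed split
is by shortening/lengthening phase rather than by instantaneous power
sign; the two coincide for the phase relationships of these loops.  Loop
closure is required in both strain and stress to 1% of each channel's
excursion plus one sample's local slope (crossings are only located to
sample resolution).  The measurement cycle defaults to 8 — loop shape
stabilizes after the first half-dozen cycles and published protocols use
cycle 7 or 8; the choice is exposed as `cycle`.  The muscle-length routine
applies the bench rule directly: stretch by 2% ML until the power gain is
at most 3%, the boundary counting as a stop.

## Dose–response fits

`fit_mm()` is bounded nonlinear least squares of $y = v_{max} x/(K_m+x)$
(via `minpack.lm::nlsLM`), initialized at $v_{max,0} = \max y$ and
$K_{m,0}$ = the first concentration reaching half of it, with basal
subtraction applied before fitting when a basal rate is given.  $K_m$
running into its bounds flags non-saturating data.  Catalytic efficiency
is the ratio $v_{max}/K_m$ of the fit at hand; note that a mean of
per-preparation ratios (as cohort tables often report) is not the ratio of
pooled estimates, so both styles are supported by fitting per replicate
and averaging, and reports should label which is shown.  `fit_fmax_vs_pi()`
is ordinary least squares with a two-sided t-test on the slope,
distinguishing fibers whose optimal frequency declines with phosphate from
control-like flat responses.

## The cross-bridge ensemble simulator

The generator of mechanical traces is a two-state (detached/attached)
ensemble of `n_bridges` independent bridges: attachment at constant rate
$f_{att}$ with attachment strain drawn uniformly on $[-d/2, d/2]$ (no
attachment-strain distribution is published for this preparation; uniform
over the stroke is the least-informative symmetric choice), detachment at
rate $g_{det0} e^{|x|/\delta}$, optionally scaled by
$1/(1 + K_m^{ATP}/[\mathrm{ATP}])$, and per-bridge force
$\kappa(x + d)$.  Imposed strain advects attached-bridge strains through
the half-sarcomere length (default 1700 nm, the *Drosophila* IFM scale).
Updates are fixed-step tau-leap Bernoulli draws at
$\Delta t = 0.02/r_{max}$, where $r_{max}$ bounds the largest reachable
rate — orders of magnitude faster than exact event-driven simulation and
accurate for the frequency-response properties of interest; a user step
exceeding $0.1/r_{max}$ is rejected.  The inner loop is compiled (Rcpp)
and draws from R's RNG, so runs are bit-reproducible under a protocol
seed.

Two consequences of this model shape the tests:

* **Linear response.**  With strain-independent rates, length drive does
  not modulate occupancy; only the attached-strain pool responds, relaxing
  at the detachment rate.  The small-amplitude modulus is a single
  work-absorbing high-pass Lorentzian with corner $g_{det0}$ — not
  $f_{att} + g_{det0}$, which is the occupancy relaxation rate of the
  unforced chain.  The suite asserts that the fitted $2\pi c$ approximates
  $g_{det0}$ within 15% and rises monotonically with it, consistent with
  the field's reading of $2\pi c$ as detachment-dominated.
* **Work production.**  A detachment rate symmetric in $|x|$, combined
  with the symmetric attachment distribution, has no first-order coupling
  between length and occupancy and therefore can never produce net
  oscillatory work.  The simulator consequently also offers
  `strain_sign = "signed"` ($g = g_{det0} e^{x/\delta}$), the classic
  insect-fiber kinetics in which stretch-accelerated detachment modulates
  occupancy at first order; that mode carries a work-producing process
  whose fitted $2\pi b$ rises with $f_{att}$ (asserted over a 3-point
  ladder, median of 5 seeded replicates).  The default remains
  `"absolute"`.

Default study conditions used across tests: $\kappa = 2$ pN/nm, $d = 8$ nm
(single-molecule myosin scale), ensembles of 1000–2000 bridges (Monte-Carlo
standard errors of a few percent on moduli after averaging 2–3 runs of
8 cycles), rates of hundreds per second (insect-fiber range), cross-section
$10^6$ nm² per half-sarcomere.  Ensemble spectra in the suite use 8–10
log-spaced frequencies spanning the corner; these sizes keep the full suite
in tens of seconds to a few minutes on one core while leaving the
Monte-Carlo error well below the asserted tolerances.

## Cardiac analysis

Diameter traces are assumed already edge-extracted (µm versus seconds, of
order 120 samples/s).  Beats are contiguous runs below a prominence
threshold (25% of the 5th-to-95th percentile range below the diastolic
level), one beat per run, edge-touching runs discarded.  Per beat: the
systolic diameter is the trough minimum; the diastolic diameter is the
median (noise-spike resistant) of the pre-trough plateau — samples above
85% of the excursion; the systolic interval is the contiguous time below
the systolic minimum plus 15% of the excursion; the heart period is the
trough-to-trough interval.  The 15% threshold is a configurable constant:
the semi-automatic tracing programs used in this literature do not publish
their internal definition, so no absolute agreement on SI with any
published cohort is claimed — the quantitative surface is recovery of the
generator's ground truth (diameters within 2%, intervals within one sample
period plus 5% at 2% noise) and within-study contrasts.  Fractional
shortening and SI/HP are computed from mean diameters and intervals by
default (`fs_mode = "per_beat"` averages per-beat ratios instead); which
convention the source literature used is unstated, so both are provided.
The synthetic generator emulates square-pulse excursions with raised-cosine
edges (10% of SI), with the edges offset so the sub-threshold time equals
the nominal SI exactly in the continuous trace; kymograms of real hearts
are smoother and noisier than this, so passing recovery tests demonstrate
correctness of the measurement logic, not performance on degraded video.

The relaxation assay takes per-heart diameters at baseline, after
extra-/intracellular calcium chelation, and after blebbistatin: step deltas
are tested within genotype by paired t-tests and between genotypes by
unpaired two-tailed Student t-tests, with zero-variance inputs flagged
rather than crashed.

## Behavior

The flight index is the weighted outcome mean $(6U + 4H + 2D)/T$, spanning
0–6.  Wingbeat frequency is the dominant periodogram peak inside an
80–300 Hz physiological band (covering the 140–200 Hz range of interest at
both assay temperatures), with parabolic interpolation on log power for
sub-bin resolution.  Detection uses a Bartlett average of 8 segment
periodograms: single-periodogram bins are exponentially distributed and
their in-band maximum routinely exceeds five times the median on pure
noise, while the averaged spectrum makes the 5x-median criterion a
reliable no-tone rejector.  Group flight indices are compared by Student's
t-test to mirror, not improve, the field's reporting convention despite
the bounded scale.

## Structure contacts

PDB input is parsed by `bio3d`.  The distance between two residues is the
minimum over their charged side-chain atoms (Lys NZ; Arg NE/NH1/NH2; Glu
OE1/OE2; Asp OD1/OD2); whether published contact distances are heavy-atom
minima or named-atom distances is generally unstated, and the minimum over
charged atoms is assumed and documented.  Formally uncharged residues fall
back to polar side-chain N/O with bridging forced false.  A salt bridge
requires opposite formal charges and distance at or below the 4.0 Å
cutoff — chosen so that ~3 Å contacts classify as bridges and ≥4.5 Å
separations do not, and configurable.  Homology models are not rebuilt;
distances printed for specific published models anchor semantics and are
exercised on constructed synthetic coordinates only.

## Statistics and reporting

Group comparisons use the classic equal-variance Student t-test (matching
the literature's "Student's t-test", not Welch), paired t-tests for
within-heart steps, and one-/two-way ANOVA with Bonferroni-adjusted
($p \cdot m$ capped at 1) pairwise contrasts against the reference group;
the two-way design is between-subjects (whether published designs treated
age as repeated measures is unstated).  Stars follow the convention
\*$p<0.05$, \*\*$p<0.01$, \*\*\*$p<0.001$ applied to adjusted p-values.
Percent changes are reported as $100(x_{test}-x_{ref})/x_{ref}$ rounded
half away from zero.  `build_report()` assembles named module outputs with
per-section provenance into deterministic JSON (fixed key order and digit
handling), so identical inputs yield byte-identical reports.

# Noise model and what the synthetic data do not show

All generators add independent Gaussian noise (none of the emulated
instruments has a published noise characterization); fiber noise defaults
are configuration values, not inferences.  The generators reproduce the
statistical structure the analysis assumes — linear viscoelastic
responses, saturating kinetics, square-pulse-like beats, multinomial
outcomes — but not instrument drift, baseline wander, video tracking
artifacts, filament compliance, sarcomere inhomogeneity, or thin-filament
regulation.  Passing round-trip tests therefore validates the estimators
against their own forward models, not against every failure mode of bench
data.

# Known limitations

* The two-state ensemble cannot reproduce a genuine stretch-activation
  delayed force rise; its work-producing mode under signed detachment is a
  minimal surrogate, and quantitative identification of $2\pi b$ with
  $f_{att}$ is monotone, not calibrated.
* No spatially explicit sarcomere lattice, thin-filament regulation, or
  super-relaxed-state kinetics.
* No series-compliance or temperature corrections in the fiber analysis;
  no step-response (tension-transient) protocols.
* Cardiac analysis starts from extracted diameter traces; video processing
  and arrhythmicity metrics are out of scope.
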