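---
title: "Model and methods: nucleotide-dependent microtubule end growth by kinetic Monte Carlo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: nucleotide-dependent microtubule end growth by kinetic Monte Carlo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtkmc)
```

## The scientific question

GTP-tubulin polymerizes at microtubule ends far more readily than
GDP-tubulin, but *where* the bound nucleotide acts has two competing
answers. In the **self-acting (cis)** picture, the nucleotide bound to a
tubulin dimer sets how tightly *that* dimer holds onto the lattice. In the
**interface-acting (trans)** picture, the nucleotide buried at the
dimer–dimer interface sets the strength of *that* interface. The two
pictures are indistinguishable at the minus-end, where the terminal dimer's
exchangeable (E-site) nucleotide is itself the interfacial nucleotide, but
they diverge at the plus-end, where the terminal dimer exposes one
nucleotide to solvent while a second, buried one sits at its bond with the
lattice. Growing both ends in mixtures of GMPCPP (a slowly-hydrolyzable
GTP analog) and GDP therefore discriminates the mechanisms: under
trans-acting rules a GDP-tubulin that lands on a GMPCPP interface binds
tightly, lingers, and *poisons* its protofilament, suppressing plus-end
growth super-stoichiometrically, while minus-end growth falls only in
proportion to the loss of GMPCPP-tubulin.

This package implements the full simulation and analysis chain for that
comparison: a stochastic lattice model of single-end elongation, the
mixed-nucleotide solution chemistry, growth-rate observables and fits, the
fluorescence binding assays used to pin the nucleotide affinity ratio, and
simulation-based calibration of the kinetic parameters.

## The lattice model

A growing end is 13 protofilaments of αβ-dimers, each a gap-free column
above an immutable all-GMPCPP seed (default 10 layers). Subunits associate
only onto protofilament tips and dissociate only from them; the lattice
never holds internal vacancies, protofilament number never changes, and —
deliberately — there is no GTP hydrolysis and no explicit tubulin
conformation state. In GMPCPP/GDP mixtures the lattice body is essentially
all GMPCPP, which is precisely the regime where those omissions matter
least.

**Lateral registry.** The twelve ordinary B-lattice interfaces are flush in
integer-layer coordinates: a subunit at layer $L$ forms one lateral bond
with a neighbour column iff that column occupies layer $L$. The seam is
staggered by half a dimer (`seam_offset = 0.5` layers): a seam subunit
spans two partner layers, and each partial overlap contributes that
fraction of a lateral bond, with bond free energies adding. A site with
total lateral bond weight $w$ has dissociation constant

$$K_D(w) = K_{D,\mathrm{long}}\,\left(\frac{K_{D,\mathrm{corner}}}{K_{D,\mathrm{long}}}\right)^{w}.$$

Integer weights recover the conventional taxonomy — *longitudinal-only*
($w=0$), *corner* ($w=1$, one longitudinal + one lateral contact), and
*bucket* ($w=2$, one longitudinal + two laterals) — and the bucket affinity
$K_{D,\mathrm{corner}}^2/K_{D,\mathrm{long}}$ is the energy-additivity
extension of the two tabulated affinities. The minus-end mirrors the sign
of the seam stagger, reflecting the opposite orientation of seam contacts
at the two ends.

Why the fractional seam? The registry is the one genuinely open geometric
choice in this model family, and it controls how new layers nucleate. We
examined the integer alternatives: a flush ring and a strict one-layer seam
pairing both under-produce growth at the reference parameter set (about
1.4–1.5 nm/s at 1.25 µM where the fitted parameters should give
2.2 nm/s), because every new layer must be pioneered by a bare
longitudinal-only landing that survives ~16 ms. Seam rules that grant a
full extra bond on a blunt face over-produce growth instead (3.7–4.9 nm/s)
by letting the two seam protofilaments ratchet each other upward on
near-irreversible corner sites. The half-dimer stagger — which is also the
physically standard picture of the seam as an A-lattice-like contact offset
by one monomer — yields moderately stabilized half-corner sites
($K_D = K_{D,\mathrm{long}} \sqrt{K_{D,\mathrm{corner}}/K_{D,\mathrm{long}}}$,
about 1.5 µM at the reference affinities) that nucleate layers at the rate
required to reproduce the reference growth behaviour with no parameter
adjustment. `seam_offset` remains configurable (0, 0.5, 1, ... layers) for
sensitivity analyses.

## Kinetic rules

* **Association.** First-order landing onto each protofilament tip at
  `kon * [tubulin]`, with the same on-rate constant for GDP- and
  GMPCPP-tubulin; the landing subunit's nucleotide is drawn from the
  solution's GDP-tubulin fraction at firing time. Defaults: `kon_plus`
  0.74, `kon_minus` 0.31 µM⁻¹s⁻¹ per protofilament.
* **Dissociation.** `koff = kon * KD(site)`, where the site KD comes from
  the lateral bond weight above and from the *governing nucleotide*: the
  interfacial nucleotide under trans rules, the tip's own under cis rules
  (identical at the minus-end by construction). A GDP-governed site is
  weakened `gdp_factor`-fold (default 3500; 3000 for the exploratory
  parameter set). The weakening acts on the longitudinal interface, so the
  corner/longitudinal ratio is nucleotide-independent — with the defaults,
  $K_{D,\mathrm{long}}^{GDP} = 3.01\times10^5$ µM and
  $K_{D,\mathrm{corner}}^{GDP} = 87.5$ µM (tabulations that print 87 µM and
  a minus-end corner off-rate of 27.3 s⁻¹ carry an affinity rounded to
  ~88 µM; this package computes consistently from the weakening factor).
* **Nucleotide exchange.** Only the plus-end tip's E-site is solvent
  exposed. Its nucleotide leaves at `k_exch_gdp` (s⁻¹) when GDP and
  `affinity_ratio * k_exch_gdp` when GMPCPP — dissociation of the bound
  nucleotide is rate-limiting, and the 12.5-fold weaker-bound analog leaves
  proportionally faster. The replacement is drawn from the fractional
  nucleotide concentrations. Exchange applies to every terminal plus-end
  subunit (the most permissive reading; sites buried under further growth
  are frozen). Default `k_exch_gdp = 0` (disabled) except where scanned.
* **Solution.** An infinite reservoir: µM tubulin and 1 mM total nucleotide
  against a single microtubule make depletion negligible. The GDP-tubulin
  fraction follows the competitive binding model below; conditions can be
  stated either as nucleotide mixtures or directly as GDP-tubulin
  fractions.

## The stochastic engine

Events are simulated exactly with the Gillespie direct method: per
protofilament one association channel, one tip-dissociation channel, and
(plus-end, when enabled) two exchange channels; waiting times are
exponential in the total rate and channels fire with probability
proportional to their rates, one reaction per step. The production engine
is compiled (Rcpp) and re-derives all ≤ 52 channel rates from the lattice
each step — at 13 protofilaments a full re-enumeration is cheaper than
incremental bookkeeping and removes a class of update bugs. A pure-R
reference engine (`enumerate_events()` + `gillespie_step()`) consumes the
R RNG stream identically; under the same seed the two produce
bitwise-identical trajectories, which the test suite asserts, and a
two-protofilament configuration is further checked against a brute-force
master-equation (matrix-exponential) solution.

Ensembles derive one sub-seed per replicate from the master seed, so
results are reproducible and independent of execution order. Trajectories
record mean protofilament length — total subunits above the seed times
8/13 nm — every `record_interval` (default 1 s, matching 1 frame/s
imaging).

## Observables and fits

Growth rates are ordinary least-squares slopes of mean length versus time,
computed per trajectory and then averaged (ensemble error bars are the SD
across replicates, n = 50 by default). The fit window starts at 30 s: a
blunt initial lattice briefly over-supplies lateral contacts, and the
measured rate is stationary after a few seconds, so the 30 s guard removes
the transient at negligible cost in precision. Concentration series are
fitted by weighted linear least squares (weights 1/SEM², i.e. minimizing
$\sum ((y-\hat y)/\mathrm{SEM})^2$); the apparent on-rate constant is
reported both in nm s⁻¹ µM⁻¹ and dimers s⁻¹ µM⁻¹ per microtubule
(divide by 8/13 nm), and the apparent critical concentration is the
x-intercept. Mixed-nucleotide series are normalized to the all-GMPCPP
reference condition; the stoichiometric-dilution line
$(C(1-f)-C_c)/(C-C_c)$ is the no-poisoning expectation against which
super-stoichiometric suppression is judged.

The closed-form layer implements the competitive nucleotide binding model
(GMPCPP-tubulin fraction $[CPP]/([CPP]+[GDP]\cdot K_{D,CPP}/K_{D,GDP})$ in
the simplified high-[GMPCPP] limit, with the exact two-KD form available),
the affine minus-end growth law (default coefficients 0.9 nm s⁻¹ µM⁻¹ and
−0.05 nm/s, stored as data and replaceable by a fresh concentration fit),
the tryptophan-quenching isotherm $y = B - A L/(L+K_D)$, the competition
(unquenching) model with the amplitude externally constrained, and the
relative-error SEM propagation for the inner-filter-corrected ratio. All
nonlinear fits are SEM-weighted Levenberg–Marquardt (`minpack.lm`), with
intervals from the parameter covariance at the optimum; predictions of the
affine growth law are kept signed for fitting and only clamped at zero for
display.

## Calibration

`fit_kon_minus()` recovers the minus-end on-rate constant by minimizing the
SEM-weighted squared distance between simulated ensemble means (50 × 300 s
per condition, the calibration protocol) and a target series, using Brent's
method on a bounded interval. Candidate evaluations share replicate seeds
(common random numbers), which makes the stochastic loss a deterministic,
nearly-smooth function of the parameter — without CRN the optimizer chases
noise. `exchange_scan()` maps growth over a grid of exchange rates and
GDP-tubulin fractions (again with CRN across the grid) and
`best_exchange_rate()` picks the grid point closest to a target suppression
curve in SEM-weighted distance. The recovery tests simulate a target at a
known truth and require the fit to return it: kon⁻ to ±0.03 µM⁻¹s⁻¹, the
exchange rate to the exact grid point.

## Synthetic data

`generate_growth_dataset()` and `generate_binding_dataset()` emulate the
tabular datasets the fitting layer consumes: per condition the generating
model (growth law or simulator ensemble; isotherm or competition model)
supplies the true mean, and the reported value is drawn with Gaussian noise
of stated coefficient of variation, `sem = cv·|µ|/√n`. A 5% CV at n ≈ 50
per condition reproduces the precision of the experimental growth-rate
tables (tens of measured microtubules per condition, SEM a few percent of
the mean). Every file embeds its truth parameters, seed and generator
version in a `#` metadata header, so any fit can be re-verified against its
generating truth with no other inputs. What the generators do *not*
emulate: outliers, drift, condition-correlated errors, or day effects —
passing recovery tests demonstrates estimator correctness, not robustness
to structured experimental error.

## Numerical choices and scale

* Simulated study conditions are the production protocol throughout:
  50 replicates × 600 s per condition (300 s inside calibration loops);
  concentration series use five points spanning 0.25–1.5 µM; the
  mixed-nucleotide comparison uses 1 µM tubulin with 0–20% GDP-tubulin in
  5% steps for the exploratory parameter set and 1.25 µM with up to 50%
  for the fitted set.
* Exchange–replacement probabilities, landing-nucleotide draws and channel
  selection consume the RNG in a fixed documented order; the engine is
  deterministic given the seed.
* Degenerate inputs: a total event rate of zero (no tubulin, bare seed)
  freezes the trajectory, which then flat-lines to its duration; seed
  subunits are never scheduled for dissociation or exchange; a
  single-protofilament lattice has no lateral partners and reduces to the
  reversible linear aggregate, whose closed-form growth rate
  `kon([tub] − KD_long)` anchors the engine tests.

## Known limitations

* The discrete half-layer seam is a coarse stand-in for the true helical
  rise distributed over all thirteen interfaces; seam-local quantities
  (which seam protofilament leads, the exact blunt-face site census) are
  convention-dependent even though ensemble growth is not.
* Simulated concentration series are convex at the lowest concentrations —
  sustained growth needs layer nucleation, which fails faster than
  linearly as concentration drops, and the seed acts as a reflecting
  boundary. A linear fit over 0.25–1.5 µM therefore places the apparent
  critical concentration near 0.2 µM, several-fold above the
  corner-affinity scale (~25–50 nM) that experimental growth curves
  report; the slope (apparent on-rate constant) is insensitive to this.
* No catastrophe/rescue statistics, lattice defects, protofilament-number
  changes, mechanical force, or hydrolysis; conclusions are restricted to
  steady elongation in hydrolysis-free (GMPCPP) conditions.

## Reproducing the study conditions

```{r example}
params <- kinetic_params()          # fitted GMPCPP set, interface-acting
mix <- mixture_series(params, "plus", 1.25, seq(0, 0.5, 0.05),
                      n_replicates = 50, duration = 600, rng_seed = 1)
normalized_mixture_curve(mix)

scan <- exchange_scan(c(0.1, 0.2, 0.4, 0.8), seq(0.1, 0.5, 0.1), params,
                      tubulin_total = 1.25, rng_seed = 1)
```
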