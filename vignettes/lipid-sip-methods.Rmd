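---
title: "Methods: inferring carbon assimilation and lipid turnover from 13C-SIP incubations"
author: "lipidsip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring carbon assimilation and lipid turnover from 13C-SIP incubations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidsip)
```

## The scientific problem

Consortia of anaerobic methanotrophic archaea (ANME) and sulphate-reducing
bacteria (SRB) oxidise methane in marine sediments:

$$\mathrm{CH_4 + SO_4^{2-} \rightarrow HCO_3^- + HS^- + H_2O}.$$

Whether these organisms build their lipid biomass from methane carbon or
from dissolved inorganic carbon (DIC) can be resolved by stable isotope
probing (SIP): sediment slurries are incubated with a ^13^C-labelled
substrate (either DI^13^C or ^13^CH~4~), and the label's appearance in
compound-specific lipid δ^13^C values is converted into assimilation rates
and turnover times. `lipidsip` implements the full inference chain from
the raw measurement tables to those rates, plus a forward simulator of the
whole incubation so that every estimator can be validated against known
truth.

## Isotope arithmetic

All mass balance is done in ^13^C **atom fraction**,
$F = {}^{13}C/({}^{13}C + {}^{12}C)$, the linear mixing variable.
Measurements arrive in delta notation relative to VPDB,

$$\delta^{13}C = \left(\frac{({}^{13}C/{}^{12}C)_{sample}}
  {({}^{13}C/{}^{12}C)_{VPDB}} - 1\right) \times 1000\ [\unicode{x2030}],$$

and are converted with $R = (\delta/1000 + 1)\, r_{VPDB}$, $F = R/(1+R)$.
Deltas are stored as measured; fractions are computed on demand, never
cached, to avoid stale double conversions. The reference ratio defaults to
$r_{VPDB} = 0.011180$ and is configurable everywhere because community
values differ in the fifth decimal. Because every estimator below is a
ratio of atom-fraction differences, the choice cancels almost completely
(the tests assert a sensitivity below 0.5 % on the worked examples).

## Derivatization correction

Fatty acids are measured as methyl esters (one added carbon) and alcohols
as TMS ethers (three added carbons per hydroxyl). The analyte composition
is recovered by atom mass balance over the $n$ analyte and $k$ added
carbons:

$$\delta_{analyte} = \frac{(n+k)\,\delta_{meas} - k\,\delta_{added}}{n}.$$

The per-mil form is the field's standard shortcut; exact balance is linear
in $F$, not in $\delta$. For a typical FAME correction the two agree to
better than 0.05 ‰ across the natural-abundance range (|δ| ≲ 200 ‰) but
drift apart by ~1.7 ‰ at +1500 ‰, so above 1500 ‰ the package switches to
the exact atom-fraction mode automatically (`mode = "auto"`). No default
is provided for $\delta_{added}$: it must come from a calibration of the
derivatizing-agent batch, and inventing one would silently bias results.

## Bulk geochemical rates

Concentration changes (mM) become rates per gram sediment dry weight via

$$rate = \frac{\Delta conc \times V_{medium} \times 1000}{m_{dw}\,\Delta t}
\quad [\mu mol\ g_{dw}^{-1}\,d^{-1}],$$

with $V_{medium}$ in litres. Multiplying (not dividing) by $V_{medium}$ is
forced by unit analysis — mM becomes µmol only through the volume — and by
the magnitudes any such incubation reports. Consumption is negative;
windows are anchored at day 0 by default, matching cumulative reporting.

The methane-oxidation rate is inferred from label transfer into DIC:

$$r_{ox} = \frac{\Delta F^{13}C_{DIC} \times conc_{DIC}}
  {excess\,F^{13}C_{CH_4} \times \Delta t}.$$

Two conventions for the excess term exist. The default subtracts the day-0
DIC background, $excess = F_{CH_4} - F_{DIC}(0)$, because that makes the
estimator *exact* for a closed DIC pool fed only by CH~4~-derived carbon
at constant $F$ (a telescoping identity the test suite verifies against
the forward simulator to 10^-9^; the proof is three lines of mass
balance). The literal reading — the absolute initial $F_{CH_4}$ — is
available behind `excess_mode = "absolute"`. Similarly, $conc_{DIC}$ is
taken at the window end by default (the exactness choice), with a
window-mean alternative behind `conc_mode = "mean"`.

## Assimilation rates and turnover times

For each lipid, treatment and sampling day $t$:

$$assim = \frac{conc_{lipid,C} \times \Delta F^{13}C_{lipid}}
  {F^{13}C_{medium} \times t}, \qquad
  turnover = \frac{F^{13}C_{medium} \times t}{\Delta F^{13}C_{lipid}},$$

with the exact identity $assim \times turnover = conc_{lipid,C}$ (asserted
to 10^-9^ relative). Conventions, each of which is a flag:

* **ΔF baseline** — the time-matched non-labelled parallel treatment;
  fallback, with a warning, to the species' day-0 value.
* **Lipid concentration** — the mean over the treatment's sampled
  timepoints (lipid stocks change little over a 30-day incubation);
  a single value is used when only one exists.
* **Carbon mass** — concentrations are converted from µg lipid to µg C
  with the *underivatized* molecular formula (assimilation describes the
  biological molecule, not the FAME/TMS derivative); `conc_basis =
  "lipid"` skips the conversion.
* **Medium atom fraction** — for DI^13^C designs, the sampling day's
  measured δ^13^C~DIC~ (the pool is nearly constant); for ^13^CH~4~
  designs, where δ^13^C~DIC~ rises steeply, the arithmetic mean of all
  measurements from day 0 through the sampling day (`averaging = "all"`;
  the endpoint-pair mean is behind `averaging = "endpoints"`). These
  defaults reproduce the published worked values.
* **Year** — exactly 365 days.
* **assim~CH4~** — the same estimator with $F^{13}C_{medium}$ taken from
  the labelled CH~4~ pool is reported for ^13^CH~4~ treatments and is
  flagged *hypothetical* throughout: for autotrophic partners it has no
  direct biological meaning and mostly traces methane-derived DIC.

### Known bias of the linear estimator

The denominator uses the **absolute** medium atom fraction, which is the
convention the published worked values require. Writing the lipid's
labelling dynamics as $\dot F_{lip} = (a/C)(F_{med} - F_{lip})$, the
short-time estimate is

$$\hat a = a\,\frac{F_{med} - F_{nat}}{F_{med}}
  \left(1 - \tfrac{t}{2\,T} + \dots\right),$$

i.e. it reads low by (i) the natural ^13^C background relative to the
medium, $F_{nat}/F_{med}$, and (ii) a self-relabelling term that grows
with the ratio of the window to the turnover time $T$. At a 5–10 %
labelling strength ($F_{med} \approx 0.06$–0.11) term (i) alone is
10–18 %; at an essentially pure label ($F_{med} \approx 0.98$) both terms
are ~1 % each. This is a property of the estimator, not of its
implementation, and it is deliberately documented rather than corrected:
the linear form is what the field reports.

## The forward simulator

`simulate_incubation()` advances per-pool ^12^C/^13^C inventories (µmol of
carbon atoms) with explicit daily Euler steps:

* AOM moves carbon CH~4~ → DIC at the CH~4~ pool's current $F$, consuming
  sulphate and producing sulphide 1:1;
* a configurable fraction of the forward flux returns DIC → CH~4~ at
  DIC's current $F$ (enzymatic reversibility), which is what makes
  δ^13^C–CH~4~ rise in DI^13^C treatments;
* organoclastic sulphate reduction (rate in µmol SO~4~ g~dw~^-1^ d^-1^)
  adds 2 mol DIC per mol SO~4~ at the sedimentary organic-matter δ^13^C
  and produces sulphide 1:1;
* carbonate dissolution adds DIC at the carbonate δ^13^C;
* each lipid pool keeps constant concentration, gaining carbon from DIC at
  its true assimilation rate $a_i$ and losing carbon at its own current
  $F$ at the same rate; the loss returns to the DIC pool, so the whole
  system is closed and both isotopes are conserved to 10^-9^ under every
  configuration (a property test).

Sedimentary organic matter and carbonate are represented as large
explicit reservoirs so that conservation holds even with those processes
active. Sulphate exhaustion halts the run with a diagnostic. Daily
explicit stepping (rather than an ODE solver) is adequate because all
fluxes are small relative to the pools at incubation scale; halving the
step changes day-30 outputs by < 0.1 % (asserted). Measurement noise is
applied only at export, under a seed: Gaussian on δ (0.5 ‰, the typical
IRMS precision for non-labelled compounds, plus a relative component for
strongly labelled values) and log-normal multiplicative on concentrations
(5 %).

`make_paperlike_config()` mirrors the motivating experiment: ~30 mM CH~4~
and DIC, 25 mM sulphate, four treatments (unlabelled DIC with CH~4~;
DI^13^C with CH~4~; DIC with ^13^CH~4~; DI^13^C without CH~4~) plus
killed controls, AOM at 4.4 µmol g~dw~^-1^ d^-1^, organoclastic sulphate
reduction at 0.7 and dissolution at 2.0 µmol g~dw~^-1^ d^-1^ (chosen so
sulphide accumulation, excess DIC production and sulphate drawdown sit at
the reported magnitudes; they are tuned, not fitted), a 3 % back-flux,
and a bottle of 0.1 L medium over 3.4 g dry sediment. The nominal
labelling strength is 10 %; the *effective* DIC label fraction defaults
to 5.3 % because the unlabelled CO~2~ delivered with the 90/10 headspace
gas dilutes the DIC spike — this reproduces starting values near +5000 ‰
for DIC and +10,000 ‰ for CH~4~, as observed. Note these two observations
(δ^13^C~DIC~ holding near +5000 ‰ while the DIC pool grows ~25 % from
unlabelled sources) cannot both hold exactly in a closed mass balance;
the simulator conserves mass, so its DI^13^C medium shows a modest label
dilution by day 30.

What the simulator does **not** emulate: gas–liquid exchange kinetics
(CH~4~ is one well-mixed pool), carbonate-system speciation, spatial
structure, population dynamics, and fractionation during derivatization.
Passing recovery tests therefore demonstrate estimator correctness under
well-mixed, closed-system conditions — not robustness to every field
complication.

## The parameter-recovery design

`make_recovery_config()` is a purpose-built validation instrument, not a
re-creation of the incubation: a non-labelled parallel plus a DI^13^C
treatment whose spike is essentially pure ^13^C ($F_{med} \approx 0.98$,
held constant by switching the geochemical processes off), with six lipid
species spanning true assimilation rates of 0.2–15 µg C g~dw~^-1^ yr^-1^
and turnover times of ~2–29 years. Under these conditions both bias terms
derived above stay below ~2 %, so day-10 estimates recover the configured
truth within 2 % noise-free, and the mean over 100 noisy replicates stays
within 5 % — which is exactly what the acceptance tests check. Running
the same recovery at the incubation's own 5–10 % labelling strength shows
the documented 10–18 % label-dilution bias; a property test asserts that
the bias shrinks as the label strengthens.

## Numerical choices and degenerate inputs

* δ ≤ −1000 ‰ and atom fractions outside (0, 1) are domain errors.
* Excess atom fractions ≤ 0 (no label contrast) raise an error in the
  oxidation estimator and a warning elsewhere; negative lipid ΔF warns of
  label loss or sample mix-up; non-positive ΔF makes turnover undefined
  (error).
* Lipid mass ↔ carbon-atom bookkeeping uses 12.011 µg per µmol C in both
  directions, so conservation is exact in atom units.
* Report tables are deterministic functions of inputs and flags; the only
  randomness anywhere is the simulator's seeded export noise.

## Problem sizes used by the test suite

The suite simulates 30-day incubations with daily steps, six lipid
species and up to six treatments; the noisy recovery study uses 100
replicate simulations. The full suite runs in well under a minute on a
single CPU.

## Limitations

The estimators inherit the linear-labelling assumptions above; turnover
times longer than the incubation are extrapolations; the assim~CH4~ mode
is a bookkeeping device, not evidence of methanotrophic assimilation; and
bulk rates depend on the per-bottle dry mass, which must be supplied by
the user (published rate tables are treated as consistency checks with
dry mass as a free parameter in the 3–4 g range, not as exact targets).
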