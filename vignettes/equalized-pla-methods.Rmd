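---
title: "Models and methods: dynamic-range equalization for proximity ligation assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dynamic-range equalization for proximity ligation assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaeq)
```

## The problem

A sandwich-style immunoassay resolves concentrations over only 3–4 orders of
magnitude: below the lower limit of quantitation the signal drowns in
background, above the upper limit it saturates. Serum proteins of clinical
interest span far more than that — femtomolar cytokines next to mid-nanomolar
acute-phase proteins — so conventional workflows split the sample and dilute
each panel differently, which introduces the notoriously analyte- and
sample-dependent artefact of non-linear dilution.

`plaeq` implements the alternative: *equalize* the signal chemistry itself,
per analyte, so that every target's reporter output lands in one quantifiable
window and a single undiluted sample can be read in one sequencing run. Two
tuning knobs make that possible in a solid-phase proximity ligation assay
(spPLA):

* **probe loading** — the concentration of the DNA-labelled detection
  antibodies (dAbs) shifts the binding equilibrium, moving the whole response
  curve up or down (and slightly rightward);
* **epitope depletion** — unlabelled antibody from the same polyclonal pool
  competes for epitopes, so a bound-antibody pair carries both required DNA
  labels with reduced probability, attenuating output binomially.

## The forward model

Each analyte is described by an effective number of dAb-addressable epitopes
$n$, one effective dissociation constant $K_d$ for the polyclonal pool, and a
bead capture efficiency. For total free antibody $T$ (5′-labelled +
3′-labelled + depletant, which compete identically), the occupancy of each
epitope is the Langmuir isotherm

$$\theta = \frac{T}{T + K_d}.$$

Conditional on binding, an antibody is 5′-labelled, 3′-labelled or unlabelled
with probabilities $p_5, p_3, p_d$ proportional to the pool concentrations. A
captured molecule yields a ligatable reporter only if at least one 5′- and
one 3′-labelled antibody are bound; with independent epitopes this is, by
inclusion–exclusion over the binomial occupancy,

$$P_{\text{pair}} = 1 - (1-\theta p_5)^n - (1-\theta p_3)^n
  + \bigl(1-\theta(p_5+p_3)\bigr)^n .$$

The reporter output for a sample concentration $x$ is then

$$\text{output}(x) = \min\!\bigl(x \cdot d \cdot \eta_c,\; c_{\text{bead}}\bigr)
  \cdot P_{\text{pair}} \cdot \eta_{\text{lig}},$$

with sample dilution $d$ (5 µL into 50 µL, i.e. 0.1), capture efficiency
$\eta_c$, bead capacity $c_{\text{bead}}$ (capture-antibody saturation) and
ligation efficiency $\eta_{\text{lig}}$.

**Mass balance.** Optionally (and by default in the study panel), the free
antibody is solved self-consistently: bound target sequesters dAb, so
$T_{\text{free}} = \max(T - n\,\theta\,c_{\text{captured}}, 0)$, iterated to a
relative tolerance of $10^{-10}$. The damping of the fixed-point iteration is
chosen per evaluation as $\min(0.5,\, 1/(1+L))$ with
$L = n\,c_{\text{captured}}/K_d$, the Lipschitz bound of the update map; a
fixed damping is not a contraction once $L > 3$, whereas this choice provably
is. Mass balance is what produces the hook effect — at high target loads the
shared antibody pool is diluted over ever more epitopes, occupancy collapses
and the signal *decreases* — and also what lets the depletant act as a pool
buffer (below).

This is deliberately the minimal equilibrium model consistent with the
qualitative behaviour of the two tuning mechanisms: independent identical
epitopes, a single effective $K_d$ per polyclonal pool, multinomial label
identity conditional on binding, no kinetics, no cross-reactivity, no
bead-level stochasticity.

## The tuning engine

Every analyte is tuned so that its output equals a common target — 1 fM
reporter DNA by default, the working point at which UMI counting is most
precise — at the *log-middle* (geometric mean) of its testing range:

```{r}
panel <- synthetic_panel()
tuned <- tune_panel(panel$analytes, panel$context)
tuned
```

Because output is monotone in the (symmetric, $c_5 = c_3$) probe loading, the
inverse problem is solved by bisection in $\log_{10}$ dAb over a 10 aM–1 µM
bracket to a relative tolerance of $10^{-3}$ — far below experimental
reproducibility. Published empirical tuning heuristics exist for this step,
but their coefficients are not public; root-finding on the declared forward
model is exact, reproducible and assumption-free, so that is what this
package does. An unattainable target (above the curve's plateau) is returned
as an explicit diagnosis, never silently clamped.

**Depletion policy.** High-abundance analytes tuned by loading alone end up
with a flat or hooked response: the tiny dAb dose that meets the 1 fM target
is exhausted by the huge epitope load. The panel tuner detects this with a
decadic-slope criterion ($d\log_{10}\text{output}/d\log_{10}x < 0.2$ at
either testing-range endpoint) and re-tunes those analytes with epitope
depletion. The depletant dose is set to the maximum bound-epitope
concentration over the range, $c_{\text{dep}} = n \cdot
c_{\text{captured}}(x_{\text{high}})$: at that scale the shared pool is no
longer measurably depleted by target binding, which restores a log-linear
response across the range (the "rightward shift"). Compensation is two-stage:
the expected fold-drop $F$ is measured on the model, loading is re-targeted
to $F \times$ target without depletant (e.g. 10 fM for a 10-fold drop and a
1 fM goal), and the final loading is re-solved jointly with the depletant in
place.

## The readout pipeline

Sequencing reads are 52-nt amplicons carrying a protein-specific barcode and
a UMI. The pipeline applies, in order: a length-then-quality filter (exactly
52 nt, all bases Phred ≥ 20), exact-sequence duplicate collapse, assignment
to the reporter with the highest *exact positional similarity score* — the
count of matching bases over non-UMI positions, no gaps or shifts — and
per-reporter counting of distinct UMIs. The UMI positions are excluded from
the score because they are random and would add ~`umi_length`/4 of noise to
every comparison; a gapped aligner is deliberately not used because the
reporters share near-identical subsequences shifted by a few bases, which
exact positional scoring keeps apart. A read assigns only if its best score
is strictly greater than 31 (a score of exactly 31 is discarded; the
threshold is configurable), and best-score ties are discarded as ambiguous.
Counts are reported as nUMI: unique UMIs for the target divided by unique
UMIs for the spiked control oligo, cancelling sample-level factors such as
library pooling. Phred+33 encoding and same-strand orientation are assumed
(both configurable).

## qPCR branch

During tuning the reporter output is read by qPCR. Traces are min–max
normalized per Eq. (above) and the Ct is the first cycle at or above 0.25 of
maximum — integer by definition, with an optional interpolated mode that
improves calibration fits. DNA calibration is ordinary least squares of Ct on
$\log_{10}$ concentration (base 10 throughout, per qPCR convention);
zero-concentration blanks cannot enter a log fit and serve only as
no-amplification checks. The inverse conversion is
$[{\rm DNA}] = 10^{(C_t - b)/m}$. For library preparation, if samples' Cts
lie within a 3-cycle band all are amplified to $1 + \overline{C_t}$,
otherwise each to $1 + C_t$, rounded half away from zero (thermocyclers take
integers).

## Calibration and quantification

Standards (six-point 3× serial dilutions of an all-analyte mix, in
triplicate) are fitted per analyte with the four-parameter logistic curve

$$\text{nUMI}(x) = \frac{A - D}{1 + (x/C)^B} + D,$$

minimizing the *log residuals* $\sum(\log \text{nUMI} - \log
\widehat{\text{nUMI}})^2$ so that standards spanning decades contribute
comparably. The optimizer is bounded Levenberg–Marquardt in a log
parametrization ($A, C, D > 0$ by construction, $B \in [0.1, 10]$, $C$ within
$10^3\times$ the standards' range), started from the data: $A$ and $D$ at the
observed extremes oriented by the data's monotone direction, $C$ at the
geometric mean of the concentration range, $B = 1$, with two deterministic
nudged restarts for knife-edge singular starts. With $B$ constrained
positive, a decreasing curve is represented by $A > D$ rather than a negative
Hill coefficient, so curve direction is carried by $\mathrm{sign}(D - A)$.
Replicates enter the loss individually, and no background subtraction is
applied — the $A$ parameter absorbs background.

Unknowns are inverted through the exact algebraic inverse
$x = C\,((A-D)/(\text{nUMI}-D) - 1)^{1/B}$; responses at or beyond the
asymptotes are flagged `below_lloq` / `above_uloq` and never extrapolated,
because the inverse is undefined there and extrapolation fabricates dynamic
range.

## The synthetic study conditions

The generator exists so that every stage is testable without instrument
data; its defaults are the package's study conditions and are not retuned:

* four analytes with testing ranges 2–200 fM, 0.5–50 pM, 5–500 pM and
  1–70 nM (seven orders of magnitude end to end), each with $n = 6$,
  $K_d = 1$ nM, capture efficiency 0.9;
* 50 µL reactions with 5 µL sample, ligation efficiency 0.8, bead capacity
  10 nM, mass balance on. Capture and ligation efficiencies are high because
  the common 1 fM target must be *attainable* for the femtomolar analyte:
  at its 20 fM log-middle only 2 fM of target is present in the reaction, so
  near-unit conversion is required — consistent with the observed working
  point of such assays. The bead capacity sits above the captured range of
  the nanomolar analyte, mirroring the practice of loading extra capture
  beads for abundant targets;
* libraries of 200,000 reads per sample; UMI length 10 (UMI space
  $4^{10} \approx 1.05$M, low collision rates at the ~30,000 molecules of
  1 fM in 50 µL); per-base substitution error 0.001 with Phred profile
  mean 35, sd 3; 1% truncated and 1% low-quality reads to exercise the
  filters; control oligo at 100 aM; per-replicate lognormal assay CV of 5%
  emulating pipetting/ligation variability.

Read depth is allocated multinomially over molecules and UMIs are drawn
uniformly, so UMI saturation follows the collision closed form
`expected_unique_umis()`. The generator is substitution-only (reads are
fixed-length and the pipeline gapless, so indels would only re-exercise the
length filter), it does not model quality-dependent or positional Illumina
error profiles, PCR chimeras, or index hopping — so passing tests demonstrate
the pipeline's logic and the method's statistical behaviour, not robustness
to every real-world sequencing artefact.

With these conditions, tuning the panel to 1 fM compresses the outputs over
all six-point standards from more than five orders of magnitude (untuned at a
uniform 250 pM dAb) to under three, and the full simulate → count → fit →
quantify loop recovers spiked truths of 8 fM, 1 pM, 50 pM and 10 nM with a
median relative error of a few percent at 200k reads per sample — both
recomputed by `scripts/acceptance.R` and asserted in the test suite.

## Numerical and design choices, in brief

* concentrations are molar everywhere internally; parsers accept
  aM–mM suffixes;
* bisection rather than Newton for tuning: unconditional bracketing
  robustness on a monotone objective;
* fixed-point damping adapted to the contraction bound (see above);
  tolerance $10^{-10}$, far below assay noise;
* similarity threshold semantics are *strictly greater than* 31; the
  equally defensible "≥" reading is one flag away;
* ties at the best similarity score discard the read rather than guess;
* single-replicate standard deviations are reported as 0 by convention;
* the spiked control oligo concentration, UMI length and Phred encoding are
  configuration, not constants, since real reporter panels vary.

## Limitations

The forward model is an equilibrium caricature: no incubation-time kinetics,
no antibody cross-reactivity, one effective $K_d$ per pool, and a hard
capacity cap instead of bead binding kinetics. Tuned concentrations for real
antibodies will differ from the synthetic panel's (they depend on the actual
affinities and epitope counts); what the package demonstrates is the
*procedure* — that a forward model plus root-finding equalizes a panel and
that the downstream pipeline quantifies it correctly.
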