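---
title: "foxdyn: models, error analysis and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foxdyn: models, error analysis and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxdyn)
```

This vignette is the package's account of its science: the models it fits,
the error analysis it performs, the conventions it adopts where the
underlying analyses are under-specified, and what its synthetic-data tests
do and do not demonstrate about real data.

## The relaxation model and its error analysis

### Exponential decay fits

Longitudinal (R₁) and rotating-frame (R₁ρ) ¹⁵N relaxation series are
pseudo-3D experiments: one 2D plane per relaxation delay, one peak per
residue. Each residue's intensities are fit to the two-parameter
mono-exponential

$$ I(t) = I_0\, e^{-R t}, $$

by unweighted least squares with a damped Gauss–Newton (Levenberg–
Marquardt) iteration. Assumptions: the decay is truly mono-exponential
(no exchange contribution resolved within the delay range), the noise is
additive, homoscedastic and Gaussian, and delays are known exactly.
Duplicated-delay points enter the fit as two independent observations —
they carry real information and averaging them would understate the
residual spread. Negative intensities are allowed (noise can push weak
peaks below zero); no log-linearisation is ever used, because it would
both forbid negative values and distort the noise model.

The fitter is vectorised across curves that share one delay schedule: the
2×2 normal equations of the damped step are solved in closed form for
thousands of curves simultaneously. This is what makes the Monte-Carlo
error analysis (1000 refits per residue) and the 500-residue recovery
suites run in seconds; `minpack.lm::nlsLM` serves as an independent
cross-check of the fitter in the test suite, not as the production path.

*Initialisation*: $I_0$ starts at the maximum intensity and $R$ at the
endpoint log-ratio $\ln(I_\mathrm{first}/I_\mathrm{last}) /
(t_\mathrm{last}-t_\mathrm{first})$, clipped to $[10^{-3}, 10^{3}]$ s⁻¹ —
robust for monotone decays, and the clip keeps pathological noise
realisations from starting the iteration at absurd rates.
*Convergence*: relative SSE change below $10^{-12}$, at most 100
iterations with per-curve damping; a curve for which no damped step
improves the fit is accepted as converged at a (local) optimum, and
non-finite parameters mark the fit failed. *Degenerate inputs*: fewer
than three distinct delays or an all-zero series are precondition errors;
a constant series converges to $R \approx 0$.

### Pooled noise and Monte-Carlo errors

The intensity noise is estimated from the duplicated delay plane as the
pooled standard deviation over all $k$ peaks,

$$ \sigma = \sqrt{ \textstyle\sum_i (s_{i,1}-s_{i,2})^2 \,/\, 2k }, $$

which is the maximum-likelihood estimate when every peak shares one
Gaussian noise level — the interleaved acquisition makes that a reasonable
assumption, and pooling across peaks is what makes a single duplicated
plane sufficient.

Rate errors are Monte-Carlo: for each residue, 1000 synthetic datasets are
drawn with every intensity resampled from a normal centred at the
*measured* value with width **2σ**, each is refit, and the error is the σ
of a three-parameter normal $A\exp(-(x-\mu)^2/2\sigma^2)$ fit to the
histogram of best-fit rates; the reported interval is **2σ** of that
distribution. Two deliberate conventions are reproduced here rather than
"fixed": resampling at *twice* the pooled noise and then *also* reporting
twice the resulting width stacks two conservative factors, so the reported
95% intervals over-cover (the acceptance suite verifies coverage ≥ 90%,
and in practice observes essentially complete coverage at SNR 50). The
resampling width is configurable (`mc_width_factor`) for sensitivity
analysis. The histogram fit uses 30 bins spanning the sample mean ± 5
sample SDs — the underlying procedure prescribes a histogram fit but no
binning, so a fixed, scale-free rule was chosen — and falls back to the
plain sample SD if the nonlinear fit fails (the two agree within ~10% on
well-behaved series, which the tests check). With fewer than 80% of
replicate fits converged the error estimate is refused outright.

The linearised (delta-method) standard error
$\sigma^2 (J^\top J)^{-1}$ evaluated at the same resampling width is
exposed as `linearized_rate_sigma()` and serves as the analytic
cross-check: at SNR 50 the two routes agree within 25% (acceptance
criterion), typically within ~10%.

### Tilted-field correction and hetNOE

R₁ρ rates measured under a spin-lock of strength ω₁ relax about a tilted
effective field once the resonance offset Ω is non-zero. The standard
correction

$$ R_2 = R_{1\rho}/\sin^2\theta - R_1/\tan^2\theta, \qquad
   \theta = \arctan(\omega_1/\Omega) $$

is applied per residue; Ω = 0 maps to θ = π/2 where $R_2 = R_{1\rho}$
exactly. The spin-lock field is configured in kHz and converted internally
as ω₁ = 2π·10³·`spinlock_khz` (default 1.9 kHz). The ¹⁵N carrier position
is *not* hard-coded: offsets require either explicit per-residue values in
Hz or a shift table plus `carrier_n_ppm`, because no universal default
exists for the carrier. The implemented form of the correction is the
standard tilted-frame expression; the identity
$R_2 = R_{1\rho} + \cot^2\theta\,(R_{1\rho}-R_1)$ is enforced to
$10^{-12}$ in the tests.

The steady-state heteronuclear NOE is the plane ratio
$I_\mathrm{sat}/I_\mathrm{ref}$ with first-order error propagation from
the pooled intensity noise (the saturated term is dropped at
$I_\mathrm{sat}=0$). Flexibility bands follow the usual reading at 600
MHz: NOE > 0.5 marks ordered backbone, negative values mark high ps–ns
flexibility, and the closed interval [0, 0.5] is intermediate — the
boundary 0.5 itself is assigned to the intermediate band, a convention
the classifier documents and the tests pin down.

## Chemical-shift analyses

The composite amide perturbation is

$$ \mathrm{CSP} = \sqrt{ \Delta\delta_H^2 + (\Delta\delta_N/7)^2 }. $$

The nitrogen divisor 7 reproduces the community-standard ≈ 0.14 weighting
of nitrogen shifts; it is exposed as `n_scale`, and an alternate
"variance" reading $\Delta\delta_N^2/7$ is selectable for sensitivity
analysis because composite-CSP formulas are notoriously typeset
ambiguously in the literature. Residues assigned in the free state but
absent (or unassigned) in the bound state are flagged *broadened* — their
peak disappeared, which is information, not missing data — and carry no
CSP value. Unassigned residues are excluded from all sums, never imputed.

Cross-homolog comparison correlates the shifts of one nucleus over
residue pairs matched by global sequence alignment (BLOSUM62, gap open 10,
gap extension 0.5), the package's declared choice where a
structure-based matching would also have been defensible; for the nearly
gap-free FH domains the two coincide. Percent identity uses identical
columns over the full alignment length, terminal gaps included. Pearson's
r is computed by `stats::cor` over mutually assigned pairs (at least
three required; zero variance on either side is an error, not NA).

Titration endpoints are classified per residue in a fixed precedence:
*broadened* (bound peak absent, or bound/free intensity ratio below
`broadening_ratio`, default 0.3) → *strong CSP* (above
`csp_strong_threshold`, default 0.05 ppm) → *weak CSP* (above the
`csp_noise_floor`, default 0.005 ppm, about the digital resolution of a
2D HSQC) → *unaffected*. The weak/strong boundary and the broadening
ratio are conventions of this package — the qualitative three-way
categorisation they implement is standard, but no published cutoffs
exist — and all three are config-exposed. The per-spectrum summary is the
dominant category over affected residues, with ties resolved toward the
more severe category (broadening over strong over weak), so that a
spectrum half-broadened and half-shifted reads as a broadening response.

## Geometry

"Backbone" means N, CA, C, O throughout. Superposition is the Kabsch
algorithm — SVD of the coordinate cross-covariance with the determinant
correction that forbids reflections — over the backbone atoms of mapped
residues with **zero cycles of outlier rejection**: every mapped residue
with a complete backbone in both models enters the fit, and the RMSD is
computed over exactly those atoms. Residues missing any backbone atom are
dropped as whole residues (an atom-level fit would weight residues
unevenly); fewer than three usable residues is an error.

Per-residue Cα deviations are measured against a *chosen reference model*
(the first, by default) after backbone superposition — the convention is
explicit because ensemble-average references are also common. RMSF
superposes every frame onto the mean structure with one refinement pass
(align to frame 1 → mean → re-align to mean → final mean), which removes
rigid-body motion exactly; the tests verify machine-zero RMSF for purely
rigid trajectories and the analytic $\sqrt{3}\sigma$ value for iid
per-coordinate jitter.

Distance monitors resolve (chain, residue, atom) selectors in every frame
and fail loudly — naming the monitor label and frame index — rather than
skipping frames. "Carboxyl group (CO)" selectors resolve to the backbone
carbonyl oxygen `O` by default, with the carbon atom selectable, since a
distance "to the carboxyl group" is pictorially defined at best. The six
bundled H4-region monitors translate to all four isoform numbering
schemes by the constant FH alignment offsets. The d₆ monitor (H4
orientation relative to helix 2) is anchored at the H4 lysine's NZ, the
package's declared reading of an under-specified definition.

### The tryptophan-interaction motif

The W-[2-5]-[S/T/C/Y] motif pairs a tryptophan with a Ser/Thr/Cys/Tyr
whose side chains can interact; the sequence scan enumerates all pairs
with 2–5 intervening residues, in both orders. The geometry of a pair is
(d, α): d is the distance from the partner's side-chain heteroatom
(OG/OG1/SG/OH) to the centroid of the tryptophan ring system, α the angle
between the ring-plane normal and the heteroatom direction, folded to
[0°, 90°] so that 0° is face-on and 90° edge-on and the sign of the
fitted normal is irrelevant. Conventions declared here: the centroid and
plane use all nine indole heavy atoms by default (the five- and
six-membered rings alone are selectable); the plane normal is the
smallest-singular-value direction of the centred ring coordinates; and
the 6 Å default interaction cutoff (`motif_d_cutoff`) flags pairs for
reporting — the underlying comparison reports full (d, α) distributions
without committing to a cutoff, so the flag is a convenience, not a
claim. A pair such as the spacing-1 Ser–Trp occasionally discussed in
this family falls outside the 2–5 window by definition and is not
reported unless the window is widened.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *statistical structure the analyses assume*:
mono-exponential decays with additive iid Gaussian noise on the standard
delay schedules (0.01–2.00 s for R₁ with the 0.507 s plane duplicated;
0.01–0.2 s for R₁ρ with 0.0575 s duplicated); titration endpoints whose
CSPs are placed deliberately above/below the classifier thresholds;
homolog shift tables with an exact population correlation; idealised
α-helices (1.5 Å rise, 100° twist, textbook values) carrying a planar
nine-atom indole and a heteroatom at an exact (d, α); and trajectories
that are rigid motions plus iid Gaussian jitter.

They deliberately do **not** emulate: multi-exponential or
exchange-broadened decays, peak overlap and lineshape-fitting artefacts,
Rician or multiplicative noise, correlated (collective) motions,
force-field physics, or realistic side-chain packing. Passing the
recovery suites therefore demonstrates that the *estimators are correct
under their own assumptions* — unbiasedness, calibrated error bars,
exact geometric round trips — not that those assumptions hold for any
particular real dataset. That separation is intentional: it is the part
of the pipeline that can be proven at desk scale.

Problem sizes used by the test and acceptance suites, chosen to give the
statistics comfortable margins while keeping a full run in tens of
seconds: 500 synthetic residues (SNR 50) for bias and coverage, 50
residues × 1000 Monte-Carlo replicates for the error-model comparison,
10⁴ random draws for the tilted-field identity, 2000 frames × 60 residues
for the RMSF expectation, and 40-residue shift tables for the titration
and correlation round trips.

## Bundled reference data

`inst/extdata/foxo_fh_domains.fasta` carries the forkhead-domain regions
of the four human FOXO proteins (UniProt Q12778, O43524, P98177, A8MYZ6)
with their author residue numbering, so that conservation and motif
analyses run without network access. The four FH regions are colinear
(constant numbering offsets, no indels), which is also why the d₁–d₆
monitor translation uses constant offsets. The bundled sequence windows
span helix 1 through the second wing (87 residues); percent-identity
figures computed from them refer to these windows, not to full-length
proteins, whose termini are far more divergent.

## Known limitations

* Offsets for the tilted-field correction must be supplied by the user
  (directly or as shifts + carrier); the package cannot guess the carrier.
* The relaxation model is strictly mono-exponential; no model-free
  analysis, spectral-density mapping or dispersion fitting is attempted.
* Titration classification is endpoint-based; no binding constants are
  estimated from titration curves.
* Structures are read from PDB text (multi-model PDB for trajectories);
  binary trajectory formats are out of scope.
* The RMSD/RMSF machinery assumes identical topology across frames and
  complete backbones for superposed residues; it reports, rather than
  repairs, violations.
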