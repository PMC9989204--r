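---
title: "Membrane observables on planar bilayers: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane observables on planar bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayr)
```

`bilayr` computes the standard observable battery of bilayer
simulations — leaflet assignment, thickness, area per lipid, order
parameters, density and dipole-potential profiles, radial distribution
functions, contact recurrence, lateral diffusion, flip-flop detection —
plus a validation procedure for coarse-grained mappings. This vignette
is the package's own account of the models behind those functions, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic test bed does and does not
establish about real data.

## The planar-bilayer model

Every analysis assumes a planar bilayer with its normal along z in an
orthorhombic box. Leaflet assignment, thickness and area per lipid use
a *global* midplane — the mean z of the reference sites (usually the
phosphates) per frame — rather than fitting a local surface. For the
flat, tension-free bilayers this package targets, curvature corrections
are far below the other sources of noise; vesicles, buckled membranes
and strongly undulating boxes are out of scope, and a local-normal
method should be used there instead. Triclinic boxes are rejected
outright rather than approximated: all geometry here relies on
independent wrapping of the three axes.

Units follow GRO conventions throughout: nm, ps, atomic mass units,
elementary charges. Coordinates are stored as read; each analysis wraps
or demands unwrapped input as its physics requires (densities wrap,
diffusion refuses wrapped input).

## Leaflets, thickness, area per lipid

A molecule is `upper` or `lower` by the sign of its reference site's
z relative to the midplane, or `transiting` within a band of
`transit_band = 0.3` nm around it. The band is chosen smaller than half
a headgroup (so settled lipids are never mislabelled) yet wide enough
that a molecule crossing the midplane spends at least one frame inside
it at typical output intervals. Thickness is the distance between the
mean reference-z of the two leaflets, excluding transiting molecules.
Area per lipid divides the lateral box area by the *mean* of the two
leaflet counts — a symmetric convention that remains meaningful for
asymmetric bilayers, with per-leaflet areas reported alongside. Guest
amphiphiles are excluded from the lipid count by default; because
conventions differ on whether a surfactant "occupies" lipid area, the
guest-inclusive value can be requested and both are reported rather
than guessing a single convention.

## Order parameters

The coarse-grained order parameter of a bead–bead bond is
`P2 = ⟨(3 cos²θ − 1)/2⟩`, θ against +z, averaged over frames and over
bonds sharing a label; 1, −0.5 and 0 mean aligned, in-plane and
isotropic. The deuterium order parameter per chain carbon is
`S_CD = |⟨(3 cos²θ_CH − 1)/2⟩|`; the absolute value matches the
positive axes on which such profiles are conventionally drawn. With
explicit hydrogens the C–H vectors are read from the coordinates
(hydrogens share their carbon's chain label and position in the site
table). Without hydrogens, the two ideal tetrahedral C–H directions of
carbon k are reconstructed in the plane perpendicular to the
C(k−1)→C(k+1) axis, symmetric about the in-plane bisector of the two
C–C bonds; terminal carbons are omitted. One degenerate case needs a
rule: on an exactly straight (collinear) chain — which the synthetic
generator produces by construction — the bisector vanishes, and the
reconstruction falls back to the analytic average over the circle of
perpendicular directions, `−P2(cos θ_axis)/2`. This is the limit the
tetrahedral construction approaches under free axial rotation, and it
makes the reconstructed and explicit conventions agree on the
all-trans z-aligned anchor (S_CD = 0.5).

Error bars everywhere are standard deviations over 5 contiguous block
means (configurable); block averaging, not the per-frame standard
deviation, is the honest estimate under the strong frame-to-frame
correlation of membrane observables.

## Profiles and the dipole potential

Density profiles bin wrapped z into uniform half-open bins after
recentring the bilayer midplane to the box centre per frame; without
recentring, slow bilayer drift smears every feature. Electron-weighted
profiles refuse site tables with undefined electron counts —
coarse-grained beads have no meaningful electron number, so CG systems
get mass densities instead. Bin counts are conserved exactly under
rebinning (the integral times the box area recovers the summed
weights), which the tests assert at 0.1%.

The dipole potential integrates Poisson's equation twice along z with
trapezoidal quadrature on the binned charge density, imposing zero
field and zero potential at the lower box edge. The permittivity enters
once, as `ε₀ = 0.05526349406 e V⁻¹ nm⁻¹`, and is pinned by a unit test
against the parallel-plate closed form `ΔΨ = σd/ε₀` (0.1 e nm⁻² over
1 nm gives 1.8095 V). The double integration is additionally checked
against an independent O(n²) double-sum oracle to 10⁻⁶ relative. A net
system charge makes the potential inconsistent with periodicity; the
result then carries a warning flag rather than silently shifting the
baseline. Profiles are not symmetrised and no per-leaflet decomposition
is attempted; binning (default 100 bins) and block length are exposed
because no single choice suits both coarse and fine traces.

## Contacts and radial distribution functions

`contact_recurrence` scores, per frame, whether the *minimum*
minimum-image distance between a guest atom group and a lipid atom
class is below a cutoff, and reports the fraction of frames in contact.
The binary per-frame convention (rather than counting simultaneous
pairs) is robust to group size and reads directly as "how persistently
does this moiety touch that one". Cutoffs are explicit parameters
recorded in the output: 0.35 nm by default — the conventional
heavy-atom criterion for hydrogen bonds and salt bridges — with 0.50 nm
the usual van der Waals choice for apolar contacts. No angular
hydrogen-bond criterion is applied; at coarse-grained and
heavy-atom-only resolutions the distance criterion is the common
denominator.

`radial_distribution` is the standard pair histogram normalised by the
per-frame ideal-gas shell expectation, with self-pairs excluded and
`r_max` capped at half the smallest box edge (beyond which
minimum-image distances are undefined). The pair loop is compiled
(Rcpp) because meaningful ideal-gas validation takes ~10⁹ pair
distances.

## Diffusion and flip-flops

Lateral MSD uses all time origins via the FFT autocorrelation
algorithm (validated against a naive O(F²) oracle), restricted to lags
up to half the trajectory, with per-frame leaflet-centre motion
subtracted so collective drift does not masquerade as diffusion.
Molecules that change leaflet are excluded and reported. The diffusion
coefficient is the least-squares slope over the 10–50% lag window
divided by 4: the short-lag end is dominated by the step distribution,
the long-lag end by origin starvation, and this window is the standard
bias/variance compromise.

A flip-flop is a leaflet-label change followed by residency: the event
is accepted only if the molecule holds the destination leaflet for at
least `min_residency` (default 10 ns), the criterion that separates
genuine translocation from midplane excursions. Transiting frames
bridge — they neither trigger a crossing nor reset the residency —
which prevents one slow crossing from splintering into several
spurious events. A crossing whose observation window ends before the
threshold can be verified is reported censored, not accepted; a return
crossing closes its excursion rather than opening a new event, so a
failed 8-ns excursion is one rejected event, not two.

## CG mapping validation

Pseudo-beads are placed at the centre of mass (site-table masses, not
geometric centres) of each bead's atoms, after reconstructing the bead
around its first atom across periodic boundaries; a bead whose atoms
still span more than half a box edge has no well-defined COM and is an
error. Bond, angle and dihedral distributions (IUPAC sign convention,
cis = 0) are histogrammed at 0.005 nm / 2° / 5° — fine enough to
resolve typical coarse-grained bonded terms without empty-bin noise —
and compared by Jensen–Shannon divergence in bits, chosen because it is
symmetric, bounded (0 = identical, 1 bit = disjoint) and defined for
non-overlapping histograms where Kullback–Leibler is not; the overlap
coefficient is co-reported as the more intuitive number. The pass
threshold (default 0.05 bits) makes numeric what is otherwise a visual
judgement of "good reproduction"; it is deliberately configurable
because no universal threshold exists. Bond histograms use data-driven
ranges padded 5%; to compare two trajectories, compute the first
distribution set and pass its `breaks` when computing the second —
mismatched binning is a refusal, never a silent rebin.

## The synthetic test bed

The generator builds what the analyses assume: lipids on a square
lateral grid at a prescribed area per lipid, phosphate planes at a
prescribed separation, straight chains tilted by a prescribed
distribution (fixed angle, wrapped Gaussian, or isotropic), guests
planted at a prescribed depth below the phosphate plane, an optional
uniform water slab, lateral Brownian motion with per-axis step variance
`2·d_lat·dt`, scripted leaflet translocations, and optional Gaussian z
noise. Dynamics are kinematic — geometry resampled per frame plus a
random walk, no forces, no thermostat — because the purpose is known
ground truth: every observable has a closed-form expectation (P2 equals
`(3cos²θ₀−1)/2` exactly at fixed tilt; thickness and area per lipid
equal their prescribed values exactly without noise; the recovered D is
the prescribed one; scripted flips are recovered by the residency
rule). Tilt is applied rigidly to whole chains so per-bond and
per-chain order coincide, giving the same closed-form anchor to P2 and
S_CD. Default conditions are a 64-lipid-per-leaflet bilayer at
0.5625 nm² per lipid and 4.0 nm phosphate separation with
d_lat = 10⁻³ nm²/ps — magnitudes typical of fluid phospholipid
bilayers. Electron counts and charges of the synthetic beads are
placeholders at plausible heavy-atom magnitudes (only conservation
properties depend on them), and the guest carboxylate is modelled
protonated so default systems are net-neutral for the potential
integration.

What passing on this test bed shows: the estimators are correct — they
recover known geometry, order, kinetics and electrostatics at stated
tolerances, and the full pipeline is bit-reproducible under a fixed
seed. What it does not show: anything about conformational realism.
Real bilayers have disordered chains, protrusions, undulations,
heterogeneous composition and correlated motion; none of these are
emulated, so agreement here validates the arithmetic of the analyses,
not any force field or sampling protocol.

## Problem sizes and reproducibility

The shipped tests run the analytic anchors at 10⁶ samples, geometry
recovery on 128 lipids × 500 frames, diffusion recovery on 32 lipids ×
5000 frames, and the ideal-gas RDF at 10⁴ sites × 100 frames — sizes at
which every stochastic tolerance (0.005 on isotropic P2, 15% on D, 0.05
on |g−1|) has comfortable margin while the whole suite stays desk-scale.
All randomness flows from explicit integer seeds through R's RNG;
identical configuration and seed reproduce every numeric output
byte-for-byte, and `run_pipeline()` records inputs, parameters, seed,
package version and per-analysis status in a manifest alongside the
tables.

## Known limitations

Planar geometry only; orthorhombic boxes only; no angular hydrogen-bond
criteria; no NMR quadrupolar-splitting conversion from S_CD; no
per-leaflet potential decomposition; the flip-flop detector assumes the
label series covers contiguous time; and the guest/lipid vocabulary of
the generator (one phosphate and one amine per lipid, carboxylate and
hydroxyl headgroup sites per guest) is a deliberate minimal caricature —
real site tables with richer polarity classes are fully supported by
the analyses themselves.
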