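---
title: "Methods: analysing polymer-grafted nanoparticle trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing polymer-grafted nanoparticle trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanobrush)
```

# Scope and data model

`nanobrush` analyses coordinate trajectories of a spherical nanoparticle
core grafted with polymer chains and immersed in an aqueous electrolyte.
The package separates *chemistry* from *geometry*: a `topology` carries
per-atom element, partial charge (e), mass (amu), Lennard-Jones
parameters (kcal/mol, Å), heavy-atom and hydrogen-bond role flags, bonds,
named groups (`NP_CORE`, `PEG`, `WATER`, `ION_NA`, `ION_CL`, extensible)
and per-chain ordered heavy-atom lists; a `trajectory` is a time-ordered
sequence of frames, each an N×3 coordinate matrix with an orthorhombic
box. Internal units are Å, ps, e, amu and kcal/mol throughout;
conversions to V, mV and m²/s happen only at reporting boundaries, using
constants derived from CODATA 2018 values at load time rather than
numbers quoted from memory.

Atom indices are 1-based everywhere inside the package — the natural R
convention — and file writers emit each format's native serial numbering.
Only orthorhombic boxes are supported; triclinic input raises an explicit
unsupported-format error rather than a silent wrong answer, since every
minimum-image operation in the package assumes a diagonal cell.

Coordinate formats (extended XYZ, GRO, PDB) cannot carry charges, LJ
parameters or bonds, so a JSON sidecar travels with each coordinate file.
GRO files are written with five decimals in nm (a widening GROMACS
explicitly permits), so a write–read round trip preserves coordinates to
10⁻⁴ Å rather than the 10⁻² Å of the standard narrow columns.

# Radial profiles

All spherically averaged profiles share one estimator: atoms are wrapped
by minimum image about the chosen center, binned into shells of width
0.1 Å (configurable), the time-averaged shell count is divided by the
shell volume $\tfrac{4\pi}{3}(r_2^3-r_1^3)$, and — for the RDF — by the
selection's mean density over the box volume so the profile tends to 1 in
the bulk. Radii beyond half the shortest box edge are excluded by
default, because shells there leave the box and the normalization claim
fails; a warning flags any user-requested larger grid.

Two center conventions exist because they answer different questions: the
core's *geometric center* (default, used for volume fractions) and a
*fixed central atom* (the usual RDF reference); a center-of-mass mode is
also provided. For water profiles the oxygen position stands for the
molecule, the standard convention.

The cumulative radial fraction is the shell-weighted running sum
normalized to end at 1, evaluated at bin right edges; an all-zero profile
is an error (the normalization is undefined), and non-monotone inputs to
downstream crossings are rejected.

**Bulk onset.** The shear plane for electrokinetics sits where the water
RDF "reaches 1". A first-touch rule would latch onto sub-bulk
oscillations inside the polymer coating, so the detector requires a
*sustained* crossing: the smallest radius where the linearly interpolated
RDF reaches 1 and stays at or above $1-\mathrm{tol}$ (default 0.05) over
the following 2 Å. Both the tolerance and the run length are exposed,
because a noisy single-frame RDF estimate needs a looser gate than a
10 000-frame average.

# Chain metrics

Chains are unwrapped from their anchor by accumulating minimum-image bond
vectors before any metric; a bonded pair further apart than half the box
is refused with an error demanding unwrapping, never silently wrapped
into a nonsense distance.

The radius of gyration is, by default, the *unweighted* root-mean-square
deviation of the chain's heavy atoms from their centroid. With that
choice the pairwise identity
$R_g^2 = \frac{1}{2N^2}\sum_{i,j}|r_i-r_j|^2$ holds exactly and serves as
an independent oracle in the tests. A mass-weighted mode about the center
of mass is provided; for PEG's heavy atoms (C and O of similar mass) the
two differ little, and the unweighted sum is the form that matches an
unweighted sum over N heavy atoms. The end-to-end distance is between the
anchor-side first and solution-side last heavy atoms of the chain order;
the terminus–core distance d uses the same terminal atom.

**Layer thickness.** thk = r(C=0.95) − r(C=0.05) with both crossings
linearly interpolated between bin edges — the radial span holding 90 % of
the polymer. The estimate is invariant to uniform rescaling of the
profile amplitude, and on analytic profiles (uniform shell, uniform ball)
it reproduces the closed forms to the interpolation error of the 0.1 Å
grid (≲10⁻³ Å).

**Volume fractions.** Every polymer heavy atom contributes 20 Å³ at its
position and every water molecule 30 Å³ at its oxygen. Assigning 20 Å³ to
*all* polymer heavy atoms — including terminal-group and anchor heavy
atoms, not only the backbone CH₂ groups and ether oxygens — is a
deliberate simplification: the per-group volume is itself a coarse
constant, and a per-species table would suggest precision the method does
not have.

**Brush fit.** The Daoud–Cotton model predicts
$\phi \propto r^{-4/3}$ (r measured from the particle surface) in the
semidilute brush regime of a star-like grafted object. The fit is
ordinary least squares of $\log\phi$ on $\log r$ over an explicit window;
nonpositive bins are dropped with a warning and fewer than five remaining
bins is an error. Exponent recovery is exact on noiseless power laws and
within 0.02 at 1 % multiplicative noise over 100 bins — the regime the
tests pin.

**Grafting density** is simply chains per surface area, with the area an
explicit argument: published chain counts and densities can imply an
*effective* surface radius different from the nominal core radius (a
2 nm-diameter particle carrying 50 chains at 2.3 chains nm⁻² implies
≈21.7 nm², not the nominal 12.6 nm²), and hiding that choice inside the
function would make the discrepancy invisible.

# Hydrogen bonds and nonbonded energies

A (donor-H, acceptor) pair counts as a hydrogen bond when the heavy-atom
distance is below 3.0 Å and the angle is below 20°. The angle's vertex is
ambiguous in common usage, so both conventions are selectable: vertex at
the *donor* (angle between donor→H and donor→acceptor; the default) or at
the *hydrogen* (deviation of D–H⋯A from linearity). The default matches
the H–donor–acceptor ordering of the criterion and, at these tight
cutoffs, the two conventions agree on all but marginal geometries. A
donor with two polar hydrogens can contribute two bonds; a donor without
any bonded polar hydrogen is a topology error, reported by atom index.

Pair energies sum truncated Coulomb $k_C q_iq_j/r$
($k_C = e^2/4\pi\varepsilon_0$ ≈ 332.06 kcal mol⁻¹ Å e⁻²) and
Lennard-Jones terms with arithmetic-mean σ / geometric-mean ε combining
rules over unordered pairs spanning the two selections, pairs in the
intersection counted once, 1-2 and 1-3 bonded pairs excluded and 1-4
included unscaled. The default 12 Å cutoff must sit below half the box;
an optional CHARMM-style switching window tapers the LJ term smoothly to
zero at the cutoff. Production MD engines treat long-range electrostatics
with Ewald summation; this package deliberately uses direct truncated
sums instead. Group-pair energy *decompositions* are short-range
dominated and are used here comparatively, and a no-cutoff direct-sum
mode (`cutoff = Inf`) exists for point-charge validation against Coulomb
closed forms. Absolute long-range electrostatic energies are out of
scope.

# Electrokinetics

The charge-density profile is the per-shell time-averaged sum of partial
charges divided by the shell volume — algebraically identical to
multiplying each atom type's number density by its charge and summing.
The field follows from the spherically symmetric Gauss law,

$$E(r) = \frac{1}{4\pi\varepsilon_0 r^2}\int_{r_0}^{r}\sigma(r')\,4\pi r'^2\,dr'
 \;+\; \frac{Q_\mathrm{core}}{4\pi\varepsilon_0 r^2},$$

integrated from the particle surface $r_0$ by trapezoidal quadrature on
the bin grid, and the potential by inward integration
$\phi(r)=\int_r^{r_\mathrm{bulk}}E\,dr'$ with $\phi(r_\mathrm{bulk})=0$.
The vacuum permittivity is correct here, not an approximation: the
solvent is explicit, so its polarization is already carried by the water
partial charges. The bulk reference makes ζ a bulk-referenced potential;
ζ is read off at the shear plane by linear interpolation. At 0.1 Å bins
the whole σ→E→φ chain reproduces Coulomb closed forms for planted shells
to better than 1 % away from shell surfaces (at a surface the true field
is discontinuous and the binned field is mid-jump by construction — a
property of the discretization, not an error). The chain is linear in σ,
and shell-by-shell charge conservation holds to 10⁻⁶ e on planted
configurations.

# Diffusion and aggregation

The MSD uses all time origins, of the selection's center of mass by
default (the conjugate's self-diffusion) or averaged over individual
atoms for independent-walker tests. A per-step displacement exceeding
half the box means wrapped coordinates and is refused. The diffusion
coefficient is the least-squares MSD slope over an explicit window
divided by $2n$ with $n=3$; the default window is the final tenth of the
curve, mirroring the practice of fitting the late, linear regime of a
production run, and a fit with R² < 0.9 warns that the window is not
diffusive.

The aggregation classifier tracks the per-frame minimum-image minimum
atom–atom separation between two core selections. The verdict is
`non-aggregated` when the separation exceeds the contact threshold
(default 10 Å) in more than 90 % of frames, `aggregated` when it stays at
or below it that often, and `transient-contact` otherwise. Threshold and
persistence are explicit configuration: a contact criterion is inherently
a judgment call, and the package keeps it visible rather than baked in.
The intersystem nonbonded energy is reported alongside when a scheme is
supplied.

# Synthetic generators: what they do and do not emulate

Every generator takes a seed and is byte-deterministic under it; ground
truth travels in a `truth` element consumed by tests, never by analyses.

* `generate_grafted_np()` builds a rigid core (central atom plus a
  Fibonacci-sphere surface shell) with freely-jointed bead chains
  anchored at quasi-uniform surface points, first bond radial. The FJC is
  chosen *because* it has closed-form statistics (⟨h²⟩ = N b²,
  ⟨h²⟩/⟨R_g²⟩ → 6): it validates estimators, not polymer physics. It has
  no excluded volume, so it cannot exhibit a real brush regime; brush
  scaling is tested on planted power-law profiles instead.
* `generate_water_bath()` packs neutral 3-site molecules (TIP3P-like
  charges) at a requested density with a minimum-distance rejection rule,
  an optional spherical cavity, and neutral Na⁺/Cl⁻ pairs from a
  molarity. It is a random packing, not an equilibrated liquid: right for
  density/RDF/charge-profile estimator tests, silent on hydrogen-bond
  networks or water structure. Passing tests on it shows the estimators
  are correct, not that real water would look like this.
* `generate_charged_shells()` places point charges on spheres and records
  the ideal-shell Coulomb superposition as the oracle for the
  electrokinetic chain.
* `generate_brownian()` draws per-step Gaussian displacements with
  per-dimension variance 2 D dt — the exact discrete realization of the
  diffusion the Einstein fit should recover.
* `generate_power_law_profile()` plants $\phi = A r^\alpha$ with optional
  multiplicative lognormal noise for the brush-fit oracle.

The molecule count of the bath is ⌊ρV⌋ (deterministic), and the ion-pair
count is the rounded molarity × volume, always added in neutral pairs.

# Numerical choices and degenerate inputs

Linear interpolation is used for every profile crossing (thickness
levels, bulk onset, ζ); crossings at a discontinuous step land within one
bin width of the step. Percent changes round half away from zero to
integers, and energy comparisons are made on magnitudes — the convention
that reproduces the published comparison arithmetic on the shipped
tables exactly (verified in the test suite). Degenerate inputs fail
loudly and specifically: atom-count mismatches name the offending frame,
unknown selection labels list the available ones, all-zero profiles
refuse normalization, zero reference values refuse percent changes,
overlapping core selections refuse the aggregation analysis.

# Problem sizes in the test suite

The suite runs in well under a minute on one CPU by choosing the smallest
sizes at which each closed form has decisive statistics: 2000 chain
samples for ⟨h²⟩ (3 standard errors ≈ 5 % of the mean), 600 samples of
N = 200 chains for the ⟨h²⟩/⟨R_g²⟩ ratio, 100 random geometries for the
hydrogen-bond oracle, 50 atoms for the O(N²) energy oracle, 400-point
shells for the 1 % electrokinetic closed forms, and 100 walkers × 10⁴
steps for the 10 % Brownian-diffusion recovery. The acceptance script
reuses the same sizes.

# Known limitations

Binary trajectory formats (XTC/DCD), triclinic cells, velocities,
Ewald/reciprocal-space electrostatics, bonded energies and force-field
typing are out of scope. The diffusion estimate applies no finite-size
periodic-boundary correction. Pair–pair g(r) between two mobile
selections is not provided — only center-referenced profiles. The
aggregation verdict is a geometric classification, not a free-energy
statement.
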