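---
title: "Methods: how nuctraj scores protein-nucleic acid recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how nuctraj scores protein-nucleic acid recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nuctraj analyses molecular-dynamics trajectories of protein-DNA/RNA
complexes to separate *sequence read-out* (direct side-chain-to-base
contacts) from *shape and electrostatic read-out* (contacts through either
backbone).  This vignette documents the models, conventions and numerical
choices behind each stage, and what the synthetic ground-truth generators
do and do not emulate.

Units are fixed package-wide: coordinates in Å, times in ps, energies in
kcal/mol, masses in amu, charges in elementary charges, temperatures in K.
Atom and residue indices are 1-based.

## Atom roles and the specific/nonspecific partition

Every atom is assigned one of four roles.  On nucleic residues, the
*backbone* is the phosphate plus the complete sugar — including O2′ and
HO2′ of ribonucleotides — and the *base* is the ring system with its
exocyclic substituents and hydrogens.  On protein residues, the *backbone*
is N, CA, C, O, their hydrogens (HA included, so glycine has an empty
heavy-atom side chain) and terminal OXT; everything else is *side chain*.

A contact is **specific** iff its protein atom is side-chain and its
nucleic atom is base; every contact that touches either backbone is
**nonspecific**.  Counting sugar atoms as backbone is a deliberate
convention: only nucleobase atoms can read sequence identity, so a
side-chain-to-sugar contact conveys shape, not sequence, information.

## Dynamic contact maps

Three contact types are detected per frame at the protein-nucleic
interface:

| type | criterion | default |
|---|---|---|
| hydrogen bond | donor-acceptor distance **and** donor-H-acceptor angle | ≤ 3.5 Å, ≥ 135° |
| salt bridge | cationic N (Arg NH1/NH2/NE, Lys NZ; His ND1/NE2 only if the `his_protonated` flag is set, default neutral) to any oxygen bonded to a phosphorus | ≤ 4.0 Å |
| apolar | carbon not covalently bonded to N/O, on both sides | ≤ 4.5 Å |

The thresholds are mainstream MD-analysis values and are all exposed in
`contact_criteria()`.  Donors and acceptors are typed from element and
bonding (N/O with an attached hydrogen donate; N/O accept); bonds come
from residue-local covalent-radius inference (`infer_bonds()`).  Systems
without explicit hydrogens therefore have no donors — `detect_hbonds()`
warns once when a system carries no hydrogens at all.

`build_dynamic_contact_map()` scores contacts the way dynamic contact maps
are conventionally reported:

1. the presence series of every atom-level event is computed over all
   analysed frames;
2. events present in no more than `persistence` (default 0.10) of the
   frames are dropped — the filter is evaluated *per atom-level event*,
   before residue-pair aggregation, and is strict (`occupancy >
   persistence`), so an event at exactly 9% is removed and one at 11% is
   kept;
3. for every (protein residue, nucleic residue, class) the per-frame
   strength is the number of surviving events simultaneously present,
   each contact type contributing exactly 1 regardless of chemistry;
4. the reported mean and SD are taken over **all** analysed frames, with
   absent frames contributing 0.  This makes the mean strength a
   well-defined expectation (an event present in 40% of frames has mean
   0.4 and SD √(0.4·0.6)); averaging only over frames-present would be
   inconsistent with SD bars on sparse contacts.

An atom pair that satisfies both the hydrogen-bond and the salt-bridge
criterion in a frame is counted once, as a salt bridge (the charge-charge
interaction dominates); the tie-break is fixed.  Because it is not
documented whether spread bars of this kind of map are frame-wise or
block-wise, both are reported (`sd` over frames, `sd_block` over five
contiguous block means).  Only intermolecular protein↔nucleic contacts
are computed.

## Interaction-energy decomposition

Short-range pairwise energies use the Coulomb term `ke·qi·qj/r` with
`ke = 332.0637` kcal·Å/(mol·e²) and the 12-6 Lennard-Jones form with
Lorentz-Berthelot combination — the Amber-style conventions.  Group-group
energies sum all cross pairs within a cutoff, fixed at 10.0 Å with plain
truncation (no switching, no long-range correction, no periodic imaging):
these group energies are qualitative trend indicators, not converged
electrostatics, and the analysis assumes whole molecules are imaged
together beforehand.

`decompose_interaction_energy()` evaluates three role-derived pairings per
frame — bases × protein side chains (*specific*), nucleic backbone × all
protein atoms, and protein backbone × bases (both *nonspecific*) — which
partition the full set of intermolecular atom pairs, so their sum is the
total short-range interface energy (verified algebraically in the tests).
Intramolecular exclusions never arise because the groups are strictly
intermolecular.

## Schlitter configurational entropy

The configurational entropy of a selection (canonically the backbone P
atoms) is estimated with Schlitter's upper bound,

$$ S = \tfrac{k_B}{2}\,\ln\det\!\left[\,\mathbf{1} +
   \frac{k_B T e^2}{\hbar^2}\,M^{1/2}\,\sigma\,M^{1/2}\right], $$

evaluated through the eigenvalues of the mass-weighted covariance
(in amu·Å²; the dimensionless prefactor $k_BTe^2/\hbar^2$ is ≈ 45.7 per
amu·Å² at 300 K) and reported as the product TS in kcal/mol at the
analysis temperature (default 300 K).

Rigid-body motion is removed before the covariance by superposing all
frames on their iteratively converged average over the same selection.
The estimator is silent on this point, but without the fit, centre-of-mass
diffusion inflates the covariance without bound and the entropy becomes
meaningless.  The fit also absorbs six degrees of freedom, so a fitted TS
is systematically below the TS of the unfitted generating covariance —
the tests assert exactly this ordering.  Mass-weighting uses true atomic
masses (nearly scalar for all-P selections, but kept general).

`windowed_entropy()` reports TS from the full analysed span and from
consecutive non-overlapping windows (production protocol: a 500 ns span
in five 100 ns windows).  The reported `sd` is the spread over window
estimates; since it is ambiguous whether such spreads conventionally
include the full-span value, `sd_incl_full` reports the other convention
too.  Differences between bound and unbound systems are formed as
differences of independent runs; no cross-system covariance is assumed.

## Essential-dynamics PCA

`pca_protocol(traj, fit_selection, analysis_selection)` superposes all
frames on the converged average over the fit selection, then
eigen-decomposes the positional covariance of the analysis selection.
The two production protocols are (1) fit on nucleic heavy atoms, analyse
the whole complex's heavy atoms; and (2) fit and analyse the nucleic
heavy atoms — the superposition is on the nucleic acids in both, and the
two coincide exactly when the system contains only nucleic atoms.
Heavy-atom filtering is the caller's job via selections, keeping the
machinery generic.  The covariance is *not* mass-weighted by default,
matching common essential-dynamics practice (a flag enables it).  Each
eigenvector's largest-magnitude component is made positive so reports are
reproducible.  `pca_project()` returns per-frame mode amplitudes (their
population variance equals the eigenvalue on the fitted frames);
`mode_animation()` renders mean ± scaled eigenvector frames for
multi-model PDB movies.

## Helical geometry

Base-pair and step parameters use the mid-step-frame (CEHS/3DNA-style)
construction, **not** a curvilinear-axis fit: each base gets a standard
reference frame by least-squares fitting the planar standard-base
geometry onto its observed ring atoms; complementary frames (strand II
flipped about x) are merged into pair frames; the rotation between
consecutive pair frames is split into a hinge bend (roll/tilt) plus a
twist about the mean normal, and translations (shift/slide/rise) are
expressed in the mid-frame.  The two families of conventions agree
closely on regular duplexes but not identically; re-implementing the
curvilinear-axis variant was deliberately left out of scope.
x-displacement comes from the local helical (screw) axis of each step:
the pair-origin offset from the axis, projected on the pair x-axis,
averaged over the flanking steps (undefined for near-zero step
rotations).

Groove widths are minimal cross-strand P-P distances minus a 5.8 Å
phosphate van-der-Waals correction, floored at 0 (El Hassan-Calladine
style).  For level *i* the candidate pairs are P1(*i*+a) vs P2(level
*i*+b) with strand offsets (a−b) of +3…+5 on the minor-groove side and
the mirrored window on the major side; the windows are a fixed package
convention calibrated on ideal B-form builds, and level indexing follows
the 5′ strand.  Depth is the distance from the width-defining P-P
midpoint to the level's pair origin projected on the pair x-axis.
Backbone torsions α…ζ and χ use the standard four-atom definitions with
circular means/SDs; angles whose atoms are missing (5′ termini without
phosphate) are NA.  Hairpin loops and bulges are excluded from helical
analysis; the pairing map is explicit user input, so only the fully
paired stem region is ever analysed.

## Synthetic ground truth

Three generators give every stage a known answer:

* **`build_ideal_duplex()`** composes pair frames through the *exact*
  transform the analysis inverts, then places standard-geometry
  nucleotides in each frame — so build → measure is an identity for the
  six step parameters (round trips hold to ~1e-13, asserted at 1e-6 over
  100 random draws within physical ranges: twist 20–45°, rise 2.5–4 Å,
  |roll|,|tilt| ≤ 15°, |shift|,|slide| ≤ 2 Å).  The sugar-phosphate
  geometry is an idealized internal-coordinate template calibrated once
  per form preset so the strand chains (O3′–P = 1.60 Å) with the
  phosphorus at a B-DNA-like 8.95 Å radius; it is a builder convention,
  not a fit to any experimental structure.  Presets: B_DNA twist 36.0°,
  rise 3.38 Å; A_RNA twist 32.7°, rise 2.81 Å, roll 8°, x-displacement
  −4 Å.  A nonzero x-displacement requires uniform parameters because the
  duplex is then built on an explicit helical axis, with (twist, roll,
  rise) matched exactly and shift/slide becoming derived quantities —
  x-displacement is not independent of the step parameters on a uniform
  helix, and this construction is the one self-consistent way to
  prescribe it.  Base (not sugar) hydrogens can be added by in-plane
  construction.
* **`make_probe_complex()`** plants single amino-acid probes (Ser, Lys,
  Val, Thr — real residue names, so classification, parameter loading and
  the detectors run unmodified) whose contact atoms satisfy each
  scheduled criterion with margin in "on" frames and violate it by ≥ 2 Å
  in "off" frames.  Probes extend along the target atom's bond direction
  (salt-bridge tails additionally tilt radially out of the helix), and a
  clash check rejects unrealisable placements, so scheduled occupancies
  are recovered *exactly*.
* **`gaussian_trajectory()`** samples frames from a prescribed 3N×3N
  covariance (full, diagonal, or rank-one spike on isotropic noise) about
  a reference, optionally with random rigid-body jitter to exercise the
  superposition machinery; a fixed seed gives byte-identical output.
  `rigid_orthogonal_mode()` draws planted modes orthogonal to the six
  rigid-body degrees of freedom so that spiked-covariance ground truth
  survives superposition.

The bundled parameter table is a minimal charge model (phosphate group
−1 e, Lys NZ +1 e, Arg NH1/NH2 +0.5 e each, all else neutral) with
element-wise Lennard-Jones parameters — sufficient to make energy
decompositions exactly predictable, not a force field.

**What passing tests show, and what they do not.**  The generators
produce rigid or Gaussian fluctuations, scripted (not thermodynamic)
contact kinetics, ideal Watson-Crick geometry and toy charges.  Green
tests therefore certify the *scoring machinery* — detection geometry,
persistence filtering, unit-strength accounting, energy summation, the
Schlitter estimator, frame conventions and round-trip consistency — under
controlled conditions.  They do not certify force-field realism,
convergence of real MD sampling, or the biological interpretation of any
map; real trajectories also contain anharmonic motions for which
Schlitter's Gaussian upper bound is only a bound.

## Problem sizes and runtime choices

The shipped test and acceptance workloads are sized for a single CPU:
contact maps on ~500-atom probe complexes over 1,000 frames; detector
oracle equivalence on ≤200-atom frames; energy oracles on ≤500-atom toys;
entropy convergence at 50,000 frames for 3–30 degrees of freedom
(sampled TS within 1% of the closed form); PCA planted-mode recovery at
20,000 frames; helical round trips over 100 random builds; and
end-to-end pipeline determinism on a 10-mer complex over 50 frames.  The
pipeline's helical stage subsamples frames (`helical_max_frames`, default
200) because base-frame fitting is the most expensive per-frame
operation.

## Known limitations

* PDB is the only bundled structure/trajectory format; binary MD formats
  can be converted upstream or read by wrapping an external reader behind
  `traj_ensemble()`.
* Water-mediated contacts, π-stacking and cation-π interactions are not
  scored; the map covers the three classical contact types only.
* Energies are gas-phase short-range group sums — no PME, no implicit or
  explicit solvation, no free energies.
* The helical module has no curvilinear global axis, bending
  decomposition, modality testing or BI/BII classification.
* Schlitter's estimate is an upper bound; no quasi-harmonic quantum
  corrections beyond it are applied.
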