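---
title: "Methods: coarse-grained ensemble simulation of TM2 helices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained ensemble simulation of TM2 helices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pistonsim)
```

This vignette is the package's own account of its models, parameters,
numerical choices and limitations. The pipeline has five stages: sequence →
ideal helix → coarse-grained system → ensemble MD (or synthetic frames) →
geometry and statistics.

## Sequences and fixtures

The shipped fixture set (`tm2_peptides()`) covers four mutant families of
chemoreceptor TM2 helices: the WY scan of the cytoplasmic aromatic anchor
pair (W209/Y210) of *E. coli* Tar, the Trp→Ala point mutants of the two
anchoring tryptophans (W192, W209), arginine-scanning mutants of
*S. typhimurium* Tar (F189R, W192R, W209R), and basic core mutants of
*E. coli* Trg (T215K, T215R, L216R). Kinase phenotype labels are
experimental metadata and are never computed from sequence.

The fixture sequences are **synthetic stand-ins**: ~30-residue hydrophobic
helices constructed once to satisfy every documented positional constraint
(the anchor residues above, full-protein numbering with W209 as the
wildtype WY tryptophan, basic residues at the cytoplasmic flank). They are
not database sequences, and the fixture file is named accordingly
(`tm2_helices_synthetic.fasta`). WY-scan mutants were generated by a block
swap — the WY pair moves by *k* positions and the displaced residues fill
the vacated sites — and are shipped as literal sequences together with a
substitution table, so `apply_mutations()` can regenerate each fixture from
its wildtype (a property the test suite checks exactly). Analyses of these
fixtures therefore probe the *mechanism* (anchor placement vs. helix
position), not the literal Tar sequence.

## Ideal helix construction

`build_ideal_helix()` places heavy atoms by internal coordinates with
(φ, ψ) = (−57°, −47°) and ω = 180°. The backbone valence angle N–Cα–C is
set to 110.0°, inside its physical range and chosen so the canonical helix
parameters — 1.50 ± 0.05 Å rise per residue and 3.6 ± 0.05 residues per
turn — are reproduced simultaneously with the textbook dihedrals (with the
more common tabulated 111.2° the rise comes out ≈ 1.56 Å). Sidechains use
one fixed common rotamer per residue type (χ1 gauche−, chains anti, rings
planar); the coarse-grained mapping uses group centroids, so rotamer detail
does not propagate downstream. The output is canonicalized (principal axis
= z, Cα centroid at origin, N-terminus toward +z), which fixes the sign
convention used everywhere: **positive z is the periplasmic direction**.

## Coarse-grained model

`map_to_cg()` follows the MARTINI philosophy: ~4 heavy atoms per bead, one
backbone bead (class N0 for helical backbone, atoms N/Cα/C/O) per residue
plus 0–4 sidechain beads at heavy-atom-group centroids; Arg/Lys carry a
charged Qd (+1) bead, Asp/Glu a Qa (−1) bead, and termini are uncharged.
The interaction table (`martini_forcefield()`) ships as data: 18 bead
subtypes, a symmetric matrix of 9 interaction levels with ε from 5.6 down
to 2.0 kJ/mol, σ = 4.7 Å (6.2 Å for the super-repulsive charged–apolar
level). The files are *MARTINI-style*, reconstructed from the published
descriptions of the 2.x forcefield; they are data, versioned with the
package, and cell-level fidelity to any specific release is not claimed.
Ring bead subtypes are folded onto the nearest regular subtype.

Nonbonded terms use the classic GROMACS force-shift form, so both the
potential and the force are continuous and exactly zero at the 12 Å
cutoff: Lennard-Jones shifted over 9–12 Å, Coulomb over 0–12 Å with
relative dielectric ε_r = 15. Bonded terms restrain the mapped ideal
geometry: harmonic bonds (12.5 kJ mol⁻¹ Å⁻²) between backbone neighbours
and all intra-residue bead pairs (which rigidifies multi-bead aromatic
sidechains without separate angle terms), cosine-harmonic angles over
backbone triples (100 kJ/mol), and harmonic wrapped dihedral restraints
over backbone quadruples. The dihedral constant (default
100 kJ mol⁻¹ rad⁻²) was calibrated so helicity (i,i+4 backbone spacing)
persists over nanoseconds at 323 K in a bilayer; no literature value is
asserted for it. DPPC is the standard 12-bead zwitterionic template (Q0
choline, Qa phosphate, 2×Na glycerol, 2×4 C1 tails); water is a single P4
bead representing four molecules.

## MD engine

Leapfrog integration with a Berendsen thermostat (reference 323 K,
τ_T = 1 ps, scaling λ = √(1 + (dt/τ_T)(T_ref/T − 1))) and a semi-isotropic
Berendsen barostat (1 bar, τ_P = 10 ps, compressibility 3×10⁻⁵ bar⁻¹)
coupling the lateral (x,y) and normal (z) box dimensions separately; the
barostat is applied every 10 steps with the coupling interval folded into
the scaling exponent, the standard practice for weak coupling. Neighbour
search is a cell list with a 2 Å skin rebuilt every 10 steps, verified in
the test suite against brute-force enumeration; exclusions cover directly
bonded pairs. Centre-of-mass momentum is removed every 100 steps. λ and μ
are clamped (0.8–1.25 and ±0.5 % per application) purely as a safeguard
against startup shocks. All hot loops are compiled C++ with an interleaved
coordinate layout; the same code path is exercised by every test, from the
two-bead cutoff check to the full bilayer.

The production protocol (`run_replica()`) is minimize → 2 fs equilibration
→ production. The reference timestep is 20 fs; for long stability runs the
package uses a further ramp to 40 fs, a standard rate for this class of
smooth coarse-grained potential, and the schedule is fully configurable.
Units are Å, ps, amu, kJ/mol, bar throughout; GRO files are written/read
in nm at the boundary.

Default system composition is 128 DPPC with ~3000 CG waters. The printed
source box of ~65×65×13 Å³ cannot hold that system (a DPPC bilayer alone
is ~40 Å thick); the package treats the z dimension as a typographical
slip and defaults to 65×65×100 Å. Desk-scale stability checks use a
thinner water slab (1000 CG waters ≈ 31 real waters per lipid, still fully
hydrated) so that a 5 ns check of the 128-lipid patch completes in minutes
rather than hours; the lipid patch itself is never scaled down.

## Geometry analysis

Per frame (`trajectory_geometry()`):

1. the bilayer is re-centred at z = 0 using the *circular* mean of the
   phosphate z distribution (coordinates are periodic in z);
2. the midplane z₀ is the midpoint of the two leaflet mean phosphate
   positions, leaflets assigned by sign about the phosphate median; frames
   whose leaflets are not separated by ≥ 10 Å are flagged as having no
   detectable bilayer and excluded;
3. helix beads are unwrapped *along the chain* (each bead to the image
   nearest its predecessor), which remains correct when the helix is longer
   than half the box;
4. shift = mean backbone-bead z − z₀ (all residues, not a central window —
   recorded so sensitivity can be tested); tilt = arccos of the z component
   of the backbone principal axis (SVD line fit, sign fixed C→N terminus),
   folded to [0°, 90°];
5. rotation = the signed angle, about the helix axis, from the projection
   of the lateral lean direction (the direction the helix tips toward) to
   the projection of the reference-residue sidechain vector. The reference
   residue defaults to the tryptophan of a WY pair (W209 in the wildtype)
   and is configurable. When tilt < 2° the lean direction is degenerate and
   the +x lab axis is used instead; when tilt > 85° the axis is nearly
   in-plane and rotation is flagged undefined. This definition is declared,
   not inferred from any source — rotation conventions differ between
   studies — and it is gauge-fixed: a rigid rotation of the whole frame
   about z leaves it unchanged (tested).

Transmembrane classification is inclusive: tilt ≤ 50°, terminal backbone
beads on opposite sides of the midplane, and |shift| ≤ 15 Å; otherwise the
frame is interfacial. Frames, not replicas, are excluded — a replica that
is mostly interfacial still contributes its transmembrane frames, and the
excluded count is reported.

## Ensemble statistics

`pool_geometry()` pools all transmembrane frames of all replicas into one
histogram (defaults: 0.25 Å shift bins, 1° tilt, 5° rotation) and reports
mean, mode and sd — both mean and mode because small reported differences
in the source literature do not specify the estimator; rotation uses
circular statistics throughout. `compare_to_wildtype()` reports
mutant-minus-wildtype differences with percentile bootstrap confidence
intervals resampling **replicas**, never frames: frames within a replica
are strongly autocorrelated, so a frame-level bootstrap would be
anti-conservative and is refused outright rather than merely discouraged.
Outputs are estimates with intervals, not hypothesis tests, so no
multiple-testing correction is applied. `phenotype_report()` assembles the
per-mutant table and a Spearman rank correlation between the phenotype
ordering (inactive < wildtype/mixed < active) and Δshift; with tied
phenotype ranks the attainable correlation is < 1 even for a perfect
ordering, so the monotonicity checks in the tests compare recovered against
imposed shifts directly.

## Synthetic data: what it does and does not show

`generate_ensemble()` produces frames containing exactly what the analysis
touches: a rigid ideal CG helix posed at sampled (shift, tilt, rotation)
plus isotropic per-bead Gaussian noise, and two phosphate leaflet grids.
Pose series are stationary AR(1) processes (shift and tilt Gaussian, tilt
clamped to [0°, 90°]; rotation exactly von Mises when uncorrelated,
otherwise a wrapped Gaussian AR(1) with matched spread 1/√κ). Ground truth
is returned next to the trajectories, and the generator writes the same
GRO frames as the engine, so synthetic and simulated data are
interchangeable downstream.

The phenotype suite imposes mean shifts {−1, −0.75, −0.5, 0, +0.5, +0.75,
+1} Å on the seven WY-scan peptides, chosen once so the active-minus-
inactive group contrast equals the 1.5 Å piston displacement; these are
test scaffolding for the statistics layer, not claims about per-mutant
values. Passing synthetic tests therefore demonstrates that the
measurement and statistics stack is correct and unbiased — it says nothing
about whether the forcefield reproduces real helix positioning, which only
the MD path at full ensemble scale (~100 replicas × 100 ns per sequence)
can address. Synthetic frames contain no lipid disorder, no water, no
helix flexibility and no interfacial kinetics.

## Numerical choices and degenerate inputs

* Force-shift constants follow the standard two-parameter polynomial; the
  finite-difference oracle in the tests holds every implemented gradient
  (nonbonded, bond, angle, dihedral) to < 10⁻⁴ relative error.
* Minimization is steepest descent with adaptive step; non-finite
  coordinates or energies abort with an informative error, and replica
  runners convert such aborts into recorded failures rather than losing
  the ensemble.
* Overlapping beads (r < 0.1 Å) are an error naming the pair; a too-small
  box (any edge ≤ 2 r_cut) is refused.
* Ties: transmembrane thresholds are inclusive (tilt = 50° is TM);
  rotation histograms bin [−180°, 180°); the circular mean of {+170°,
  −170°} is ±180°, not 0°.
* Determinism: a run is a pure function of (system, velocities,
  parameters); velocity generation is the only RNG consumer and takes an
  explicit seed. Replica seeds are derived as base + fixed offsets, and
  serial and forked-parallel ensembles produce identical trajectories.

## Problem sizes used by tests and the acceptance script

The routine suite validates physics at desk scale: a 216-bead fluid for
energy conservation (10⁵ steps at 2 fs) and thermostat relaxation, 10⁴
synthetic frames for estimator recovery, seven ensembles × 8 replicas for
the phenotype suite, a 20-lipid dispersion for aggregation dynamics, and
one 128-DPPC patch for 5 ns of barostatted production. The acceptance
script repeats the same computations (with a 1 ns bilayer run) from a
caller-supplied seed. The full published-scale experiment — ~100 replicas
of 100 ns per sequence across ~20 sequences — runs through exactly the
same `run_pipeline()` interface with larger `n_replicas`/`length_ns`.

## Known limitations

* Single helix only: helix–helix packing within the receptor TM bundle is
  out of scope, so mutants whose phenotype depends on bundle contacts
  (e.g. extreme rotations in Trg) can only be interpreted as single-helix
  positioning effects.
* The shipped interaction table is MARTINI-style, not a verbatim release;
  quantitative agreement with published per-mutant values additionally
  requires full ensemble scale.
* Berendsen coupling does not sample a rigorous NPT ensemble; it matches
  the simulated era's practice and is adequate for positional statistics.
* No long-range electrostatics beyond the shifted 12 Å Coulomb; no
  polarizable water; no XTC/TRR trajectories (GRO frame sequences only).
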