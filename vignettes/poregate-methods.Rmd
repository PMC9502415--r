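---
title: "Collective variables, ground-truth generators and design choices in poregate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective variables, ground-truth generators and design choices in poregate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
```

## The scientific problem

G protein-gated inwardly rectifying potassium (GIRK/Kir3) channels gate
potassium flux through two constrictions arranged in series along the pore:
the transmembrane helix-bundle-crossing (HBC) gate, formed by four
pore-lining phenylalanines (GIRK1 F181, GIRK2 F192), and the cytosolic
G-loop gate, formed by girdle methionines (GIRK2 M313/M319). Channel opening
couples PIP2 binding at a lysine-rich site, bending of the inner
transmembrane helix (TM2) about a conserved hinge glycine sitting exactly
twelve residues below the HBC phenylalanine, movement of the interfacial
slide helix relative to TM1, and allosteric communication from the
ligand-binding site down to the cytosolic gate. `poregate` implements the
trajectory observables that quantify each of these couplings, together with
synthetic-trajectory generators whose ground truth is exact, so that every
analysis stage can be validated end to end without molecular-dynamics data.

## Gate geometry and occlusion

A gate is measured as the per-frame minimum, over the two diagonal subunit
pairs (first-third and second-fourth chain in pore order), of the minimum
sidechain heavy-atom distance between the paired gate residues. Diagonal
pairing is the natural reading of a pore *diameter*; the alternative
(adjacent pairing) would measure the side of the square rather than its
diagonal and systematically underestimate the open lumen. Hydrogens are
excluded because the occlusion criterion is quoted for heavy-atom centers.
A frame counts as open when the gate distance is at least 5.7 Å, the
minimal diameter that still passes a partially solvated potassium ion;
`classify_occlusion()` reports the open fraction over a window.

Distances use the minimum-image convention on the per-frame orthorhombic
box whenever the trajectory carries one; fixture trajectories without a box
line disable imaging, which keeps hand-built geometric tests exact.

## Conduction counting

A conduction event is one ion traversing both gate planes in sequence. Each
ion runs a three-state machine on its unwrapped z coordinate: ABOVE
(`z > z_HBC + δ`), IN_PORE (between the planes, within `pore_radius` of the
pore axis), BELOW (`z < z_Gloop − δ`). Completing ABOVE → IN_PORE → BELOW
emits one inward event; returning ABOVE or leaving the pore cylinder
laterally resets the machine. The hysteresis δ (default 2 Å) suppresses
double-counting from thermal recrossings at a plane; the default is larger
than per-frame thermal jitter but well below the ≥ 5 Å inter-gate spacing.
`pore_radius` defaults to 10 Å. Both are configuration-exposed. We read the
traversal criterion as plane crossings with hysteresis rather than strict
passage through each residue ring; the ring-ordering reading would require
per-subunit contact bookkeeping the downstream statistics never use.

Gate planes may be static numbers (synthetic fixtures) or derived per frame
from the z centroid of the gate residues' Cα atoms
(`gate_planes_from_spec()`), which tracks channel drift in membrane
simulations.

## The synthetic pore and its calibration

`simulate_pore_trajectory()` is an overdamped Euler walk,
`Δz = μ·E·dt + noise`, with geometric gate blocking: an ion may cross a
gate plane only while that gate's radius is at least 2 Å, otherwise it
reflects. Blocking is geometric rather than energetic because ground truth
must be unambiguous — a Boltzmann barrier would make "blocked" a matter of
probability. The mobility constant μ = 25 Å·nm/(V·ns) with dt = 0.1 ns was
chosen once so that the physiological −0.06 V/nm field drifts ions
0.15 Å/frame, giving at least one traversal per 1000 frames through an
open 5 Å pore; it is frozen as a named constant.

Two constructions make the logged ground truth exact for any detector
hysteresis up to 2 Å. First, once an ion passes below the lower plane it
descends monotonically until it overshoots by 3.2 Å, is logged, and
respawns above the upper gate — no ion ever lingers ambiguously inside a
hysteresis band. Second, in the last dozen frames the lower plane reflects
even when open, so a run never ends with a half-completed traversal that
the detector would count but the ground truth would not.

The field unit deserves a note: the same external field is quoted in the
literature both as −0.06 kcal/(mol·Å·e) and as −0.06 V/nm, and these are
not numerically interconvertible as printed. The package adopts V/nm
throughout, because it is the unit under which the standard worked example
holds exactly: `field_to_voltage(0.06, 35)` = 0.06 V/nm × 3.5 nm = 210 mV,
a physiological transmembrane potential.

## Salt bridges and normalized formation

A basic atom (lysine NZ by default) is engaged in a frame iff its minimum
distance to any acceptor atom (PIP2 phosphate atoms O11–O16, P2, P3) is
within 4.0 Å. The source analyses state only that a "default" salt-bridge
cutoff was used; 4.0 Å is the standard heavy-atom criterion and the value
is configuration-exposed. *Normalized* salt-bridge formation is defined
here as the mean per-frame engaged count divided by the number of candidate
lysines. The literature leaves the normalization unspecified; this choice
bounds the quantity in [0, 1], makes a condition's fold change against a
reference well-defined, and reproduces the reported regime — engagement
probabilities of 0.6 and 0.4 against a 0.5 reference recover 1.2× and 0.8×
fold changes to within binomial sampling error
(`simulate_bridge_engagement()` places engaged pairs at 3.5 Å and
disengaged pairs at 6.0 Å, so the coordinates reproduce the Bernoulli table
exactly under the cutoff).

Inter-segment contact totals (e.g. TM1 versus TM2) count unordered
heavy-atom pairs within 4.0 Å per frame; no cutoff is stated for that
total in the source analyses, so the salt-bridge default is reused and
exposed. Typed residue-pair distances use one rule per class: pi-stacking
is ring-centroid to ring-centroid (the six-membered ring for Phe/Tyr/Trp,
the imidazole for His — one unambiguous centroid per residue) with a 4.0 Å
cutoff; Van der Waals packing is the minimum sidechain heavy-atom distance
with a 3.0 Å cutoff, i.e. twice the smallest heavy-atom VdW radius
(1.5 Å); charge-dipole hydrogen bonds and charge-charge interactions use
the minimum polar sidechain heavy-atom (N*/O*) distance with 4.0 Å.
Whether the source figures measured atom-minimum or centroid distances per
panel is not stated; one rule per class is the uniform reading, and the
class table is exposed via `interaction_classes()`. Histograms default to
0.25 Å bins over 0–12 Å.

## Helix bend and axis angles

The TM2 bend is the angle at the centroid of the pivot segment (GIRK1
I167–G169) between vectors to the centroid of one helical turn above
(G158–F162) and one below (A174–G178); 180° is straight. Centroids are
unweighted backbone-atom (N, CA, C, O) centroids: mass weighting changes
the result negligibly for four atoms of similar mass, and the source
describes backbone centers of mass without specifying weights; a
mass-weighted mode is available by flag.

The TM1/slide-helix angle takes each segment's axis as the principal
direction (largest-variance singular vector) of its backbone atoms,
oriented N→C so angles are comparable across frames, folded to [0, 180).
The principal-direction reading is one of several consistent with "vectors
parallel with the axis"; a first-to-last endpoint mode is provided as the
alternative. For ideal helices of ≥ 10 residues the two agree to a small
fraction of a degree.

`simulate_bent_helix()` builds an ideal α-helix by internal-coordinate
chain extension at φ = −57°, ψ = −47° (which yields the canonical ~1.5 Å
rise and ~100° twist per residue) and then rotates the C-terminal arm
rigidly about the pivot centroid, in the plane spanned by the outer and
inner centroid vectors, by exactly the angle that makes the measured
centroid bend equal the programmed value. Because the generator calibrates
against the same centroid definition the analysis uses, noise-free recovery
is exact to machine precision for any programmed bend in (0°, 180°] — an
intentional property: a ground-truth generator whose truth is only
approximate cannot distinguish analysis bugs from construction error.
Per-frame isotropic Gaussian noise (σ in Å) is added afterwards; at
σ = 0.3 Å the mean recovered bend stays within 2° and the 165° < 170° <
177° ordering of activator/apo/inhibitor-like conditions is preserved.

Backbone φ/ψ follow the standard definitions (C(i−1)–N–CA–C and
N–CA–C–N(i+1)), validated against an independent torsion implementation.
Note that dihedrals are noise-sensitive: 0.05 Å coordinate jitter already
moves individual φ values by ~10–20°, which is why dihedral-shift flagging
(threshold 20°, circular difference against the first frame) should be
applied to windowed series, not single frames. Ramachandran classification
uses fixed rectangles — favored α (φ ∈ [−100, −30], ψ ∈ [−67, −7]) and β
(φ ∈ [−180, −100], ψ ∈ [90, 180]), allowed = each box dilated by 20° plus
the left-handed box (φ ∈ [40, 80], ψ ∈ [20, 80]) — because the regions are
named but not bounded in the source; a fixed, documented rectangle set
makes the classifier deterministic and testable. The β box wraps through
ψ = 180°.

## Correlation networks and suboptimal paths

The dynamic cross-correlation matrix is
`cij = <Δri·Δrj> / sqrt(<|Δri|²><|Δrj|²>)` on Cα deviations from the
time-mean position, conventionally over the last 150 ns. By default the Cα
set is superposed onto its running mean by iterative least-squares fitting
first; whether the original toolchain correlated superposed or raw
coordinates is not stated, and superposed is the default reading because
rigid-body tumbling otherwise masquerades as coupling (a test demonstrates
exactly this). Generators that program correlations place displacements in
a shared frame, so their recovery tests run with superposition off.

The residue network keeps edges where `|cij| ≥ 0.4` with edge length
`−log|cij|` — the standard correlation-to-distance transform, making
perfectly coupled pairs zero-cost. Absolute correlation is used so that
anticorrelation counts as coupling; a flag restricts to positive
correlations. Suboptimal paths are the k (default 250) lowest-total-weight
distinct simple paths by Yen's algorithm with lexicographic tie-breaking,
so ensembles are deterministic and verifiable against exhaustive
enumeration; the per-edge usage table (`edge_usage()`) is the spline
weighting used for visualization in external viewers. Community detection
is deliberately not implemented: the analyses this package reproduces did
not use it.

## Replicate statistics

Gate-distance series are summarized over the last 5 ns of each replicate.
The default summary is one mean per replicate, avoiding frame-level
pseudo-replication (frames within a replicate are strongly autocorrelated,
so pooling them inflates the effective sample size); pooled-frames mode is
available for comparison. One-way ANOVA is the classical fixed-effects F
via `stats::aov`. Replicate sizing uses the two-sample normal
approximation `n = ⌈2((z_{1−α/2}+z_power)·σ/δ)²⌉`, floored at 2, with an
optional iterated t refinement; the effect sizes behind any particular
published replicate count are not printed, so the function is validated
against its own closed form (δ = σ at α = 0.05, power 0.8 → 16; power
0.9 → 22). When several gates or conditions are tested in one pipeline
run, Bonferroni correction of the reported p-values is the conservative
default.

## What the generators do and do not emulate

The synthetic pore reproduces the *statistical structure* the analyses
assume — drift under a constant field, gate blocking, four-fold gate
geometry, programmed correlations and engagement probabilities — but none
of the physics: no solvent, no lipids, no electrostatics beyond the
constant field, no knock-on permeation, no force field. Passing tests
therefore demonstrate that the estimators recover known truth under the
assumed data model, not that the biological conclusions hold for any
particular MD data set. Headline MD observables from production-scale
simulations (hundreds of ns, ~10^5 atoms) are not recomputable at desk
scale; the package's checks run on thousands of frames and tens of
residues (2000-frame pore runs, 200-frame helix ensembles, 5000-frame
correlation walks), sizes chosen to keep Monte-Carlo error comfortably
inside the stated tolerances.

## Numerical choices and degenerate inputs

* Coordinates are Å, times ns, angles degrees; z is the membrane normal
  with the extracellular side at +z, so inward conduction moves from
  positive to negative z.
* Residue numbering is 1-based canonical UniProt numbering per subunit;
  chains carry no renumbering offsets. The subunit arrangement around the
  pore is user-supplied (alternating by default), since the chain ↔
  subunit convention is not fixed by the structures alone.
* Windows are half-open `[start, end)`; the last-N-ns presets anchor at
  the final frame time plus an epsilon so the final frame is included.
* Selections resolve to sorted unique atom indices, so identical
  expressions always give identical, order-stable results.
* Degenerate inputs fail loudly rather than silently: glycine-like gate
  residues with no sidechain heavy atoms, zero-variance residues in a
  DCCM, collinear-deficient axis segments, terminal residues for
  dihedrals, disconnected source/sink pairs, and zero references for fold
  changes all raise named errors.
* All generator randomness flows through an isolated seeded stream
  (`withr::with_seed`), leaving the caller's RNG untouched; identical
  specs give bit-identical output.

## A worked example

```{r example}
sim <- simulate_pore_trajectory(pore_spec(n_ions = 20, n_frames = 2000,
                                          field = -0.06, seed = 7))
ions <- resolve_selection(sim$trajectory$topology, expression = "chain:I")
res <- count_conductions(sim$trajectory, ions, gate_planes = c(7.5, -7.5))
c(detected = res$count, truth = nrow(sim$truth$traversal_events))

gs <- gate_spec("HBC", sim$trajectory$topology, sim$assignment)
classify_occlusion(gate_min_distance(sim$trajectory, gs))

field_to_voltage(0.06, 35)
```

## Known limitations

XTC trajectories are not readable (no installed R reader); convert to DCD
or the documented plain-text fixture format. The conduction detector
assumes an approximately membrane-normal pore axis; tilted pores should be
aligned first. Yen's algorithm is exact but not asymptotically optimal;
for networks beyond a few hundred nodes with large k, expect minutes
rather than seconds. The normalized salt-bridge definition is one of
several defensible readings (see above); fold changes are insensitive to
the choice as long as the same normalization is applied to both condition
and reference.
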