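---
title: "Methods: structural and thermodynamic analysis of cohesin-dockerin complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural and thermodynamic analysis of cohesin-dockerin complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohdock)
```

# Scope

Cellulosomes are assembled by dockerin modules (Doc) on the enzymes binding
cohesin modules (Coh) on non-catalytic scaffoldins. A dockerin is a tandem
duplication: two calcium-binding loops, each followed by an α-helix. When
the duplication conserves the cohesin-contacting residues, the module can
bind its cohesin in two orientations related by a ~180° rotation (the
*dual-binding mode*); when the symmetry-related positions carry chemically
incompatible residues, only one face is functional (*single-binding mode*).
`cohdock` implements the analysis chain that discriminates the two:
structure reading, superposition and rmsd, secondary structure, interface
contact typing, calcium-site classification, the internal two-fold test,
and 1:1 isothermal titration calorimetry (ITC) simulation and fitting.

All structure-facing functions take and return tidy atom tables (one row
per atom, author residue numbering) so results compose with dplyr verbs.

# Rigid-body superposition

`kabsch_superpose()` computes the least-squares proper rotation by singular
value decomposition of the 3×3 covariance of the centred point sets, with
the determinant sign corrected so reflections are never returned. Chains
are paired by `superpose_chains()`: a global sequence alignment (identity
scoring, affine gap penalties of 10/0.5 via Biostrings) fixes the residue
correspondence, and only mutually present atoms of the chosen set (Cα, or
N/CA/C/O) are fitted. We deliberately use alignment-guided single-pass
pairing rather than iterative structural alignment with outlier rejection:
the chains compared here are homologous, and a fixed pairing makes every
reported rmsd reproducible from the sequences alone. Published
"main-chain carbon" rmsds are evaluated on Cα atoms, since the printed
atom counts are close to the chain residue counts.

The test suite checks the implementation against an independent
quaternion-eigenvalue oracle (largest eigenvalue of the 4×4 key matrix)
on a thousand random point sets at 1e-9, plus rigid-motion invariance and
the guarantee that superposition never increases the deviation.

# Secondary structure

`assign_secondary_structure()` is a minimal main-chain hydrogen-bond
assigner in the Kabsch–Sander style. Amide hydrogens are reconstructed
from the preceding carbonyl (H = N + unit(C−O)); bond energy uses the
electrostatic model `E = 0.084 · 332 · (1/rON + 1/rCH − 1/rOH − 1/rCN)`
kcal/mol with a −0.5 kcal/mol threshold. Helices come from pairs of
consecutive i→i+4 turns; strands from the standard parallel/antiparallel
bridge patterns, with a minimum strand length of 2 and sheets formed by
transitive bridge pairing. Strand indices follow sequence order from 1, so
sheet compositions can be compared directly with published strand
numbering; `sheet_topology()` orders each sheet by walking the strand
adjacency graph from a terminal strand (the orientation of the walk is
arbitrary, so comparisons should accept a reversed order). Turns, bridge
sub-classes and solvent accessibility are intentionally out of scope.
Residues with incomplete backbones are labelled coil and reported in a
warning rather than failing the chain.

# Interface contacts

Because crystal structures carry no hydrogens, all contact criteria are
heavy-atom criteria:

* **Hydrogen bond** — donor and acceptor heavy atoms on different chains
  within 3.5 Å, and at least one covalent antecedent of the donor making
  an antecedent–donor–acceptor angle ≥ 90°. Donor/acceptor capacity comes
  from a fixed per-residue table; His ND1/NE2 and the Ser/Thr/Tyr
  hydroxyls act as both donor and acceptor.
* **Salt bridge** — both atoms formally charged (Lys/Arg N⁺ vs Asp/Glu
  O⁻) within 4.0 Å; tagged as a sub-classification of the polar contact,
  never double-counted.
* **Hydrophobic contact** — apolar carbons (aliphatic/aromatic carbons not
  bonded to N/O, fixed table) within 4.5 Å, reported per residue pair
  with the minimum atomic distance; the atom-level list is kept as an
  attribute.

These defaults are in the same family as the PISA-style criteria used to
produce published contact tables; small count differences at borderline
distances are expected where the original criteria are unpublished.
Duplicated atom pairs are collapsed, so counts are over unique pairs.
`interface_report()` tags every contact `H1`, `H3` or `other` by the
dockerin residue's helix membership, mirroring the published table layout
(`write_contacts_tsv()` emits that shape).

# Calcium sites

`detect_calcium_sites()` collects, for each Ca²⁺ ion of the chain, the
protein O/N atoms of that chain and water oxygens within 3.0 Å — a
deliberately generous cutoff around the typical 2.2–2.6 Å Ca–O distance,
chosen because no cutoff is stated alongside the published coordination
patterns. Residues contributing only main-chain oxygens still count.
Classification is on the *offset pattern*: auth-number offsets of the
coordinating residues from the first one. Offsets {0, 2, 4, 11} with at
least one water are the canonical EF-hand-like dockerin arrangement;
{0, 6, 12} plus water is the atypical arrangement of the second repeat;
anything else — including extra coordinating residues — is `other`.
Matching is exact-set so that a noisy site never silently passes. Sites
are ordered by their first coordinating residue, which is how "the
N-terminal repeat site" is identified.

# Repeat segmentation and the two-fold test

`segment_repeats()` anchors repeat *k* at calcium site *k*'s first
coordinating residue and extends it through the longest helix following
that anchor. Two boundary decisions were genuinely open and are resolved
as follows:

* **Common window length.** Both repeats get the same window length (the
  larger of the two anchor-to-helix-end spans, clamped to the chain).
  Otherwise a helix end under-called by a residue or two in one repeat
  leaves tail positions without symmetry mates, and an unpaired contact
  position would count against the dual verdict for a purely
  bookkeeping reason.
* **Pooled helix boundaries.** Helix-1 and helix-3 boundary calls are
  pooled across the repeats (helix-3 mapped back by the anchor shift,
  union taken). The repeats are structurally equivalent, so a boundary
  missed in one repeat is recovered from the other; this makes the set of
  "key" contact positions stable under coordinate noise.

With other than exactly two calcium sites the segmentation falls back to a
sequence-midpoint split flagged `low_confidence`.

`internal_symmetry_superpose()` superposes repeat 2's main chain onto
repeat 1 with the alignment-guided fit; the resulting transform is the
molecule's internal two-fold, and its rotation angle (from the trace of
the rotation) is ~180° for a true tandem duplicate.
`build_rotated_model()` applies that transform to the whole chain — the
"rotated by 180°" model used to compare the two candidate binding faces.

`map_symmetry_mates()` reads the mate of each repeat-1 position off the
superposition pairing and classifies the pair with the residue class
table: identical → `conserved`; same class → `compatible`; otherwise
`incompatible`. The classes (nonpolar A V L I M F W C P; polar
S T N Q Y H G; positive K R; negative D E) stand in for qualitative
published compatibility judgments; glycine sits with the polar class as
small/flexible, and the whole table is a function argument because
borderline cases (e.g. Ala vs Ser) are not adjudicated by any reference.

`assess_dual_binding()` takes the contact positions (dockerin residues
with ≥1 polar or hydrophobic contact), restricts to those inside helix-1
or helix-3 (loop contacts are reported but do not drive the verdict,
since the interface reasoning is helix-based), and returns `dual` only if
every key position maps to a conserved/compatible mate, `single` if any
maps incompatibly, `indeterminate` for an empty interface. An unpaired
key position counts as incompatible. `sequence_fingerprint()` performs the
sequence-only version of the test: positions 11 and 15 of the reference
frame (frame position 1 = auth 29) must both be nonpolar.

# ITC: single-site model and fit

`model_heats()` implements the 1:1 (Wiseman) isotherm. After injection
*i* the totals follow the perfusion dilution convention — each injection
of volume *dv* scales the cell contents by (1 − dv/V₀) and adds titrant
at (dv/V₀)·[syringe] — chosen over the exponential convention and
switchable by editing the dilution series in one place. The bound
concentration is the smaller root of `Ka(nMt − B)(Lt − B) = B`, the
cumulative heat is `Q = B·ΔH·V₀`, and per-injection heats carry the
displaced-volume correction
`q_i = Q_i − Q_{i−1} + (dv/V₀)(Q_i + Q_{i−1})/2 + q₀`.
A bisection solver reimplementing the equilibrium independently serves as
the oracle in the tests (agreement to 1e-6 relative).

`fit_single_site()` fits (n, log Ka, ΔH, q₀) by Levenberg–Marquardt
(minpack.lm); Ka is fitted on the log scale to enforce positivity and
condition the optimisation. Starting values are data-driven: n = 1, ΔH
from the largest-magnitude heat scaled by the moles injected, q₀ from the
tail heats, and Ka from the width of the steepest part of the isotherm.
First-injection exclusion exists but is off by default. ΔG = −RT ln Ka
(R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, default T = 308 K) and TΔS = ΔH − ΔG are
derived, never fitted, so the identity ΔG = ΔH − TΔS holds exactly for
every fit. A Wiseman c-value above 10⁴ sets an ill-conditioning flag.

Simulated experiments default to the published schedule — 28 successive
10 µL injections at 220 s intervals, 308 K — with the cell concentration
chosen so c = n·Ka·[cell] ≈ 100 and the syringe 15× the cell, a standard
well-conditioned design adopted because the experimental concentrations
are not printed. Heat noise is i.i.d. Gaussian; "1% noise" means 1% of
the maximum model heat. At that noise the fitted Ka of a c ≈ 100 design
has a sampling spread of a few percent (the fit's reported standard error
agrees with the replicate spread), which bounds how tightly a single
simulated experiment can pin Ka — relevant when comparing recovered
values against published uncertainty bands that reflect much quieter
instruments.

# Synthetic fixtures

`make_symmetric_dockerin()` builds repeat 1 from internal coordinates
(NeRF with standard bond lengths/angles; loop at φ = −120°, ψ = +120°,
helix at φ = −57°, ψ = −47°), pins the calcium site (ligand oxygens on
distinct octahedral vertices 2.4 Å from the ion, one water, offsets
{0, 2, 4, 11}), and generates repeat 2 by an exact 180° rotation about an
axis perpendicular to helix-1 — so internal rmsd 0 and rotation angle
180° hold by construction. The default frame mirrors the reference
dockerin: repeat 1 spans auth 28–55 with the helix at 39–55 and the
diagnostic nonpolar positions at 39 and 43. `make_asymmetric_dockerin()`
then rewrites chosen repeat-2 mates (e.g. the mate of 43 to Gln) with
idealized side chains. `make_cohesin_plateau()` adds a two-strand
leucine ribbon 10 Å from helix-1 with side chains pinned 4.0 Å from the
designated contact atoms, plus an optional planted Ser-OG/His-ND1 pair at
exactly 2.9 Å. Generator knobs: `rotation_axis_jitter` (degrees),
`coordinate_jitter` (Å of Gaussian noise, applied after the clash check),
`seed`. Self-clashes beyond 1.5 Å tolerance abort generation.

What the fixtures emulate: the loop+helix repeat architecture, canonical
calcium coordination offsets, an apolar contact plateau, and exact or
degraded internal symmetry. What they do not: real side-chain rotamers
(side chains beyond Cβ are schematic), a physical inter-repeat linker
(left as a numbering gap), crystallographic waters beyond the ion sites,
or any energetics. Passing the fixture grid therefore demonstrates that
the *logic* — segmentation, mate mapping, class calls, verdicts — is
correct and noise-stable; it does not validate the geometric criteria
against experimental coordinates, which is what the download-dependent
checks on the deposited entries are for.

# Problem sizes and determinism

The test suite runs entirely from generated data: dockerins of 2×28
residues, plateaus of 16–17 residues, titrations of 10–28 injections,
oracle comparisons on 100–1000 random instances, and 50-replicate
recovery studies — sizes chosen so the full suite completes in about two
minutes while leaving the statistical assertions well-powered. Every
stochastic step (simulation noise, jitter, random point sets) flows from
explicit seeds; reports carry the configuration snapshot used.

# Known limitations

* Interface criteria are fixed-table heuristics; unusual protonation
  states, metal-mediated bridges and aromatic interactions are not
  modelled.
* The secondary-structure assigner covers helix/strand/coil only, and its
  strand calls near chain termini are conservative.
* Deposited-structure comparisons require the entries to be fetched (or
  supplied locally); nothing is bundled.
* The compatibility class table is a coarse stand-in for side-chain
  packing; the `single` verdict rests on class boundaries, not on
  modelled sterics.
* Only the 1:1 binding model is implemented — no multi-site, competitive
  or global fitting, and no raw thermogram integration.
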