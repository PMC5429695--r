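# cohdock

Structural and thermodynamic analysis of cohesin–dockerin complexes.

Cellulosomes — the multi-enzyme machines anaerobic microbes use to
degrade plant cell walls — are held together by dockerin modules (Doc) on
the enzymes binding cohesin modules (Coh) on scaffoldin proteins. A
dockerin is a tandem duplication of a calcium-binding loop plus an
α-helix; if the duplication conserves the cohesin-contacting residues the
module can bind in two orientations related by a ~180° rotation (the
*dual-binding mode*), otherwise it presents a *single* binding face.
`cohdock` is for structural biologists who want to run that
classification, and the surrounding measurements, as a reproducible
pipeline rather than a by-hand inspection:

* **Structures as tidy tables** — `read_structure()` / `write_structure()`
  parse PDB/mmCIF into one-row-per-atom tibbles (author numbering,
  hetero atoms kept, highest-occupancy altlocs), so everything composes
  with dplyr.
* **Superposition** — `kabsch_superpose()` (SVD Kabsch, reflections
  excluded) and `superpose_chains()` (alignment-guided residue pairing)
  report rmsd = √(Σ‖Rpᵢ+t − qᵢ‖²/n) over Cα or main-chain atoms.
* **Secondary structure** — a Kabsch–Sander-style main-chain H-bond
  assigner (`assign_secondary_structure()`, energy cutoff −0.5 kcal/mol)
  with strand/sheet topology (`sheet_topology()`).
* **Interface contacts** — `detect_polar_contacts()` (3.5 Å + antecedent
  angle ≥ 90°, salt bridges ≤ 4.0 Å), `detect_hydrophobic_contacts()`
  (apolar C–C ≤ 4.5 Å), and `interface_report()` grouped by dockerin
  helix (H1/H3).
* **Calcium sites** — `detect_calcium_sites()` plus
  `classify_coordination_pattern()`: offsets {0, 2, 4, 11} + water =
  canonical EF-hand-like; {0, 6, 12} + water = atypical.
* **The two-fold symmetry test** — `segment_repeats()`,
  `internal_symmetry_superpose()`, `build_rotated_model()`,
  `map_symmetry_mates()` and `assess_dual_binding()` decide
  dual vs single binding mode from the conservation of symmetry-related
  contact positions; `sequence_fingerprint()` is the sequence-only check
  on frame positions #11/#15.
* **ITC** — the 1:1 (Wiseman) model: `model_heats()`,
  `simulate_titration()`, `fit_single_site()` (Levenberg–Marquardt on
  n, log Ka, ΔH, q₀), with ΔG = −RT ln Ka and TΔS = ΔH − ΔG derived
  exactly; `tidy()`, `glance()` and `autoplot()` methods included.
* **Synthetic fixtures** — `make_symmetric_dockerin()`,
  `make_asymmetric_dockerin()`, `make_cohesin_plateau()` and
  `make_itc_dataset()` generate idealized test systems with tunable
  internal symmetry, so the whole pipeline is testable offline.

See the methods vignette (`vignettes/cohesin-dockerin-methods.Rmd`) for
the models, criteria and design decisions.

## Worked example

Classify a synthetic dockerin–cohesin complex:

```r
library(cohdock)

cplx <- make_cohesin_plateau(make_symmetric_dockerin())
report <- analyze_complex(cplx, doc_chain = "D", coh_chain = "C")
report
#> Cohesin-dockerin complex analysis
#>   dockerin chain D, cohesin chain C
#>   calcium sites: 2 (canonical, canonical)
#>   contacts: hbond=1 salt_bridge=0 hydrophobic=8
#>   binding-mode verdict: dual
report$symmetry
#> Internal two-fold symmetry report
#>   internal rmsd: 0.00 A, rotation angle: 180.0 deg
#>   key contact positions: 39, 42, 43, 46, 49, 50, 52, 53
#>   contact conservation: 1
#>   verdict: dual
```

The dockerin's two repeats superpose onto each other with rmsd ≈ 0 under
a 180° rotation and every cohesin-contacting helix position maps to a
conserved mate, so the module would present two equivalent binding faces
(*dual*). Substituting the symmetry mate of contact position 43 with a
polar residue flips the verdict:

```r
asym <- make_asymmetric_dockerin(
  dockerin_spec(substitutions = list(list(43, "Q"))))
analyze_complex(make_cohesin_plateau(asym), "D", "C")$verdict
#> [1] "single"
```

Simulate and fit an ITC experiment at a published wild-type parameter set
(Ka = 1.18×10⁸ M⁻¹, ΔH = −50.68 kcal/mol, 28 × 10 µL injections, c ≈ 100,
1% heat noise):

```r
pars <- thermo_params(n = 1, Ka = 1.18e8, dH = -50.68)
prot <- itc_protocol(Ka = 1.18e8)
noise <- 0.01 * max(abs(model_heats(prot, pars)))
fit <- fit_single_site(simulate_titration(prot, pars, noise, seed = 1))
fit
#> Single-site ITC fit
#>   N    : 0.998 +/- 0.003 sites
#>   Ka   : 1.168e+08 +/- 7.19e+06 M-1
#>   dG   : -11.37 kcal/mol
#>   dH   : -50.69 +/- 0.30 kcal/mol
#>   TdS  : -39.32 kcal/mol  (T = 308 K)
#>   rms residual: 0.059 ucal over 28 injections
```

The fit recovers the generating stoichiometry and association constant;
`autoplot(fit)` draws the binding isotherm with the fitted curve.

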