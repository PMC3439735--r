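---
title: "Predicting fragment-ion intensities from protonation-isomer thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fragment-ion intensities from protonation-isomer thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boltzms)
```

## The model

A doubly charged tryptic peptide carries one proton sequestered on the
basic side chain of its C-terminal Lys/Arg and one mobile proton that
relocates among backbone sites: the N-terminal amine (position 1) and
the amide bonds (positions 2..n, counted N to C), each of which can be
protonated at the amide oxygen or the amide nitrogen. Each placement
defines a protonation isomer (`<SEQ>_NH_<k>` for the nitrogen series,
`<SEQ>_C-OH_<k>` for oxygen), and each isomer is realised by many
conformers.

The working hypothesis is thermodynamic: low-energy collisional
activation in an ion trap samples an equilibrated precursor population,
so the intensity of the y/b pair produced by cleavage at amide *k* is
proportional to the equilibrium population of the isomer protonated
there. With conformer effective energies $E_c$ (kJ/mol),

$$P_i \;=\; \sum_{c \in i} \frac{e^{-E_c/RT}}{Z},
\qquad Z = \sum_{\text{all conformers, all isomers}} e^{-E_c/RT},$$

one *global* Boltzmann distribution over all conformers of all isomers.
Normalising per isomer first and reweighting afterwards would make the
isomer populations incomparable, which is why `aggregate_populations()`
always builds a single distribution. Cleavage at position $k$ maps to
y$(n{+}1{-}k)$ and b$(k{-}1)$; the position-1 isomer implies no amide
cleavage and maps to no ions. Intensities are reported relative to the
most populated y ion (relative intensity 1.0). The b ion of a cleavage
is reported with its y partner's relative value: the pair arises from
one cleavage event and no independent y/b branching ratio is modelled.
Amide-oxygen isomers run through exactly the same machinery when
requested; the nitrogen series is the default because nitrogen
protonation is what activates the amide bond toward cleavage, and in
practice oxygen-series populations do not track measured intensities.

### Energy variants

Four effective-energy definitions feed the distribution:

| variant | effective energy | meaning |
|---------|------------------|---------|
| `E`    | electronic energy | raw quantum-chemical energies |
| `EHC`  | E + enthalpic correction | adds ZPE, thermal vibrational, rotational, translational and pV terms |
| `GE`   | E + Gibbs correction | additionally subtracts $T\,S$ |
| `GEEC` | as GE, one conformer per isomer | each isomer reduced to its single lowest-G conformer before the distribution |

`EHC` versus `GE` isolates the entropic term, which is dominated by the
low-frequency modes of floppy molecules — exactly where the harmonic
approximation is least reliable. `GEEC` versus `GE` isolates the effect
of conformational sampling: the pipeline test suite contains a
constructed ensemble in which the isomer ranking flips when each isomer
is collapsed to its single most stable conformer.

## Pipeline and its parameters

`run_predict()` executes: read → `keep_lowest` → `filter_energy_window`
→ `deduplicate` → `thermo_corrections` → `aggregate_populations` (per
variant) → `predict_intensities`, logging conformer counts per stage.
Defaults (all configurable via `pipeline_config()`):

* **Temperature 443.15 K, pressure 2.2e-8 atm** — ion transfer tube
  temperature and trap pressure read off the instrument; these define
  $RT \approx 3.685$ kJ/mol and the translational entropy reference.
* **keep_n = 1000** per isomer — the pruning depth applied after a
  100,000-conformer force-field search in the production workflow.
* **Energy windows 40 / 20 kJ/mol** (semi-empirical / DFT stage, per
  isomer). The 20 kJ/mol DFT cutoff is justified by the Boltzmann
  factor: a state 20 kJ/mol up contributes
  $e^{-20/RT}/(1+e^{-20/RT}) \approx 0.44\%$ at 443.15 K (the fraction
  is sometimes quoted as roughly 0.6%; the closed form gives 0.44% and
  is what the package computes). The wider semi-empirical window
  compensates for energy reordering between theory levels.
* **Deduplication: |ΔE| ≤ 0.03 kJ/mol and align score > 0.98** — a
  conformer must never enter the distribution twice. Candidate pairs
  are gated by energy agreement, then compared geometrically.
* **Annotation tolerance ± 0.5 m/z** — unit resolution of an ion trap;
  no tolerance is prescribed by the benchmark data, so this is exposed
  as a parameter.

### The align score

The duplicate test in the original workflow used a proprietary
"align score" with cutoff 0.98 and no published definition. The package
defines

$$\mathrm{score}(\mathrm{RMSD}) = e^{-\mathrm{RMSD}/\sigma}, \qquad
\sigma = 1\ \text{Å (default)},$$

with the RMSD taken over heavy atoms after Kabsch superposition
(centroid shift, SVD of the coordinate covariance, determinant-corrected
proper rotation). This is monotone in RMSD, equals 1 at identity, and
places the 0.98 cutoff at RMSD ≈ 0.02 Å — a near-identical-geometry
regime consistent with the screen's purpose. Both σ and the cutoff are
arguments. Atom correspondence is by position: conformer ensembles
descend from a single starting structure, so element order is
preserved, and no graph matching is attempted.

### Survivor rule and tie-breaks

Within each isomer, conformers are ordered by (energy, id); for every
surviving pair that passes both duplicate gates, the higher-(energy,
id) member is removed. This makes the survivor the lower-energy
conformer, with lexicographic id as the deterministic tie-break, and a
single ordered sweep is already transitively stable (removal cannot
create new pairs). `keep_lowest` breaks energy ties by id for the same
reason. Peak annotation assigns, repeatedly, the (ion, peak) pair with
the most intense in-tolerance peak, ties to the closest m/z; each peak
is consumed at most once.

## Thermochemistry

Harmonic-oscillator / rigid-rotor / ideal-gas corrections at the stated
T and P, CODATA 2018 constants (R = 8.314462618 J/mol/K):

* vibrational: per real mode with $x = h c \nu / k_B T$, ZPE
  $N_A h c \nu / 2$, thermal energy $N_A h c \nu/(e^x - 1)$, entropy
  $R[x/(e^x-1) - \ln(1 - e^{-x})]$;
* rotational: nonlinear rigid rotor from the principal moments of the
  mass-weighted inertia tensor, symmetry number 1 (peptides are
  asymmetric), energy $\tfrac32 RT$; linear geometries are rejected
  rather than silently mishandled;
* translational: Sackur–Tetrode at T, P, energy $\tfrac32 RT$; plus the
  ideal-gas $pV = RT$ term in the enthalpy.

Then `enthalpy_correction = ZPE + E_vib + 3RT + RT`, `entropy = S_vib +
S_rot + S_trans`, `gibbs_correction = enthalpy_correction − T·S`.

Whether the original corrections included the rotational/translational
terms at trap pressure is not documented; the full ideal-gas treatment
is implemented because it is the standard composition, and
`thermo_corrections(include = ...)` can switch any component off for
sensitivity analysis. Since every conformer of every isomer receives
nearly the same rotational/translational contribution, these terms
largely cancel in the Boltzmann ratios, so the choice is benign.

Imaginary frequencies (negative wavenumbers) are dropped with a warning
and a per-conformer count, because a saddle point's soft mode carries no
meaningful harmonic thermodynamics; `thermo_conditions(on_imaginary =
"error")` makes them fatal instead. Frequencies are unscaled by default
(`frequency_scale` is available), and an optional `low_frequency_floor`
raises soft modes before the sums — a crude probe of the harmonic
entropy problem for floppy molecules, off by default.

Degenerate inputs are refused loudly: empty ensembles, conformers
without frequencies under a corrected variant (named in the error),
all-imaginary mode lists, non-K/R C-termini without the explicit
override (the sequestered-proton assumption is part of the model, not a
convenience).

## Numerical choices

Boltzmann weights are computed after subtracting the minimum energy, so
arbitrary absolute energies (hartree-scale inputs are converted at
2625.4996 kJ/mol per hartree) cannot overflow the exponentials; the
tests check shift invariance to 1e-9 and normalisation to 1e-12.
Energies are kJ/mol everywhere internally; accepted input units are
hartree, kcal/mol, kJ/mol, eV. The 244.3 precursor *m/z* of doubly
charged GAVLK is reproduced by average residue masses with a 1.00739 Da
charge carrier — the monoisotopic value is 244.17, so the instrument
setting is interpreted as an average-mass quantity.

## Synthetic fixtures: what they do and do not show

`synth_ensemble()` builds ensembles by *inverse-Boltzmann*
construction: within-isomer energies are drawn uniformly on
[0, spread] (default 5 kJ/mol, a realistic low-energy conformer band),
then each isomer is shifted by the closed-form offset
$-RT\ln(\text{target}/q_i)$ so the aggregation recovers the target
populations exactly (to floating-point). Because the construction is
exact rather than fitted, a recovery failure in a test indicates a
pipeline bug, not generator slack. Geometries are random points in a
10 Å box (minimum separation 0.8 Å) and frequencies are log-uniform on
[20, 3600] cm⁻¹ — physically plausible ranges, not peptide-like
structures. Synthetic spectra place one peak per predicted ion at its
theoretical m/z with mean-preserving log-normal intensity noise.

Consequently the tests demonstrate that the *machinery* — filtering,
deduplication, thermochemistry, aggregation, mapping, scoring — is
correct, and that the published benchmark arithmetic is reproduced from
printed intensities. They do not validate the thermodynamic hypothesis
itself on new peptides: that requires real conformer ensembles from
quantum-chemistry calculations (on the order of 100 CPU-hours per
conformer at B3LYP/6-31G**), which enter through the JSON interchange
format.

Test problem sizes are deliberately small — ensembles of 4–20
conformers, 4–12-atom geometries, 10–30-mode frequency sets, 200-seed
Monte-Carlo noise checks — chosen so each oracle (brute-force rotation
search, exhaustive assignment enumeration, numerical ln Q
differentiation, direct Boltzmann summation) runs exhaustively.

## Known limitations

* Harmonic vibrational entropies are unreliable for floppy molecules;
  no quasi-harmonic or hindered-rotor scheme is provided (the `EHC`
  variant exists precisely to sidestep the entropic term).
* No PTMs, non-standard residues, neutral losses, internal/immonium
  ions, isotope envelopes, or multiply charged fragments; the fragment
  charge model is +1 with the second proton retained on the y side.
* No kinetics: competing fragmentation pathways, RRKM rates and
  scrambling are outside the thermodynamic model.
* Conformer generation and QM optimisation are external; the package
  starts at their outputs.
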