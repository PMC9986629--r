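---
title: "Screening flexible sites for thermostabilization: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening flexible sites for thermostabilization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfscreen)
```

## The problem and the model

Thermal inactivation of an enzyme usually begins at its most mobile
regions: surface loops unfold first and nucleate global unfolding.
The rigidifying-flexible-sites (RFS) strategy therefore (i) locates the
flexible, surface-exposed regions of a structure, (ii) proposes rigidifying
substitutions there — β-turns are prime targets because positional
amino-acid preferences are strong (proline at position i+1 above all), and
(iii) discards proposals that would either perturb catalysis or fight
evolution. `rfscreen` implements that triage as a chain of independent,
individually toggleable filters over a saturation-mutagenesis ΔΔG table,
plus the ensemble analytics used to rationalize the winners afterwards.

Flexibility is read from crystallographic/model B-factors (Å²), reduced to
one value per residue (all-atom mean by default; Cα-only by flag — the
choice matters little for backbone-dominated models but is exposed because
input conventions differ). Group means over secondary-structure classes,
the surface/buried partition and the catalytic shell are plain arithmetic
means of member residues; empty groups report `NA`, never zero.

## Geometry choices

**SASA.** Shrake–Rupley sphere-point counting with a deterministic
golden-section spiral (no RNG), probe 1.4 Å, fixed vdW radii
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å; unknown elements fall back to
carbon with a warning). Relative SASA divides by a fixed per-residue-type
maximum-exposure table; the surface flag uses the conventional 25% cut,
configurable. At the default 960 points per sphere the per-residue
discretization error is ~1–3%; validation against the independent
latitude–longitude quadrature oracle (`sasa_grid_oracle()`) is run at 3840
points, where agreement is within 2% per residue. The quadrature oracle
shares no code path or point set with the spiral counter.

**Secondary structure.** A torsion-window method rather than a
hydrogen-bond (DSSP-style) one: helix = runs of ≥ 4 residues with
φ ∈ [−90, −30], ψ ∈ [−77, −17]; sheet = runs of ≥ 3 with φ ∈ [−170, −70]
and ψ in the extended band; loop otherwise, including every residue whose
dihedrals are undefined (termini, chain breaks, missing atoms). The
three-class partition is all the screen needs, and torsion windows are
deterministic without hydrogens.

**β-turns.** Window i..i+3 with Cα(i)–Cα(i+3) ≤ 7 Å and neither central
residue helical. Types I, II, I′, II′ and VIII are matched in that order of
precedence against canonical central (φ, ψ) with a ±30° tolerance, one
angle allowed ±45°; everything else is type IV. Overlapping windows are all
reported (no merge rule is imposed — merging would discard information and
any numbering convention downstream can be applied by the caller).

**Superposition.** Kabsch least squares with reflection correction via the
determinant sign; weighted variants are supported. Degenerate inputs
(< 3 points, rank-deficient covariance) are errors, not silent garbage.

## The filter chain and ranking

Filters are pure predicates combined by conjunction, so any permutation of
enabled filters yields the same pass set (tested). Defaults, with their
reasoning:

* **ΔΔG ≤ −0.5 kJ/mol**, boundary inclusive. ΔΔG predictors carry roughly
  ±0.5 kJ/mol of numerical noise, so only predictions clear of that band
  count as stabilizing; the rejected side is the strict `> −0.5`.
* **Mean Cα distance to catalytic residues ≥ 13 Å.** Known negative
  controls sat at 10.5–11.9 Å while accepted sites lay farther out; 13 Å
  splits those brackets and is configurable because the true safe radius is
  enzyme-dependent.
* **Conservation veto at 80%.** Accepted sites in practice show < 50%
  identity to thermostable homologs, rejected ones ≥ 92%; 0.80 sits between
  the brackets. Conservation is identity-to-the-query over non-gapped
  homologs — the question is whether the *wild-type* residue is conserved,
  not what the column consensus is — and gapped homolog positions leave the
  denominator so length variation is not penalized.
* **Preference floor at 0** (no floor): positional turn preference is
  reported and contributes to ranking; Pro substitutions are additionally
  flagged. A hard floor is available for stricter screens.

The rank score is an equal-weight sum of z-scored B-factor, −ΔΔG, catalytic
distance and preference (weights configurable); ties break by lower ΔΔG,
then higher B-factor, then N-to-C position. Z-scoring makes the four
heterogeneous scales commensurable without hand-chosen units.

Per-residue ΔΔG aggregation (used when excluding residues whose whole
substitution spectrum is destabilizing) is ambiguous in common practice —
minimum and mean over substitutions are both defensible — so both are
implemented; the minimum is the default because a single strongly
stabilizing substitution suffices to keep a site interesting.

## Ensemble analytics

RMSF superposes all frames onto an iterated mean structure (convergence at
< 1e-6 Å shift, hard cap 20 rounds for determinism); the DCCM normalizes
displacement covariances so in-phase motion gives +1 and anti-phase −1.
A residue that is genuinely static while others move still acquires
apparent variance through the rigid-body fit — this is a mathematical
property of superposition, not a bug — so exactly-zero-variance rows (which
get `NA`) arise only in superposition-neutral geometries.

Hydrogen bonds use donor–acceptor ≤ 3.5 Å plus D–H⋯A ≥ 120° where a
hydrogen exists or can be reconstructed (backbone amide H from N, CA and
the preceding C along the external bisector). Carbonyl/carboxyl oxygens
never donate; nitrogen donors without any usable H fall back to the
distance criterion with an explicit `angle_checked = FALSE` flag. Pairs
within one residue, and backbone–backbone pairs fewer than two residues
apart, are excluded as covalent-neighbour artifacts. Salt bridges use the
common 4.0 Å side-chain N–O criterion, configurable; occupancy is the exact
frame-count ratio, and the per-frame minimum-distance series is kept so
distance shifts can be reported alongside occupancy changes.

The constraint-network transition temperature is the affine map
`T = −20 · E_cut + 300` (E in kcal/mol, T in K). The rigidity network
itself is not computed here; P∞ series are ingested from file or
synthesized. `find_transition()` places the transition at the point
*ending* the largest single-step P∞ drop — the first point of the flexible
phase — with ties resolved toward the larger (less negative) cutoff, and a
monotone-flat series yields an explicit no-transition result.

## Kinetics

Michaelis–Menten and single-exponential decay fits use Levenberg–Marquardt
least squares with analytic-free starts: `Vmax₀ = max(v)` and `Km₀`
interpolated at half-max; decay starts from the log-linear regression.
The decay model is fixed as first-order because a reported half-life
presupposes it. `t₁/₂·k = ln 2` holds by construction. Non-identifiable
designs (velocity independent of substrate) are reported as
`converged = FALSE` rather than returning a meaningless `Km` near zero;
non-positive activities are excluded with a warning before log-transform.

Parameter-recovery validation uses the constant-CV error model
(σᵢ = 2% of each observation), the standard description of enzyme-assay
noise. Under a homoscedastic alternative (σ = 2% of Vmax everywhere), `Km`
on a 1–10 mg/mL design with `Km ≈ 5.5` is weakly identified and its median
recovery error is ~10% — a property of the design, not the optimizer —
which is why the heteroscedastic model is the validation condition.

## What the generators emulate — and what they do not

`build_peptide()` lays down ideal backbone geometry (N–CA 1.458, CA–C
1.525, C–N 1.329 Å; angles 111.2°, 116.2°, 121.7°; ω = 180°) with segment
dihedrals: helix (−57, −47), strand (−120, 130), canonical turn centrals.
Turn segments carry fixed extended flanks (−160, 170) and (−80, 100),
chosen so that windows overlapping a planted turn stay above the 7 Å
cutoff; that makes planted-equals-detected an exact property on fixtures.
Side chains beyond Cβ are generated only where an analysis needs the atoms
(Asp/Glu/Arg/Lys/His charged tips), with idealized geometry.

`build_ensemble()` draws isotropic per-residue Gaussian displacements
scaled so the expected RMSF of residue r is the planted value; correlated
blocks share one latent vector per frame (sign ±1); bond plants override
the atom pair's coordinates *after* sampling, so planted occupancies are
exact rather than probabilistic. Mobility-recovery tests use 40-residue
peptides: with fewer anchors the rigid-body fit absorbs a visible fraction
of a lone mover's displacement (≈ 10% at 16 residues, ≈ 3% at 40).

These fixtures are deliberately minimal: no rotamers, no physical
dynamics, no sequence-evolution model, no crystal contacts. Passing
plant-and-recover tests therefore demonstrates that the analytics compute
their definitions correctly — not that the screen's thresholds are optimal
for any particular real enzyme, which depends on model quality and the ΔΔG
predictor used.

## Problem sizes and numerical conventions

Test fixtures use peptides of ~10–60 residues, ensembles of up to 900
frames, 13-homolog alignments, 380-row saturation tables and 200-seed
simulation studies; all randomness flows from explicit integer seeds and
the generators are bit-reproducible. Angles live in (−180, 180]; author
residue numbering is preserved verbatim and all cross-references use
`chain:res_seq` keys. Negative B-factors clamp to zero with a warning;
waters and HETATM records are excluded from screening by default.

## Known limitations

* B-factors of homology models inherit template/server conventions; the
  package treats them as given.
* The torsion-window secondary structure has no π/3₁₀ subtypes and may
  class isolated helical turns as loop — acceptable for the 3-class screen,
  not a DSSP replacement.
* Hydroxyl (Ser/Thr/Tyr) donors are only detected when an explicit H is
  present, since their H position is rotameric.
* The rigidity (pebble-game) network construction behind P∞ is out of
  scope; only transition detection and the temperature map are provided.
* Epistasis of combined mutants is not modelled; the screen ranks single
  substitutions.
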