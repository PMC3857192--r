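---
title: "Designing and verifying conformation-locking disulfide bonds with sslock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying conformation-locking disulfide bonds with sslock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sslock)
```

## The problem and the model

Two-state receptors such as the integrin αIIbβ3 headpiece interconvert
between a closed, low-affinity conformation and an open, high-affinity one
in which the β-subunit hybrid domain swings 60–70° away from the α-subunit
β-propeller. Whether a given function (soluble ligand binding, priming,
adhesion, outside-in signaling) requires that swing-out can be tested by a
mutant that physically cannot swing out: two residues, one per subunit,
are mutated to cysteine so that a disulfide bond staples the subunits
together in the closed arrangement.

The design criterion is purely geometric. For residues *i*, *j* with Cβ
coordinates in both endpoint structures,

* d_closed(i, j) must be small enough that, after mutation to cysteine,
  the two Sγ atoms can reach bonding distance. Native disulfides show
  Cβ–Cβ distances near 3.5–4.5 Å, but engineering tolerates substantially
  more because side-chain and backbone relaxations absorb several Å; the
  default `closed_max = 12` Å brackets the accepted published pairs
  (7.7 and 11.7 Å).
* d_open(i, j) must be large enough that the bond is strictly
  incompatible with the open state; the default `open_min = 20` Å sits
  well below the published open-state separations (32.6 and 38.7 Å) while
  excluding pairs whose motion is marginal.

Candidates are ranked by Δd = d_open − d_closed, the closed/open contrast
that the published pairs maximize. The screen deliberately models nothing
beyond Cβ geometry — no Sγ rotamers, no χ-angle or Cα–Cβ–Sγ energetics —
because the original selection criterion was the Cβ distance; this is a
stated non-goal, not an omission.

## Structure handling choices

The PDB reader is intentionally small and deterministic:

* only the first `MODEL` block is read (a warning reports extras);
* only `ATOM` records of the 20 standard residues are kept;
* alternate locations are resolved by highest occupancy, ties broken by
  the lexicographically smallest altloc id — repeated parses of the same
  file serialize identically;
* occupancies outside [0, 1] are clamped and logged; malformed lines are
  skipped and counted;
* insertion codes are part of the residue key everywhere, so screening
  iterates residue keys, never raw integers;
* coordinates are Å throughout, no unit conversion anywhere.

Residues missing from one state (unmodeled loops) are skipped and counted
rather than raised, since pairs cannot be evaluated without both
endpoints. Glycine has no Cβ; an optional virtual Cβ is constructed from
N/CA/C with a 1.532 Å bond, 110.4° N–CA–Cβ angle and L-chirality. It is
off by default — the residues this workflow targets (K, E, R) all have
real Cβ atoms — and when the backbone is so distorted that the target
angle is infeasible the construction preserves the bond length exactly
and shortens both angles equally.

Author-vs-construct numbering (mature protein without the leader
sequence) is handled by an explicit per-chain offset map
(`numbering_map()`), which round-trips exactly. The acceptance check
assumes offset 0 between the published mature-protein numbering and the
3FCS/3FCU author numbering; the assumption is stated in the test itself
so a failure would localize immediately to numbering rather than to the
distance code.

## Mass-spectrometric verification

An engineered disulfide is proven by finding, in an LC-MS/MS run of the
non-reduced protein, a peak whose m/z matches a crosslinked peptide that
cannot exist in the wild type. The arithmetic is exact and monoisotopic:

* peptide mass = Σ residue masses + 18.0105646 (water);
* crosslink mass = M_a + M_b − 2 × 1.0078250 (two hydrogens leave when
  S–S forms);
* m/z = (M + z × 1.0072765)/z for the [M + zH]^z+ ion.

Average masses are out of scope. Digestion rules: trypsin cleaves after
K/R with the Keil proline block on by default (consistent with the
published peptides); Asp-N is configurable as a residue set with presets
`aspn_d` = {D} (vendor definition) and `aspn_de` = {D, E}, because some
Asp-N preparations also cleave N-terminal to glutamate — and producing
the published "EVC" peptide requires a cut before a glutamate, so the
broadened preset is the documented default for that workflow. A
sequential trypsin-then-Asp-N digest is modelled as the union of both
enzymes' cut sites on the intact sequence: after two days of sequential
digestion every site of either enzyme is assumed cut, and spans are
tracked on the original sequence. Missed cleavages default to 2, the
common database-search setting. Cysteines are unmodified by default
(the workflow must preserve the disulfide, so there is no reduction or
alkylation step); fixed modifications are available as a mass-delta
table. Intra-peptide disulfides are excluded from enumeration. Observed
and predicted peaks are compared in ppm space (default 10 ppm, an
Orbitrap-class tolerance) at the same charge state; reported m/z values
are displayed at 4 decimals with full precision kept internally.

A note on the published charge states: the printed ion labels are of the
MH₄³⁺ / MH₄⁺ form, whose arithmetic consistent with the printed m/z
values is (M + zH)^z+ with z = 3 and z = 1. The implementation therefore
exposes z explicitly and makes no assumption about the label notation.
The two published peaks verify to within 3.9 ppm (488.2550 computed vs
488.2569 printed, z = 3) and 0.3 mDa (653.2633 vs 653.2630, z = 1); the
second value is printed as 653.2639 in one figure legend and 653.2630 in
the text, both within the 1 mDa window. The exact subunit flanking
sequences needed to regenerate VELCVR/CLAEVGR by digesting the full
chains are not printed in the source material, so digestion-level
reproduction of those peptides uses synthetic mini-chains and the mass
arithmetic uses the printed peptide strings.

## Assay quantifications

**NNFI.** Flow-cytometry binding is summarized as
(GMFI_sample − GMFI_background) / expression_ratio, with the geometric
mean as the location statistic (fluorescence is near log-normal). The
background well is an explicit caller choice, because both
excess-unlabeled-antibody and EDTA backgrounds are in legitimate use.
The expression ratio is a fraction (0.8), not a percent; the CLI accepts
percent input behind an explicit `--expression-percent` flag. Negative
NNFI is flagged, not raised. Two gain facts are asserted by the tests:
a detector gain applied to the expression channel cancels when the
expression ratio is a ratio of geometric means, and a gain on the binding
channel scales NNFI linearly — so NNFI comparisons are only meaningful at
a fixed binding-channel gain.

**Percent inhibition** is (1 − treated/control) × 100 with a positive
control required.

**Elliptical form factor.** A spread cell's mask is reduced to the ratio
of the major to minor axis of a fitted ellipse (1 = circular, larger =
eccentric spreading). The fit is moments-based — axis lengths are
4 × √eigenvalue of the foreground-pixel covariance, the regionprops
convention, exact for an ideal filled ellipse — rather than a contour
least-squares fit, for determinism on small masks and exact rotation
invariance of the eigenvalue ratio. One mask is one cell: when several
8-connected components are present the largest is used with a warning,
and segmentation is considered upstream. Degenerate masks (empty,
collinear, fewer than 16 foreground pixels) are errors. Mask input is a
CSV 0/1 matrix; PNG/TIFF readers are not available in this R
environment, so image masks should be exported to CSV upstream.

## What the synthetic generators emulate

`make_two_state_toy()` builds two poly-alanine-like chains in which chain
B rotates rigidly about a hinge axis, emulating a domain swing-out. The
layout guarantees that exactly one inter-chain pair (A1–B1, 8 Å apart
closed, margins ≥ 15 Å elsewhere) can pass the default thresholds, and
for hinge angles ≥ 30° its open-state separation does exceed 20 Å, so
the screen must report exactly that pair; its open-state distance has
the closed form √(1250(1 − cos θ) + 400 sin θ + 64). A hinge of 0° is
accepted as the degenerate no-motion case (identical states, zero
candidates). The default hinge of 60° matches the magnitude of the real
hybrid-domain swing-out. Seeded z-jitter (±0.3 Å) on non-engineered
residues makes fixtures distinct per seed while leaving the designed
margins intact.

`make_integrin_standin()` is a clearly-labelled synthetic surrogate for
the real closed/open crystallographic pair: K321/E358/R360 with the four
published Cβ distances as construction targets and a 2.9 Å NZ–OE1 salt
bridge at the interface. Because the distances are inputs, a green test
on the stand-in establishes that the parse → Cβ → screen → contact
pipeline measures correctly — it is *not* a reproduction of the
published measurement, which requires the real downloaded structures
(see the acceptance test's message).

The flow-event generator draws log-normal events with a known geometric
mean; the mask generator rasterizes exact filled ellipses. None of the
generators emulate experimental nuisance (debris and doublets in
cytometry, segmentation error, crystallographic disorder), so green
property tests establish correctness of the computations, not robustness
to dirty data.

## Numerical choices and limitations

* All mass comparisons use 1e-4 Da (display) and 1e-6 Da (identities);
  distance assertions use 1e-3 Å against PDB text, which carries 3
  decimals, and 1e-6 Å internally (e.g. rigid-motion invariance).
* Screen ties are broken deterministically: Δd descending, then d_closed
  ascending, then residue identity — identical inputs give byte-identical
  TSV output.
* The screen's universe is residues present with a resolvable Cβ in both
  states; everything else is skipped and counted, never silently
  dropped.
* Temporal ordering of contacts along the closed→open pathway is not
  computable from two endpoint structures and is out of scope, as are MD
  simulation, disulfide energetics/rotamers, MS/MS fragment-ion
  prediction, FCS parsing, gating, segmentation, and the statistical
  hypothesis tests of the downstream biology.
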