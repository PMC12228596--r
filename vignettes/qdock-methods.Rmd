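---
title: "Methods: quantum docking-site search on the lattice interaction space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantum docking-site search on the lattice interaction space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdock)
```

## Model and assumptions

`qdock` works on the interaction-space refinement of the protein lattice
model. A molecule is an ordered chain of interaction sites; each site
carries two continuous properties, a hydrophobic interaction value `h` and a
hydrogen-bonding value `hb`, each confined to a closed user-supplied range.
The model deliberately abstracts away 3D geometry, solvent effects and
further interaction types (π-stacking, salt bridges, …): a docking site is
a contiguous, ligand-sized run of protein sites whose interaction profile
matches the ligand's. The two-property choice reflects the two interactions
most frequently observed in protein–ligand complexes; the site encoding is
two qubits per site, one per property, so adding a third interaction type is
a localized change (one more qubit per site and one more range).

The units of `h` and `hb` are not fixed by the model. They enter only
through their position inside their range, so any affine-consistent scale
works; the package treats them as abstract reals and validates range
membership strictly — out-of-range values are errors, never clamped, since
silent clamping would corrupt the binary labels that drive the search.

## The two encodings

**Binary (first) encoding.** Each property value is thresholded at the
midpoint of its range: `[min, mid)` maps to bit 0 and the closed upper
interval `[mid, max]` to bit 1. The midpoint itself belongs to the upper
bin — the interval mapping is half-open below and closed above, and the
package adopts that boundary exactly. A site yields the two-bit string
`q_h q_hb` (hydrophobic bit left); a chain yields the concatenation in
chain order, read as a big-endian basis label (first site = most
significant bits). All I/O and reports use this canonical string; the
backends index the statevector accordingly.

**Amplitude (second) encoding.** For evaluation, a value `v` in
`[min, max]` becomes the one-qubit state `α|0⟩ + β|1⟩` with
`α ∝ (max − v)` and `β ∝ (v − min)`, normalized. All amplitudes are real
and non-negative by construction, so no phase bookkeeping is needed
anywhere in the package. `β` increases strictly with `v`, and rounding to
the dominant branch reproduces the binary bit except exactly at the
midpoint, where the closed-upper-interval rule of the first encoding
applies. Sites and chains are tensor products of these one-qubit states,
giving unit statevectors of dimension `4^sites`.

## Subspace Grover search and the 1/N threshold

The protein label is cut into consecutive, non-overlapping windows of one
ligand-length each. Duplicate window labels are removed keeping each
label's last occurrence (one occurrence answers the presence question), and
the `N` survivors span the uniform superposition `|s⟩ = (1/√N) Σ|x⟩`. The
search applies `k` rounds of oracle (`I − 2|t⟩⟨t|`, `t` the ligand label)
and diffusion (`2|s⟩⟨s| − I`). Because the search lives in the
`N`-dimensional subspace rather than the full register space, fewer than
`√N` iterations suffice; the package uses the single-marked-item optimum
`k = max(1, ⌊(π/4)√N⌋)`, exposed as a config override
(`dock_control(iterations = ...)`). For an in-subspace target the exact
probability after `k` rounds is `sin²((2k+1)·arcsin(1/√N))`; for a target
outside the subspace it is exactly 0, because the oracle acts as the
identity on the span of `|s⟩`.

Presence is decided by comparing the measured target probability with the
threshold `1/N`. The threshold is derived from the extreme case `N = 2`:
in a two-dimensional subspace one Grover round leaves a present target at
exactly `p = 1/2 = 1/N` (no amplification is possible there, since
`sin²(3·arcsin(1/√2)) = 1/2`), while an absent target stays at 0. The
boundary is therefore **inclusive** — `p ≥ 1/N` (with a `1e-9` float
tolerance) reads present. A strict comparison would make a present target
in a two-window range undetectable in principle, which is precisely the
case the threshold is built around. With `N ≥ 3` and the default iteration
count, present targets sit far above the threshold (at `N = 3` already
`25/27 ≈ 0.926`), so the boundary only matters at `N = 2`. Single-label
ranges (`N = 1`) bypass the quantum path entirely: the threshold `1/1`
is unusable and a direct label comparison is deterministic.

## Two diffusion implementations

The diffusion reflection is implemented twice, and every search can use
either:

* **matrix** — the explicit dense unitary `2|s⟩⟨s| − I` applied to the
  statevector, the direct realization of the operator definition;
* **ancilla** — amplitude amplification on one extra qubit: the reflection
  is assembled as `A (I − 2|0…0⟩⟨0…0|) A⁻¹` with `A` the state-preparation
  unitary (a Householder reflection taking `|0…0⟩` to `|s⟩`), and the
  zero-state phase flip is realized by phase kickback off an ancilla
  prepared in `|−⟩` via an X controlled on the register being all-zero.

The two differ by a global phase `(−1)^k`, which is unobservable; their
register distributions agree to `1e−10` on every test instance, and the
suite asserts this for `N` from 2 to 32. State preparation of the
non-uniform `|s⟩` is part of the backend contract — the prepared vector
must match the subspace superposition to `1e−10`; how it would compile to
gates on hardware is out of scope.

## Localization: segmentation, bisection, shift

A presence test says *whether* the ligand pattern occurs in a window range,
not *where*. The controller therefore bisects: a present range with more
than one window is split on a window boundary (left part takes ⌈w/2⌉
windows — the ceiling-left rule keeps every recursion level a valid window
set) and **both** halves are searched, because a present parent does not
identify which half holds the match and multiple docking sites may exist.
Absent ranges are pruned. At a single window the decision is deterministic.

Windows are aligned to the chain start, so matches at unaligned offsets are
invisible to one segmentation. Shifting the protein by 1 … L−1 sites
(dropping leading sites) realigns the grid; offsets at L and beyond would
regenerate already-searched windows. Across all shifts every contiguous
ligand-sized run of the protein appears as a window in exactly one pass
(verified by enumeration in the tests), so the controller's output equals a
classical substring scan over all site offsets — the suite checks exact
agreement on seeded random instances. Trailing remainders shorter than one
window are dropped, never searched as partial sites; each drop is recorded
in the search trace so users can see uncovered tail positions. Candidate
positions are always reported as 0-based site offsets into the original,
unshifted protein.

## SWAP-test Euclidean distance

Candidates are ranked by the Euclidean distance between amplitude-encoded
states, estimated quantum-mechanically. With embedded vectors `A`, `B`
(norms `|A|`, `|B|`, `Z = |A|² + |B|²`), the package prepares
`|ψ⟩ = (|A⟩|0⟩ + |B⟩|1⟩)/√2` (ancilla last — the register position is
fixed and documented) and the magnitude qubit
`|φ⟩ = (|A||0⟩ − |B||1⟩)/√Z`, then simulates the SWAP-test circuit: control
Hadamard, controlled-SWAP of ψ's ancilla with φ's qubit, Hadamard, measure
the control. The exact statistic is `p0 = ½ + ½‖⟨φ|ψ⟩‖²`, where the
contraction runs over ψ's ancilla; this identity is the one consistent with
the distance inversion `D = √(4Z(p0 − ½))` and is verified in the tests by
direct comparison with the classical distance on the raw embedded vectors
(`1e−9` over dimensions 2, 4 and 16). In the ranking pipeline both states
are unit vectors, so `Z = 2`; the operations nevertheless accept
arbitrary-norm inputs because the construction is defined for general
magnitudes.

Numerical edge cases: an exact `p0` can fall below 0.5 by float jitter only
(≤ 1e−12), which is ignored; a *sampled* `p0` below 0.5 is shot noise, and
the distance is clamped to 0 with a `clamped` flag propagated into the
candidate table and the JSON report, never an exception. Ties in the
ranking are broken by ascending start offset, so the output is a pure
function of the input set (permutation-invariant, asserted in the tests).
Sampled rankings report 95% intervals per candidate obtained by binomial
error propagation through the inversion formula.

## Backends, determinism and capacity

The exact statevector backend is the default for decisions and ranking:
probabilities are exact squared amplitudes and a whole run is a pure
function of its inputs (reports reproduce byte-for-byte). The sampling
backend emulates a finite-shot simulator: every measurement draws seeded
multinomial counts, and each measurement in a run derives a child seed from
the master seed (`dock_control(seed = ...)`), so sampled runs are
reproducible bit-for-bit while successive measurements stay independent.
The RNG state of the calling session is always restored.

A `qubit_budget` (default 12) guards every register allocation; the dense
explicit-matrix diffusion is the binding constraint, at `O(4^n)` memory for
an `n`-qubit register. The worked instances (ligands of 1–3 sites, i.e.
2–6-qubit search registers) are far below the guard.

## Synthetic data

The generator draws per-site values independently and uniformly within
their ranges (uniformity is itself tested by goodness of fit), and plants
docking sites in two modes: `exact-continuous` copies the ligand's values
(a distance-0, rank-1 site by construction) and `exact-binary` draws values
inside each ligand value's half-interval but distinct from it, controlled
by a `jitter` half-width that errors if it would cross a label boundary.
Bitstring instances used in the documentation and tests are realized as
continuous chains via quarter-point values, whose binary encodings equal
the stated labels. Negative controls are rejection-sampled until no slice
matches the ligand label. What the generator does **not** emulate: any
correlation structure along real chains, measurement error in the property
values, or a physically derived distribution of `h`/`hb` — passing tests
demonstrate the search and ranking machinery, not the adequacy of uniform
values as a stand-in for real interaction profiles, and no derivation of
values from structures or SMILES is attempted.

## Test problem sizes

The suite exercises: the closed-form Grover property for `N` = 2 … 32 and
`k` = 1 … 5 against a brute-force matrix oracle; distance/oracle
equivalence on 50 random instances per dimension in {2, 4, 16}; sampling
consistency at 10,000 shots over 200 seeded trials (5σ coverage ≥ 99%);
and end-to-end recovery on 100 seeded proteins of up to 16 sites with
ligands of 2–3 sites, compared exactly against the classical substring
scan. These sizes keep the whole suite well under a minute while covering
every register width the 12-qubit default budget admits for the matrix
path with headroom.

## Known limitations

* The search register grows with the *ligand* size (2 qubits per ligand
  site), and the dense simulation grows exponentially with it; the package
  is a desk-scale simulator of the algorithm, not a hardware client. No
  transpilation, noise models or error mitigation are included.
* The presence decision on the sampling backend inherits binomial noise; at
  `N = 2` the present/absent gap collapses to 0.5 vs 0, so a sampled
  two-window decision is a near-coin-flip at the boundary. Use the exact
  backend for decisions (the default) or larger shot counts.
* Matches are exact binary-label matches. Near-matches (e.g. one property
  marginally across its midpoint) are invisible to the search even though
  their amplitude-encoded distance would be small; the ranking stage only
  evaluates what the search located.
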