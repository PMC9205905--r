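---
title: "Methods: transfer geometry and anchored superposition in pbsfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transfer geometry and anchored superposition in pbsfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsfret)
```

`pbsfret` turns an atomic model of a phycobilisome (or any bilin-bearing
pigment–protein complex) into three geometric analyses: a pairwise Förster
geometry table, a distance-gated chromophore transfer network with ranked
candidate pathways to the terminal emitters, and an anchored-superposition
comparison quantifying monomer rearrangements in phycocyanin rods. This
vignette documents the models behind each stage, the tunable parameters, the
synthetic-data generator the tests rest on, and the design choices made where
the methodology was genuinely open.

## 1. The point-dipole transfer model

The transfer-rate proxy between a donor and an acceptor chromophore is
$k \propto V^2\Theta$, with the point-dipole coupling in its two equivalent
forms

$$V \approx \frac{\boldsymbol{\mu}_D\cdot\boldsymbol{\mu}_A}{r^3}
  - \frac{3(\mathbf{r}\cdot\boldsymbol{\mu}_D)(\mathbf{r}\cdot\boldsymbol{\mu}_A)}{r^5}
  = \frac{\mu_D\,\mu_A\,(\cos\theta_T - 3\cos\theta_D\cos\theta_A)}{r^3},$$

and the orientation factor
$\kappa^2 = (\cos\theta_T - 3\cos\theta_D\cos\theta_A)^2 \in [0, 4]$.
Both forms are implemented (`dipole_coupling(form = "vector")` /
`form = "cosine"`) and their agreement is asserted to $10^{-9}$ relative in
the test suite; `pair_geometry()` uses the cosine form. Angles are stored as
cosines throughout — never degrees — to avoid convention drift.

Deliberate simplifications, reflected in the `Non-goals` of the API:

* **The spectral overlap $\Theta$ is a constant** (`overlap_factor_default`,
  1.0). No spectra are computed, so couplings and rates are relative
  quantities; the constant only sets a global scale.
* **Dipole magnitudes default to 1.** The analysis ranks geometries; absolute
  rate constants (refractive index, quantum yield, literature dipole
  strengths) are out of scope. Magnitudes are configurable per chromophore
  for users who want literature values.
* **No excitonic Hamiltonian.** At the 20–30 Å separations typical of
  adjacent bilins the point-dipole approximation is informative but coherent
  coupling is not modelled; the ranked pathways are geometric candidates, not
  kinetic predictions.

The isotropic sanity check: for freely rotating pigments the average of
$\kappa^2$ is $2/3$. `isotropic_kappa_mean(n, seed)` estimates it by Monte
Carlo with uniform-on-sphere dipoles (normalised 3-D Gaussian draws —
unbiased and seedable), converging as $n^{-1/2}$:

```{r iso}
isotropic_kappa_mean(1e5, seed = 1)
```

## 2. Chromophores: extraction, naming, dipoles, environment

**Extraction.** Every hetero residue whose 3-letter code is in the assembly
map's `ligand_codes` (default `CYC`, phycocyanobilin) becomes a chromophore.
The chromophore *centre* is the unweighted centroid of the configured
conjugated atoms. This convention is explicit and configurable because
"centre-to-centre distance" is ambiguous — centroid of the full ligand, of
the conjugated system, or of rings B/C shift distances by 1–2 Å. The shipped
default conjugated set is the ring B/C tetrapyrrole atoms plus the methine
bridge carbons of the conjugation path, the part of the π-system that carries
the transition dipole.

**Naming.** IDs follow the field convention: cylinder + trimer index,
subunit descriptor, attachment cysteine (`C1-a1-84`, `A3-aLCM-198`,
`A3-bApcF-82`, `A1-aApcD-81`). The attachment cysteine is found as the
nearest SG atom within 2.5 Å of the ligand (optionally restricted to a
configured attachment atom); when none qualifies the ligand's own author
number is used and the chromophore carries an `attach_fallback` flag rather
than failing. ApcD identification in pentacylindrical cores is tentative in
the literature, so IDs on ApcD chains carry a `tentative` flag.

**Transition dipoles.** The exact atom convention for the PCB transition
dipole varies between studies and is rarely machine-readable, so the package
uses a declared geometric stand-in: the principal axis of the conjugated
atoms (leading eigenvector of their 3×3 covariance), sign-oriented so its
projection on the vector from a ring-A-side atom to a ring-D-side atom is
positive. The axis is invariant under rigid motion (up to the sign rule,
verified property-style in the tests), and the atom list and sign pair are
configuration, so any published convention can be substituted without code
changes. A conjugated system whose top two covariance eigenvalues agree to
better than $10^{-6}$ relative has no defined long axis and raises an error
rather than returning an arbitrary direction.

**Environment.** `chromophore_environment()` lists all polymer residues with
any atom within a cutoff of any conjugated atom, sorted by minimum distance —
the aromatic cages and hydrogen-bonding partners around each bilin that tune
its site energy. The chromophore's own attachment cysteine is excluded by
default since it is trivially in contact.

Chromophores with fewer than 4 conjugated atoms present are flagged
`incomplete`, reported with a warning (never silently dropped), and excluded
from pair analysis: a 3-point system barely constrains an axis and its
centroid is not comparable with complete chromophores.

## 3. The transfer network

`all_pairs()` emits every unordered chromophore pair within a distance gate,
once, with the lexicographically smaller ID as donor and rows sorted by
descending weight $\kappa^2/r^6$. The **default cutoff is 35 Å** — the
longest inter-cylinder bridging distance observed in phycobilisome cores —
so the gated graph retains every physically discussed contact while dropping
the quadratic bulk of distant pairs.

`strongest_path()` ranks candidate routes to the terminal emitters by the
**product of edge weights** along simple paths, equivalently the minimum of
$\sum -\log w$. This is a declared formalisation: under the rate proxy, a
sequence of independent hops has a figure of merit proportional to the
product of per-hop weights. The literature discusses pathways qualitatively;
this rule makes them computable and reproducible, and nothing stronger is
claimed — in particular no master-equation kinetics and no assertion that the
top-ranked path is *the* biological pathway. Numerical specifics:

* all physical weights are far below 1, so $-\log w$ is positive and a
  label-setting (Dijkstra) search is exact, with its optimum automatically a
  simple path;
* synthetic graphs may carry weights above 1; the search then falls back to
  exhaustive simple-path enumeration with the same objective;
* exact cost ties are broken by the lexicographically smallest node sequence,
  making results independent of edge insertion order (verified against an
  independent exhaustive-enumeration oracle);
* a source that cannot reach any sink returns a `"disconnected"` status, not
  an error, since isolated chromophores are an expected feature of gated
  graphs.

Sinks default to the terminal-emitter chromophores (ApcE/α-LCM at Cys198 and
ApcD at Cys81, `find_terminal_emitters()`), and `bridging_pairs()` reports
inter-cylinder edges sorted by ascending distance — the conduits through
which excitation energy crosses between cylinders.

## 4. Anchored superposition

Ordinary best-fit RMSD of each monomer separately answers "has the monomer
changed internally?". The rod-rearrangement question is different: *with the
rod held as one body, where has each monomer moved?* The anchored procedure:

1. pair the Cα residues of the anchor monomer across the two assemblies by
   global sequence alignment (match +1, mismatch 0, linear gap −1) — robust
   to numbering offsets between crystal and cryo-EM depositions, which is why
   alignment was chosen over residue-number equality;
2. Kabsch-fit the anchor's paired Cα (proper rotation, det = +1, reflection
   branch corrected);
3. apply that single transform to the whole mobile assembly;
4. report each monomer's Cα RMSD with **no further fitting**.

The anchor's anchored RMSD equals its own best-fit RMSD by construction, and
every other monomer's anchored RMSD is bounded below by its dedicated
best-fit RMSD — both are asserted property-style over randomly perturbed
synthetic rods. RMSDs are unweighted with no outlier trimming, as no trimming
rule is standard for this comparison. A "monomer" is the αβ chain pair
grouped by the assembly map's (cylinder, unit index); alignment tie-breaks
prefer diagonal over gap moves, deterministically.

Degenerate inputs are errors, not warnings: fewer than 3 paired residues
("insufficient correspondence"), collinear coordinate sets ("rank-deficient
coordinates"), improper planted rotations in the generator.

## 5. The synthetic-data generator

The generator produces the three study geometries with *analytic* ground
truth, which is what makes every stage testable without downloads:

* `make_ring(n, radius, dipole_mode)` — n pseudo-chromophores equally spaced
  on a circle, emulating an (αβ)₃ trimer ring's chromophore placement.
  Pairwise distances are the exact chords $2R\sin(k\pi/n)$. Each
  pseudo-chromophore is a 5-atom collinear run (0.5 Å spacing) reusing the
  configured conjugated atom names, so principal-axis dipole assignment
  reproduces the intended tangent/radial/axial direction exactly and the
  fixture survives PDB round trips.
* `make_stacked_rings(n_rings, spacing, ...)` — rings stacked along z, each
  its own "cylinder", emulating trimer stacking; with aligned phases the
  nearest inter-ring distance is exactly the spacing.
* `make_rod(n_units, n_res)` — αβ monomers of Cα-only chains on a coarse
  helix with seeded jitter and identical per-role sequences across units, so
  residue pairing is the identity; `perturb_assembly()` plants proper rigid
  motions per monomer and records the exact anchored per-unit RMSD
  ($\mathrm{rms}(T_a^{-1}T_u x - x)$; $|t|$ for a pure translation of a unit
  with an untouched anchor).

All randomness flows through one integer seed (`withr::with_seed`), and
regenerating with the same seed reproduces manifests bit-for-bit. What the
fixtures deliberately do **not** emulate: real bilin chemistry and ring
geometry, B-factors/occupancies, alternate conformations at density limits,
or sequence divergence between depositions. Green tests on these fixtures
therefore certify the geometry pipeline — extraction, dipole assignment,
distances, κ², path search, anchored RMSD — to stated numerical precision;
they do not certify chemical assignments in real maps, which remain the
modeller's responsibility.

Problem sizes used by the test suite and the acceptance script — $10^6$
Monte-Carlo orientation draws, $10^4$ coupling self-consistency pairs, 20
chromophores for pair-gating oracles, 15-node graphs for exhaustive path
enumeration, 30-mers for alignment oracles, 4–6-monomer rods of 16–24
residues per chain — were chosen as the smallest sizes at which the checked
statistics are stable (the Monte-Carlo mean, for instance, has standard error
≈ 0.0008 at $10^6$ draws against a tolerance of 0.01).

## 6. I/O conventions and degenerate inputs

* Author residue numbering is authoritative everywhere; nothing renumbers.
* Alternate locations resolve to the highest-occupancy conformer, ties to the
  alphabetically first alt-loc ID — a deterministic single-conformer geometry.
* Waters are excluded; hydrogens are ignored (cryo-EM depositions carry
  none); only the first model of a multi-model file is used, with a notice.
* Reading goes through `bio3d` for both PDB and mmCIF. `bio3d` has no mmCIF
  writer, so the package writes a minimal canonical `atom_site` loop; the
  PDB/mmCIF renderings of the same fixture are asserted to parse to identical
  chromophore sets.
* Files with zero atoms, unparseable blocks, duplicate chain assignments,
  unknown subunit roles, and unwritable outputs all raise explicit errors
  naming the offender.

The packaged `inst/extdata/synthetic_core_map.cfg` illustrates the
assembly-map format at full core scale. Its chain IDs are synthetic
placeholders (the chain-to-cylinder correspondence of any given deposition
must come from that entry's own annotations); its role multiset matches the
published subunit inventory of a pentacylindrical core (38 ApcA, 40 ApcB, 6
ApcC, 2 ApcD, 2 ApcE, 2 ApcF).

## 7. Known limitations

* The principal-axis dipole is a stand-in; published per-atom dipole
  conventions, once known, should be supplied via the configuration rather
  than assumed.
* The max-product pathway objective is a ranking heuristic, not kinetics.
* Analyses of deposited structures (chromophore counts, bridging distances,
  per-monomer rod RMSDs against a crystal packing) require the coordinate
  files and a curated chain map; the library operates on local paths only,
  with a thin `fetch` helper in the CLI for users with network access. The
  crystal-packing rod must be supplied pre-assembled (generate it from the
  entry's assembly records with any standard tool); the library does not
  expand crystal symmetry.
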