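---
title: "Predicting DNA-binding patches with shortest-path graph kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting DNA-binding patches with shortest-path graph kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchkernel)
library(dplyr)
```

## The problem and the model

Proteins bind DNA through a patch of surface residues whose physicochemical
and evolutionary character differs from the rest of the surface. Most
predictors summarize a candidate patch as a flat feature vector, which
discards how those features are arranged in space — yet the spatial
arrangement of, say, a conserved positively charged ridge is precisely what
makes a site DNA-binding. `patchkernel` keeps the arrangement: a surface
patch is a **labeled graph** whose nodes are residues (labeled with a
26-dimensional attribute vector) and whose edges are residue contacts, and
patches are compared with a **shortest-path graph kernel**.

The pipeline has four stages.

**1. Residues and attributes.** Each residue carries 26 attributes:
relative solvent accessibility, electrostatic potential, sequence entropy,
surface curvature, pocket size, structural conservation, and the 20 columns
of a PSI-BLAST position-specific scoring matrix. Computing these requires
external tools, so the package *consumes* them as a tab-separated table
(`read_feature_table()`) alongside the PDB coordinates
(`read_structure()`). All attributes are min–max scaled to [0, 1] with
extremes taken over the union of all training residues
(`fit_normalizer()` / `apply_normalizer()`); unseen values are clipped.

**2. Patches and graphs.** An *interface residue* loses at least 1 Å² of
solvent-accessible surface area upon DNA binding
(`asa_unbound − asa_complex ≥ 1`, inclusive); a *surface residue* has
relative accessibility above 5% in the unbound protein (strict). Three
patch kinds are built: the **interface patch** (all interface residues of a
protein), a size-matched **non-interface patch** (a random connected set of
non-interface surface residues, the training negative), and **centered
patches** (each surface residue plus its *k* = 5 nearest surface
neighbors, the prediction-time unit — one patch, one score, per residue).
Two residues are in contact when the closest distance between their heavy
atoms is below the sum of the atoms' van der Waals radii plus 0.5 Å. The
contact graph of a patch is then transformed into its **shortest-path
graph** (same nodes; one edge per connected pair, weighted by the
hop-count shortest distance, computed with Floyd–Warshall).

**3. The kernel.** Two shortest-path graphs are compared edge against
edge:

$$K(G_1, G_2) = \sum_{e_1 \in E_1} \sum_{e_2 \in E_2}
  k_{node}(v_1, v_2)\; k_{weight}(e_1, e_2)\; k_{node}(w_1, w_2)$$

with a Gaussian node kernel
$k_{node}(v, w) = \exp(-\gamma \lVert labels(v) - labels(w)\rVert^2)$ and a
Brownian-bridge weight kernel
$k_{weight}(e_1, e_2) = \max(0,\; c - |w_1 - w_2|)$.

**4. The voting classifier.** Kernel magnitudes grow with graph size, so a
raw $K$ comparison between differently sized patches is meaningless.
Instead, for every training protein the query is compared with that
protein's interface and non-interface patches — which have the same node
count by construction — and $K(G, G_{int}) > K(G, G_{non})$ casts one vote.
The query is labeled *interface* when votes exceed half the training-set
size (strictly). Vote counts also serve as a ranking score: sorting a
protein's centered patches by votes puts the most interface-like patch
first, and thresholding the vote count traces a ROC curve.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `gamma` | 72 | — | Gaussian node-kernel coefficient, $1/(2\delta^2)$; cross-validated accuracy peaks here and varies little over 32–128 |
| `c` | 2 | hops | Brownian-bridge cutoff; weight gaps ≥ `c` contribute nothing; accuracy is insensitive over 1–5 |
| contact pad | 0.5 | Å | added to the atom-radius sum in the contact rule |
| `k` | 5 | residues | neighbors per centered patch (patch size 6) |
| interface Δ | 1.0 | Å² | ASA-loss threshold, inclusive |
| surface cutoff | 5 | % | relative accessibility, strict |
| radii | C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 | Å | element radius table, overridable via config |

`gamma` acts on squared distances in the unit cube of normalized
attributes: at `gamma = 72`, a Euclidean label distance of 0.1 already
drops the node kernel to `exp(-0.72) ≈ 0.49`, so only closely matching
residue pairs contribute. Exposing `gamma` directly (rather than
$\delta$) matches how the quantity is calibrated.

## Design choices where the design was open

- **Hop counts, not Ångströms.** Contact edges carry no length, so "the
  shortest distance in the original graph" is a hop count; Floyd–Warshall
  over unit weights (equivalent to BFS, and verified against an
  independent BFS oracle in the tests). Physical-distance path lengths are
  a deliberate non-goal.
- **Disconnected node pairs** get *no* edge in the shortest-path graph:
  the Brownian bridge is undefined at infinite weight, and omission is the
  standard shortest-path-kernel convention. A patch that is entirely
  edgeless contributes a kernel value of 0 (with a warning).
- **Ordered-edge enumeration.** Undirected edges have no canonical
  orientation for the $k_{node}(v_1,v_2) \cdot k_{node}(w_1,w_2)$ pairing.
  Both orientations of every edge are enumerated in both graphs, which
  covers the two possible matchings symmetrically and guarantees
  $K(G_1,G_2)=K(G_2,G_1)$. The uniform factor of 4 this introduces cancels
  in the classifier, which only ever compares $K$ values against
  size-matched alternatives (a single-edge self-comparison with identical
  labels therefore evaluates to $4 \times 1 \times 2 \times 1 = 8$).
- **Normalization scope.** Min–max extremes are taken dataset-wide over
  the training residues, not per protein: the kernel compares residues
  *across* proteins, and per-protein scaling would make identical residues
  look different. In cross-validation the normalizer is refit on each
  fold's training proteins and applied (with clipping) to the held-out
  protein. Negative attributes such as electrostatic potential get no
  special transform — min–max handles them like any other column.
- **Ties.** A kernel tie $K(G,G_{int}) = K(G,G_{non})$ casts no vote
  (strict inequality); a vote count of exactly half the training set is
  classified non-interface (strict majority); equal vote counts in a
  ranking are ordered by center residue key so top-*k* output is
  reproducible.
- **Residue-level scores.** The per-residue score used for the ROC is the
  vote count of the patch *centered* on the residue — the only
  construction that yields exactly one score per surface residue. The
  residue's own interface status is its ground truth.
- **Centered-patch neighbor metric.** "Nearest" uses the minimum
  heavy-atom distance, the same metric as the contact rule, with
  lexicographic key tie-breaks; the neighbor pool is restricted to surface
  residues so patches stay on the surface.
- **Interface patches may be disconnected** — no connectivity is imposed
  on them; contiguity is required only of the sampled negative patch.

## The synthetic generator

Real inputs require seven external feature tools, so the package ships a
generator (`generate_protein()` / `generate_dataset()`) that emulates the
*statistical shape* of the task with fully controlled ground truth:

- Residues sit on a self-avoiding 3D random walk with 3.8 Å steps (one
  carbon-like atom each, so consecutive residues always satisfy the
  contact rule), confined to a sphere of radius
  $3.8 \cdot n^{1/3}$ Å so the chain packs into a globule with
  protein-like non-backbone contact density. Structures are redrawn
  (bounded retries) if the non-interface surface contact graph could not
  host a size-matched connected negative patch — a validity requirement of
  the training construction.
- A spatially coherent cluster of ⌈0.2 n⌉ residues (the residues nearest
  a random seed residue) is the interface; its ASA fields are synthesized
  to pass the ≥ 1 Å² rule, everything else fails it. 8% of non-interface
  residues are marked buried (relative accessibility < 5%); all others,
  and all interface residues, are surface.
- All 26 attributes draw from Gaussians with mean 0.4 and sd `noise_sd`
  (default 0.15), clipped to [0, 1]. On a random subset of 8 attributes —
  drawn once per dataset, mimicking the real situation where some features
  (PSSM) are informative and others (curvature, pocket) barely are — the
  interface mean is shifted by `separation`. At `separation = 1` the
  classes are nearly disjoint on the shifted attributes; at 0 they are
  identically distributed and classification must collapse to chance.
- A single root seed drives everything (walk, cluster, noise, buried set,
  per-protein derived seeds `seed + i`), so identical configurations are
  byte-identical on disk.

What the generator does **not** emulate: real side-chain geometry and
packing, correlated attribute structure (real PSSM columns co-vary with
conservation and accessibility), class imbalance across proteins, and the
idiosyncrasies of real DNA-binding sites (grooves, bends, multi-patch
interfaces). Passing the synthetic end-to-end checks therefore shows the
*machinery* is correct — graphs, kernel, voting, evaluation — not that the
accuracy figures transfer to real complexes, which additionally depend on
feature quality from the external tools.

## Numerical choices and degenerate inputs

- Floyd–Warshall runs on a dense matrix with `Inf` for non-edges; patch
  sizes are tens of residues, so no sparse machinery is needed.
- The kernel precomputes the node-pair Gaussian matrix and evaluates the
  edge-pair sum as vectorized outer products; an independent, deliberately
  naive quadruple-loop implementation in the test helpers must agree to
  1e-9.
- AUC integrates the trapezoid rule over the integer vote thresholds
  `|T| .. 0` plus the closing all-positive anchor; with tied integer
  scores this equals the midrank Mann–Whitney statistic, and the tests
  assert that equality to 1e-9.
- Degenerate inputs have defined behavior: a constant attribute normalizes
  to 0; an unfitted normalizer, a patch residue missing from the protein,
  unnormalized labels, an empty training set, an empty patch list, a
  single-class ROC, and an out-of-range threshold are all explicit errors;
  an edgeless graph yields kernel 0 with a warning rather than an error so
  a single isolated patch cannot abort a whole evaluation.

## Problem sizes in the shipped checks

The package's own evaluation protocol runs at 20 synthetic proteins of 60
residues (interface patches of 12, ~56 surface residues per protein,
~1120 scored residues in the residue-level ROC), chosen as the smallest
scale at which patch statistics are stable; the separation-recovery check
repeats cross-validation at three seeds for separations 1.0 and 0.
Expected behavior at these conditions: cross-validated patch accuracy at
the ceiling for separation 1.0, chance-level (binomial band around 0.5
over 40 patches) at separation 0, residue-level AUC well above 0.9, and a
coverage that rises with *k* while accuracy drifts down.

## Known limitations

- Features are consumed, never computed: no ASA, electrostatics,
  conservation or PSSM calculation from coordinates or sequence.
- The kernel is exact O(|E₁|·|E₂|); shortest-path graphs of large patches
  are near-complete, so very large interface patches (hundreds of
  residues) would get slow. No kernel approximation is provided.
- Vote counts are not calibrated probabilities, and no SVM (or other
  learner) is layered on the Gram matrix.
- The positive-semidefiniteness of the Gram matrix is sanity-checked
  numerically on small graph sets in the tests, not proven here.
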