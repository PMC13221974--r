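---
title: "Spherical-harmonics shape and electrostatics descriptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spherical-harmonics shape and electrostatics descriptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liraseek)
```

## The model

A small molecule's solvent-accessible envelope is treated as a *star-shaped*
surface: every ray from the molecular centre of geometry is assumed to cross
the surface exactly once, so the whole surface is a single-valued function
$r(\theta, \phi)$ on the unit sphere. For near-convex drug-like ligands this
is a good approximation; deep invaginations are invisible by construction
(the sampler keeps the *farthest* ray–sphere crossing), and a conformer for
which more than a configurable fraction of rays misses every atom sphere is
rejected outright rather than silently misrepresented.

Any square-integrable function on the sphere expands in an orthonormal real
spherical-harmonics basis,

$$f(\theta,\phi) = \sum_{\ell=0}^{\infty} \sum_{m=-\ell}^{\ell}
  a_{\ell m}\, Y_{\ell m}(\theta, \phi), \qquad
  a_{\ell m} = \int_\Omega f\, Y_{\ell m}\, d\Omega ,$$

and truncating at a band limit $L$ gives a compact, coarse-to-fine surface
code of $(L+1)^2$ numbers per channel. Two channels are expanded on the same
surface: the radius $r(\theta,\phi)$ in Å, and the electrostatic potential
at the surface points in kcal·mol⁻¹·e⁻¹.

The basis convention matters, because the forward quadrature and the
reconstruction must be exact inverses for band-limited fields:

$$Y_{\ell 0} = \bar P_{\ell 0}(\cos\theta), \qquad
  Y_{\ell m} = \sqrt{2}\,\bar P_{\ell m}(\cos\theta)\cos(m\phi)\ (m>0), \qquad
  Y_{\ell,-m} = \sqrt{2}\,\bar P_{\ell m}(\cos\theta)\sin(m\phi),$$

with $\bar P_{\ell m}$ the orthonormalized associated Legendre function
*without* the Condon–Shortley phase. The $\sqrt 2$ factor for $m \ne 0$ and
the azimuthal (not polar) angle in the trigonometric argument are the two
ingredients some printed statements of this basis drop; without them the
family is not orthonormal and nothing downstream (Parseval, rotation
invariance, the fingerprint algebra) holds. Orthonormality is enforced by a
test that checks the full Gram matrix on the quadrature grid against the
identity to 1e-10 up to $L = 15$.

### Quadrature

Coefficients are computed by weighted summation on a tensor-product grid:
Gauss–Legendre nodes in $\cos\theta$ (count `oversample_factor * (L+1)`)
crossed with uniform azimuths (count `oversample_factor * (2L+2)`), weights
summing to $4\pi$. An oversample factor of 1 already integrates products of
two basis functions of degree ≤ L exactly; the default of 2 adds headroom
because molecular surfaces are not band-limited. The default analysis grid
(L = 15, factor 2) has 32 × 64 = 2048 nodes.

### Fingerprints and the DRIF metric

Under a rigid rotation the degree-$\ell$ coefficient block transforms by an
orthogonal Wigner-D matrix, so the per-degree norms

$$A_\ell = \Big(\sum_m a_{\ell m}^2\Big)^{1/2}, \qquad
  A_L = \Big(\sum_{\ell \le L} A_\ell^2\Big)^{1/2}$$

are exactly rotation invariant: they are the rotation-invariant fingerprint
(RIF) of one channel. Two fingerprints are compared by

$$\mathrm{DRIF}^2 = A_L^2 + B_L^2 - 2 \sum_\ell A_\ell B_\ell
  = \sum_\ell (A_\ell - B_\ell)^2 ,$$

the squared Euclidean distance between amplitude vectors. The package
returns its square root by default — then DRIF is a true metric in the
channel's units (the triangle inequality is property-tested on random
triples) — and exposes the squared form as an option. Ranking by DRIF needs
no alignment at all; that is the point of the construction.

Because the two channels have different units, the combined screening score
is a dimensionless weighted sum, each channel's DRIF normalized by the
query's total amplitude in that channel, with an $\varepsilon$ floor so
neutral (zero-ESP) queries are well defined. The default shape weight of 0.5
treats the channels evenly; 1.0 reproduces pure shape ranking. Both
per-channel distances are always reported alongside the combined score, so
the weighting is transparent.

## Electrostatics

The surface potential is a point-charge Coulomb model evaluated at the
sampled surface points, $V(x) = k \sum_i q_i / |x - x_i|$ with
$k = 332.0636$ kcal·Å·mol⁻¹·e⁻², optionally with a distance-dependent
dielectric ($1/r^2$). Charges come from one of three models: Gasteiger
(computed by Open Babel from the molecule's connectivity), `file` (per-atom
charges read from PQR), or `zero` (shape-only screening). The
spherical-harmonics machinery is agnostic to where the surface values come
from — any higher-fidelity surface potential could be substituted per node
without touching the rest of the pipeline.

## Alignment

Hits are oriented onto the query by maximizing the normalized coefficient
correlation $C(R) = \sum_{\ell m} a_{\ell m} [D^\ell(R)\, b]_{\ell m} /
(\lVert a\rVert \lVert b\rVert)$ over rotations. Rather than an SO(3) FFT,
$C$ is evaluated directly on a $(2B)^3$ ZYZ Euler grid with $B = L + 1$: in
the complex basis the rotation factorizes as
$e^{-im'\alpha} d^\ell_{m'm}(\beta)\, e^{-im\gamma}$, so for each grid
$\beta$ the whole $(\alpha, \gamma)$ plane is two small complex matrix
products. At $L = 15$ that is 32 768 rotations in well under a second —
direct evaluation is simpler than the FFT and fast enough at every band
limit exposed here. The best grid point is polished by Nelder–Mead descent
on $-C(R)$; planted rotations are recovered to ~1e-6 rad on band-limited
inputs (the suite requires 0.02 rad over 50 random rotations).

The little-d matrices are built as matrix exponentials of the real
antisymmetric $J_y$ generator through a per-degree cached
eigendecomposition, which keeps every $d^\ell(\beta)$ orthogonal to machine
precision — degree norms are preserved exactly, which the RIF invariance
tests rely on.

Molecule-level superposition wraps this in an ICP-style loop: centre both
molecules at their centres of geometry, expand both surfaces, find the best
rotation, rotate the mover, re-expand, and repeat until the correlation
gain falls below `tol` (1e-4) or `max_iter` (10) is hit — non-convergence is
reported in the result, not thrown. Iterating matters because ray-cast
surfaces are not band-limited: the sampled field of the rotated molecule is
not exactly the Wigner-rotated field. A flat correlation landscape (top
grid values indistinguishable within 1e-6, as for spheres or highly
symmetric molecules) is flagged `degenerate` and resolved deterministically
by lexicographic Euler order.

## Screening

`build_db()` precomputes descriptors for every conformer of a library SDF
into a single-file columnar text container whose header records the build
parameters (band limit, probe, charge model, oversampling, radius table,
dielectric). `query_db()` refuses to scan unless the query is processed
with exactly those parameters — parameter drift between database and query
is a silent ranking killer, so it is a hard error. The scan itself is a flat
linear pass with bit-reproducible scores, ties broken lexicographically by
(compound, conformer), and at most `per_compound_cap` conformers (default
5) reported per compound. Amplitudes are serialized with `%.17g`, so
rebuilds and appends are byte-identical for identical inputs.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `L` | 15 | — | resolves drug-like surface detail; 6 is a fast preset that remains adequate for ranking |
| `oversample_factor` | 2 | — | quadrature headroom for non-band-limited fields |
| `probe_radius` | 1.4 | Å | water-probe solvent-accessible envelope; 0 gives the bare vdW surface |
| `miss_fraction_threshold` | 0.05 | — | tolerated star-shape violation before hard failure |
| `charge_method` | gasteiger | — | standard empirical charges; `file`/`zero` for PQR input / shape-only |
| `dielectric_model` | vacuum | — | plain Coulomb; `distance_dependent` screens like $1/r^2$ |
| `shape_weight` | 0.5 | — | even channel weighting in the combined score |
| `per_compound_cap` | 5 | — | conformers reported per compound |
| ICP `tol`, `max_iter` | 1e-4, 10 | — | correlation-gain stop; cap returns `converged = FALSE` |

## What the synthetic generators emulate — and what they do not

The fixtures exist so every numerical claim is testable without downloads:

* **Spheres and ellipsoids** have closed-form expansions ($a_{00} =
  r\sqrt{4\pi}$; axis permutations are rotations) and bypass the molecular
  path entirely, isolating the harmonics core.
* **Band-limited random fields** (coefficients $\sim N(0, \mathrm{decay}^\ell)$,
  decay 0.8, monopole shifted to keep radius channels positive) are exact
  round-trip and rotation oracles.
* **Random-walk molecules** (1.5 Å steps, self-avoiding, radii from
  {1.2, 1.5, 1.7} Å, charges $\sim N(0, 0.1\,e)$ recentred to exact
  neutrality) exercise realistic surface complexity at molecular scale.
  They are *not* chemically valid — no valence, no sterics — so tests built
  on them certify the geometry and algebra, not chemistry.
* **Decoy libraries** name records `CPDk_confj`; conformers of one compound
  are rigid rotations of its base geometry, so the per-compound cap and
  rotation-invariance claims are exercised, but real conformational
  flexibility (torsions) is not emulated. Retrieval results on decoys
  demonstrate self-retrieval under jitter, not enrichment of true actives.
* **The drug-like set** is 20 committed conformers (distance-geometry
  embedding + MMFF94s minimization, generated once and stored as static
  coordinates with explicit hydrogens) spanning 12–39 atoms. It grounds the
  fidelity benchmarks in real molecular geometry; it is one conformer per
  compound, so it says nothing about conformer ensembles.

## Numerical choices and degenerate inputs

* Legendre functions use the stable normalized upward recursion — no
  factorials, safe far beyond degree 64; validated against sectoral closed
  forms at $\ell = 40$.
* The one-point Gauss–Legendre rule ($L=0$, oversample 1) is special-cased.
* Ray misses are filled with the centre-to-nearest-sphere distance and
  flagged; all-miss is a hard error (centre outside the envelope).
* Tangent rays (discriminant ≈ 0) legitimately yield near-zero crossings;
  the far-intersection max over atoms makes them irrelevant except for
  pathological two-sphere toys.
* A surface point closer than 1e-6 Å to an atom centre aborts ESP sampling
  (impossible for genuine outer-envelope points).
* Euler extraction at the gimbal poles ($\beta \in \{0, \pi\}$) fixes
  $\gamma = 0$.
* Score ties in the scan break by (compound_id, conformer_id); the SO(3)
  grid keeps the first maximizer in lexicographic Euler order when the
  landscape is flat.

## Problem sizes used by the test and benchmark suites

The shipped suites run at desk scale: fidelity benchmarks over the 20
committed conformers on the 2048-node L = 15 grid; planted-rotation
recovery over 50 random rotations; retrieval with a 0.05 Å-jittered planted
copy among 999 synthetic decoy conformers (333 compounds × 3 rigid-rotation
conformers); scan-scaling checks on 40- and 160-record libraries. These
sizes were chosen as the smallest that exercise every claimed property with
comfortable statistical margin.

## Known limitations

* The star-shaped representation cannot encode interior cavities or
  strongly concave pockets; such conformers either lose detail or trip the
  miss-fraction guard.
* The point-charge ESP is a deliberate simplification: smoother than
  quantum-derived surface potentials, hence easier to truncate. Fidelity
  numbers for the ESP channel should be read as upper-bound truncation
  checks on this model, not as statements about any particular
  quantum-mechanical reference.
* Gasteiger charges require connectivity; PDB input must either come with
  PQR charges or use the `zero` model.
* Alignment of highly symmetric molecules is inherently ambiguous; the
  `degenerate` flag reports it rather than pretending a unique optimum.
* The linear scan is sufficient for desk-scale libraries (thousands of
  conformers per second per core after descriptor precomputation); no
  sharded or approximate index is provided.
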