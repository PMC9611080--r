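---
title: "fingerphantom: model, transport algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fingerphantom: model, transport algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what the package models, how the numerics work, and
which choices were open design decisions. It is the reference for anyone
who wants to trust, modify or extend the phantom or the transport engine.

## 1. The phantom

### Grid and axes

The label volume is a 3D integer grid: 160 × 320 × 133 voxels at 0.2 mm
isotropic pitch, 6,809,600 voxels in total. `x` is the finger width, `y`
the long axis (proximal at `y = 0`, fingertip at the far end), `z` the
depth axis along which light is propagated (volar side at low `z`).
Voxels are addressed 0-based in the engine; voxel centres sit at
`(i + 0.5) * pitch`; physical extents are half-open. Label 0 is the
ambient medium; labels 1–15 are tissues. Label 13 carries two names —
*synovial membrane* and *joint capsule* — because the model does not
separate the capsule from its synovial lining.

### Geometry

The anatomy is idealized but dimensionally realistic:

* **Outer shape** — a superellipse cross-section
  (|x/rx|^2.5 + |z/rz|^2.5 ≤ 1) with rz = 0.88 rx, a piecewise-linear
  radius profile along y (7.8 mm proximally, tapering to 5.8 mm before the
  tip, closed by an elliptical tip cap), and gentle waists of ≈ 0.4 mm at
  the two joint lines: skin is anchored at the flexion creases, so soft
  tissue thins over the joints.
* **Skin** — an epidermis shell of 0.4 mm (palmar epidermis is thick) and
  a dermis shell of 1.2 mm, produced by shrinking the superellipse radii;
  the subcutis mask is the whole finger interior and, ranking last in the
  priority list, receives every voxel nothing else claims.
* **Phalanges** — three elliptical cylinders (proximal 4.4 × 3.0 mm
  half-axes, middle 3.8 × 2.6, distal 2.8 × 2.0), shifted 0.6 mm dorsally
  (volar flattening leaves the flexor compartment free), with flat
  joint-facing ends so the joint gap contains no bone. Mid-shaft phalanx
  widths of 7–9 mm are deliberate: the bones fill most of the finger core,
  leaving a ≈ 1 mm subcutaneous ring, as in adult anatomy.
* **Joints** — at the proximal and distal interphalangeal lines (PIP at
  y = 24.5 mm, DIP at 42.5 mm): 0.4 mm cartilage discs cap the bone ends;
  between them an elliptical synovial-fluid lens (PIP: 2.6 × 2.4 mm
  half-axes, 1.8 mm thick) surrounded by a 0.45 mm synovial membrane /
  capsule shell. The lens is kept well inside the bone silhouette so that
  a 7.5-fold effusion still fits the grid (section 2).
* **Tendons** — flexor (2.2 × 0.9 mm half-axes) and extensor
  (2.0 × 0.55 mm) elliptical tracks running the full y extent, riding the
  volar/dorsal bone surface with small clearances and clamped inside the
  finger interior; the A4 pulley is a 0.4 mm annular sheath around the
  flexor over the mid phalanx (y 33.5–35.5 mm).
* **Small structures** — collateral ligaments (0.6 mm radius capsules
  beside each joint), volar plates (blocks between bone and flexor tendon
  at each joint), paired digital arteries (0.45 mm radius), veins and
  nerves (0.4 mm) at fixed fractions of the inner cross-section so they
  taper with the finger, and six 0.5 mm Pacinian corpuscles in the volar
  subcutis.

All lengths are `phantom_params()` fields and can be overridden
individually. The only randomness is optional jitter on corpuscle centres
(`jitter_mm`, default 0), seeded explicitly; by default generation is a
pure function and bit-reproducible.

### Overlap resolution and cleanup

Masks are built independently per tissue, so overlaps are inevitable and
intentional (ligaments overlay bone, the membrane shell overlaps the
cavity). Each voxel receives the claimant with the best priority rank.
The default ranking puts fine structures first — vessels, nerves,
corpuscles, cartilage, the synovial space, pulley, ligaments, plates —
then tendon, bone, the skin shells, and subcutis last, because structures
that are locally one or two voxels thick must never be overwritten by the
bulky tissues around them. The ranking is data (`tissue_table(priority =)`),
not code.

The cleanup pass enforces 6-neighbourhood consistency: any voxel with no
in-grid 6-neighbour of its own label (ambient counts as a label) is
reassigned to the modal label of its neighbours, ties broken toward the
smallest id for determinism. The unanimous case of this rule is exactly the
single-voxel hole fill. Decisions in one sweep are simultaneous (taken on
the input state), and sweeps repeat until a fixed point, which makes the
operation idempotent; the sweep cap (25) has never been reached in
practice — the default phantom settles in one or two sweeps.

`validate_phantom()` reports per-label voxel counts, the label partition
identity, two containment checks (every tissue voxel exposed to ambient is
epidermis; bone is never exposed) and per-label 6-connected component
counts. Checks are flags, not errors, so defective volumes can be
inspected.

## 2. Disease-state transforms

### Joint inflammation

The targets are volume ratios: synovial fluid × 7.5 and membrane × 3 in
the combined preset (`inflammation_preset()` also provides fluid-only and
membrane-only states). The transform acts on transverse (x–z) slices
within an axial window (default 8 mm, cosine-tapered, centred on the PIP
joint): each slice is remapped radially about the joint centroid with a
piecewise-linear profile in the radius built from equivalent-disk radii of
the slice's bone+cartilage, cavity and membrane areas — the core inside
the bone radius is rigid, the cavity band is dilated, the membrane band is
dilated independently, and everything beyond is displaced outward rigidly
(the finger visibly swells). Labels are categorical, so resampling is
nearest-neighbour throughout.

Because voxelization makes the achieved ratio a step function of the
stretch amplitude, the amplitudes are solved numerically: bisection on the
achieved cavity count (then, holding it fixed, on the membrane count),
terminating when within 0.3 % of the target or after 24 iterations. The
achieved ratios are returned as an attribute and are typically within
1–2 % of the targets; the contract tested is 5 %, the voxelization
tolerance. Unit factors return the input object unchanged. If a requested
swelling cannot fit between the joint centroid and the grid edge the
transform stops with an explicit error rather than clipping anatomy.

Measurement convention: the ratios are counted inside the axial window of
the transformed joint. The phantom has a second (DIP) joint that the
transform does not touch; whole-volume counts would mix the two and
understate the local effect.

### Tendon rupture and geometric scaling

Rupture relabels tendon voxels with y in a half-open range to subcutis —
the surrounding filler — and touches nothing else; no contraction or
retraction is modelled. Scaling resamples to `round(f * dim)` voxels per
axis with nearest neighbour; the voxel pitch is unchanged, so the finger
physically shrinks or grows, and no new label can appear. Up-then-down
round trips are exact; down-then-up round trips preserve volume fractions
of the bulky labels to ≈ 3 % but alias structures at or below the
resampling cell (the 2-voxel cartilage discs lose up to half their volume
at f = 0.5) — an inherent property of categorical resampling, stated here
so nobody mistakes it for a defect.

## 3. Optical properties

`default_spectra()` builds the shipped table over 400–1100 nm in 10 nm
steps from a small chromophore model, per tissue: absorption is
B·(S·μa,HbO2 + (1−S)·μa,Hb) + W·μa,water + M·μa,melanosome + 0.005 mm⁻¹,
with blood volume fraction B, oxygen saturation S = 0.75 (0.98 in
arteries, 0.60 in veins), water fraction W and, for the epidermis only, a
melanosome fraction M = 0.03. Haemoglobin and water use coarse extinction
knot tables interpolated linearly; reduced scattering follows
μs′ = a·(λ/500 nm)^(−b) and μs = μs′/(1−g) with fixed g and n per tissue.
Everything is stored in mm⁻¹.

Values are literature-style class defaults, not subject measurements;
choices worth flagging: bone carries B = 0.05 and W = 0.25 for its marrow
(μa ≈ 0.03 mm⁻¹ at 860 nm, within the published bone range) and a
scattering amplitude at the upper literature end (μs′ ≈ 2.2–2.7 mm⁻¹ in
the red/NIR) so that the phalanges act as the optical obstacle they are;
articular cartilage is nearly transparent (μs′ ≈ 0.2–0.3 mm⁻¹), and the
synovial fluid is essentially water with trace scattering and n = 1.345.
The whole table is replaceable via `load_spectra()` (CSV, mm⁻¹ or cm⁻¹
with conversion), and validation enforces μa, μs ≥ 0, −1 < g < 1, n ≥ 1,
unique wavelengths per tissue and, for full tables, 400–1100 nm coverage
of all 15 tissues.

Arthritic property changes are layered on as named override sets
(`apply_spectra_overrides()`, data frame or YAML; an illustrative template
ships in `inst/extdata/arthritic_overrides.yaml`): per-tissue
multiplicative factors or absolute replacements of one property across all
wavelengths.

`properties_at()` returns exact rows on grid points, linear interpolation
between, an error outside the tabulated range, and the fixed ambient
row (μa = μs = 0, n = 1) for id 0.

## 4. The Monte Carlo engine

Packets of weight 1 enter the grid perfectly collimated along +z,
uniformly over the z = 0 face, with a Fresnel event at the entry face
(specular reflection is recorded in the reflectance image). Propagation is
the classic hop–drop–spin scheme extended to a voxel grid:

1. a dimensionless step −ln(u) is consumed voxel by voxel, each sub-segment
   costing μt × length; vacuum voxels (μt = 0) are crossed ballistically;
2. at the interaction point a fraction μa/μt of the weight is deposited in
   the containing voxel (recorded in the optional 3D absorbed grid), then
   Russian roulette below w = 10⁻⁴ (survive with probability 1/10 at ×10
   weight — unbiased), then a Henyey–Greenstein spin with the local g;
3. at every voxel face where the refractive index differs, the unpolarized
   Fresnel reflectance decides stochastically between specular reflection
   (the normal direction component flips) and Snell refraction (tangential
   components scaled by n1/n2, normal component set to the refracted
   cosine); total internal reflection falls out of the same formula.
   Grazing hits (|cos| < 10⁻¹²) are treated as pure reflections to avoid
   division blow-ups;
4. the lateral x/y grid limits are mirrors (the model approximates a
   laterally extended medium); the z faces are the recording planes:
   packets crossing them into ambient add their full weight to the
   transmittance (forward) or reflectance (backward) image at the (x, y)
   pixel of the crossing, and totals R, T, A are normalized by the
   launched count. With absorption recorded, R + T + A = 1 up to roulette
   noise (≲ 10⁻⁶ relative in practice; the contract tested is 10⁻³).

Each packet owns a PCG32 stream seeded by hashing (master seed, packet
index, wavelength substream), so results are bit-identical for a fixed
seed regardless of execution order, and `spectral_sweep()` wavelengths are
statistically independent; a sweep of length one reproduces
`run_simulation()` exactly. A per-packet event guard (5 × 10⁷) catches
pathological orbits; weight lost that way is reported separately and is
zero in all shipped configurations.

### Verification

The engine is tested against independent oracles: exact Beer–Lambert
transmittance of pure absorbers at optical depths 0.5–2; the 4 %
normal-incidence specular reflectance of an n = 1.5 absorbing slab; the
mean Henyey–Greenstein polar cosine equal to g; energy closure with the
absorbed grid; invariance of slab results to the lateral grid size
(the mirror condition at work); and the published benchmark for a
scattering slab of optical thickness 2, single-scattering albedo 0.9,
g = 0.75 and matched boundaries, whose total diffuse reflectance 0.09739
and transmittance 0.66096 are van de Hulst's adding–doubling values. A
caution for future maintainers: that reference value belongs to the finite
slab — a *semi-infinite* medium with the same optical properties reflects
≈ 0.165 (we re-derived both numbers with a standalone vectorized MC
checked against the exact isotropic H-function result before trusting the
engine test).

## 5. Imaging utilities

Thickness projections sum voxel counts along one axis times the pitch;
projecting along x gives the sagittal view. The volume-conservation
identity (sum of map × pixel area = voxel count × voxel volume) is tested
for all 15 tissues. Spectral band integration is the unweighted mean of
the in-band images (the 650–760 nm band of the default grid averages 12
wavelengths); the log display transform is log10 after clamping at a
positive floor.

## 6. File formats and CLI

Volumes round-trip through NIfTI-1 (int32, pitch in the header pixdim) or
raw little-endian int32 with a JSON sidecar; float-valued files are
rejected. Simulation images are written as uncompressed 32-bit float TIFF
with a JSON sidecar for totals and metadata; sweep stacks become
multi-image TIFFs — a deliberately simple, dependency-light stack format
that also keeps outputs byte-deterministic. Meshes are extracted by
marching tetrahedra: each cell of 8 voxel-centre nodes is split into six
tetrahedra around a consistent main diagonal, so face diagonals match
between neighbouring cells and the iso-0.5 surface is watertight; the mask
is zero-padded so boundary-touching structures close. We chose the
tetrahedral decomposition over classic 256-case marching cubes because it
needs no case tables, has no ambiguous configurations, and its output is
easy to audit (the single-voxel surface has Euler characteristic 2, as
does a voxelized ball). Laplacian smoothing (uniform weights, λ = 0.5)
moves vertices toward their neighbourhood mean and never changes vertex or
triangle counts. STL export is little-endian binary with normals
recomputed from the winding.

The `cli()` function (wrapped by `inst/scripts/fingerphantom`) exposes
generate / transform / simulate / project / export-mesh; a YAML config can
supply any flag's default. All subcommands are thin calls into the
functions above, so library results and CLI results are bit-identical.

## 7. What the synthetic phantom does and does not emulate

The generator reproduces the *structural statistics* of a segmented
finger — tissue inventory, layer nesting, realistic calibres and
positions, joint architecture — not the anatomy of any individual: real
phalanges are waisted and asymmetric, real synovial recesses wrap the
condyles irregularly, real tissue boundaries are rough at the voxel scale,
and real segmentations contain label noise that our cleanup pass would
actually have to fight. Consequently, tests passing on the phantom
demonstrate the correctness of the algorithms (priority merge, cleanup,
transforms, transport, projections) and the qualitative transillumination
physics, but say nothing about segmentation accuracy on real MRI, which is
out of scope.

Desk-scale statistics deserve a separate caveat. At full scale and
realistic optical properties, the finger transmits so little light through
its core that interior image structure needs on the order of 10⁸ packets
to resolve — the scale of the original GPU simulations. The packaged
qualitative check therefore runs 10⁶ packets at 650 nm (inside the
650–760 nm band where blood absorption makes bony versus bloodless regions
differ most) on a half-scale phantom, where the joint-line brightening and
the edge-versus-centre ordering are resolvable on region means. On the
full-scale phantom the same orderings are present but sit within Monte
Carlo noise at 10⁶ packets; lateral diffusion over a ~12 mm thick medium
blurs features below ≈ 8 mm regardless of packet count.

## 8. Numerical choices, in one place

* Cleanup tie-break: smallest label id; neighbourhood: 6-connected;
  out-of-grid neighbours ignored.
* Inflammation: cosine axial taper; equivalent-disk piecewise radial map;
  bisection with 0.3 % early stop, 24 iterations max, amplitude bracket
  grown geometrically; capacity check against the nearest x/z grid edge
  with a 0.4 mm margin.
* Scaling: `src = clamp(ceiling((i − 0.5)/f))`, which makes f = 1 exact.
* Engine: roulette w_th = 10⁻⁴, m = 10; grazing threshold 10⁻¹²; entry
  face Fresnel against n = 1; absorbed energy deposited at the interaction
  voxel (not spread along the path).
* RNG: PCG32, one stream per packet, seeds derived via splitmix64 hashing;
  no state shared between packets.
* Mesh: iso-level 0.5 on the binary mask, edge midpoints as vertices,
  vertices welded by lattice-edge key; triangle orientation fixed per
  tetrahedron by the inside-centroid test.
* Test problem sizes: oracle grids ≤ 32³; engine oracles at 10⁵–10⁶
  packets; the qualitative transillumination check at 10⁶ packets on the
  half-scale phantom.
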