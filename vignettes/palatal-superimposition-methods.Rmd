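---
title: "Methods: palatal-vault superimposition and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: palatal-vault superimposition and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palatesup)
```

## The problem

Orthodontic treatment moves teeth by millimetres over months. Quantifying
that movement in three dimensions requires bringing two acquisitions of the
same maxilla — a pre-treatment and a post-treatment digital dental model —
into a common coordinate system, using a structure that treatment does not
move. Radiographic (CBCT) superimposition can anchor on bone, but exposes
the patient to radiation. Digital dental models (laser-scanned casts or
intraoral scans) are radiation-free, but contain no bone: the only
plausibly stable structure they show is the mucosa of the palatal vault.
The anterior palatal rugae deform with tooth movement; the medial part of
the third ruga and the vault dorsal to it have been reported stable to
within about half a millimetre.

`palatesup` implements this palatal-vault superimposition and — its main
purpose — a validation harness for it: both a palatal-vault route and a
reference (CBCT-anchored) route bring the post-treatment model into the
pre-treatment space, teeth are measured identically on both superimposed
models, and the signed differences between routes quantify the method's
accuracy, with intraclass correlation coefficients over repeated sessions
quantifying reliability. Since no patient scan pairs are distributed with
the package, a synthetic palate phantom with analytic ground truth stands
in for them; every quantitative claim the package makes is checked against
that ground truth.

## Registration model

Superimposition is rigid: a dental model reproduces the anatomy at 1:1
scale, so only a rotation $R$ (proper, $\det R = +1$) and translation $t$
are estimated, never scale.

**Coarse alignment.** Every registration is seeded by a least-squares
rigid fit (Kabsch/SVD) of at least three matched, non-collinear landmarks
— here the two palatal-suture points plus three rugae/papilla alignment
points. This mirrors the landmark pre-alignment used by clinical software
before any surface optimisation, and it matters: the palatal vault is
smooth, so the surface objective has long, shallow valleys in which a
poorly seeded optimisation creeps slowly. With a sensible landmark seed
the iterative stage converges in a handful of iterations.

**Fine registration.** Region-restricted trimmed point-to-surface ICP.
Sample points are the masked region's vertices plus face barycentres
(edge midpoints are added for sparse masks so at least ~500 samples
constrain the fit, with a deterministic stride cap at 4000). Each
iteration: (1) each sample is matched to its exact nearest point on the
fixed triangle mesh (point-to-triangle distance, computed in compiled
code with bounding-sphere pruning); (2) correspondences farther than
`gate_factor` (default 5) times the current RMS are rejected, guarding
against boundary capture; (3) the worst `trim` fraction (default 10%) of
the remainder is discarded, mimicking the robust best-fit of commercial
tools and de-weighting soft-tissue edge effects; (4) the rigid update is
the Kabsch fit of the original samples to the surviving foot points, and
is accepted only if the trimmed RMS does not increase. The objective is
therefore monotone non-increasing across accepted iterations.
Convergence: relative RMS change below `tol` (default 1e-6), an absolute
RMS below 1e-9 mm, or `max_iter` (default 100). For noisy surfaces the
RMS plateaus at the noise floor and the relative-change criterion is
slow to trigger; the cohort analyses therefore run with `max_iter = 30`,
`tol = 1e-5`, which on the noisy phantom lands as close to the true pose
as the full 100-iteration run (both within the ~0.01 mm / ~0.02 degree
registration noise floor).

Near-planar regions (smallest singular value of the centred sample cloud
below 1e-4 of the largest) are flagged `degenerate_region` rather than
refused: a plane constrains three of the six degrees of freedom well and
the flag tells the analyst to scrutinise the rest.

## Measurement model

**Coordinate frame.** The functional occlusal plane (FOP) is fitted by
orthogonal least squares (total least squares; the normal is the smallest
singular vector of the centred cusp cloud) to 14 cusp points: buccal and
lingual cusps of both first and second premolars, and the mesial-buccal,
distal-buccal and mesial-lingual cusps of both first molars — the
distal-lingual molar cusp is excluded. Whether lingual premolar cusps
belong in the fit is ambiguous in the clinical literature; the package
defaults to all cusps as listed (`cusp_set = "all"`, 14 points) with a
buccal-only option (8 points). The FOP normal's sign is fixed by
convention so the posterior suture point B (gingival to the occlusal
surface) has positive offset; every angle sign follows from this. With A
and B marked on the palatal suture and A′, B′ their FOP projections, the
frame is: origin B′, x = B′→A′ (anterior, in the FOP), y = B′→B (the FOP
normal), z = x × y (transverse, right-handed). A is taken as the anterior
point, so +x points anteriorly — a convention the package declares rather
than inherits. Frame construction commutes with rigid motion
(equivariance), so measured coordinates do not depend on the pose in which
a model happens to sit; this is tested.

**Tooth measurement.** Position is the frame coordinate of one landmark:
the mesial-buccal cusp for a first molar (U6), the incisal-edge midpoint
for a central incisor (U1). Orientation uses the tooth's own planes: the
*mesiodistal plane* contains the mesial and distal groove/edge points and
their FOP projections (a vertical plane along the tooth's mesiodistal
direction); the *buccolingual plane* is perpendicular to both the
mesiodistal plane and the FOP, anchored at the tooth-axis midpoint (the
anchor affects no angle). The tooth axis joins the most occlusal and most
gingival points of the molar's buccal groove, or the incisal- and
gingival-edge midpoints of the incisor. *Torque* is the signed angle
between the axis's projection onto the mesiodistal plane and the FOP
normal; *tip* the same with the buccolingual plane. This protocol-literal
assignment is the reverse of common orthodontic usage; a
`swap_tip_torque` switch relabels the two if desired, defaulting to the
literal protocol.

Angle conventions the protocol leaves open were fixed as follows. The
projected axis is treated as a *line*: it is canonicalised to the
gingival side of the FOP normal before signing, so the angle lies in
(−90°, 90°], is invariant to swapping the axis endpoints, and is zero for
an upright tooth regardless of which way the axis vector points. The sign
is positive when the projected axis leans toward the frame's +x axis
(torque) or +z axis (tip); when the relevant in-plane direction is nearly
orthogonal to the preferred axis (as the mesiodistal direction of an
incisor is to +x), a deterministic fallback through the remaining frame
axes keeps the sign reproducible.

**Crown transfer.** To compare the two routes without re-identifying
landmarks on each superimposed model — which would mix landmark
identification error into the superimposition comparison — each crown
patch is copied (mesh restriction to the crown mask) from the
reference-superimposed model, rigidly registered onto the
palatal-vault-superimposed model by the same ICP, and its bonded
landmarks are carried along by the recovered transform. When the two
superimposed models are identical the transfer is exact and every
deviation is zero to numerical precision; this null property is tested at
1e-9.

## Statistics

Signed deviations are (palatal-vault route) − (reference route), per
subject, per tooth, in x, y, z (plus the Euclidean `total`), tip and
torque. Accuracy tables report mean, SD and a conventional two-sided
one-sample t-test against zero per variable (α = 0.05, no
multiple-testing correction — matching standard practice for this
design). The `total` rows are non-negative by construction, so their
t-test against zero is reported but is not a test of unbiasedness.

Reliability uses the single-measurement intraclass correlation
coefficient computed from the two-way ANOVA mean squares. The model is
configurable: the default ICC(2,1) (two-way random effects, absolute
agreement) treats examiners/sessions as random and penalises systematic
offsets; ICC(3,1) (consistency) is available. Intra-examiner ICC pairs an
examiner's two sessions; inter-examiner ICC pairs the two examiners'
first sessions. Degenerate layouts are handled exactly: perfect agreement
gives ICC = 1; zero between-subject variance raises a warning because the
coefficient is then meaningless.

## The synthetic phantom

The phantom emulates the study inputs in a canonical space where the
answer is known exactly:

* **Palate**: a super-elliptic dome, 38 mm long, 44 mm wide, 13 mm high,
  with three sinusoidal rugae-like ridges (0.5 mm amplitude, 4 mm
  wavelength) in the anterior third. The stable region — the medial band
  of the third ruga and the vault dorsal to it — is emitted as an
  explicit face mask.
* **Teeth**: four measurable crowns (both U6s and U1s) as superellipsoid
  solids placed on a parabolic arch, plus premolar cusp landmarks for the
  FOP fit. Landmark constellations are built directly in world
  coordinates from the requested (position, tip, torque): the
  groove/edge points run horizontally along the arch tangent and the
  axis is $n + \tan(\text{torque})\,t_{md} + \tan(\text{tip})\,t_{bl}$
  with exactly the in-plane directions the measurement uses. A rigid
  template cannot do this — the mesiodistal plane is landmark-derived,
  so carrying exact angles across poses requires constructing, not
  transforming. Consequently, with the default coplanar cusps,
  *parameters in = measurements out* to machine precision, which is the
  package's strongest self-check (asserted at 1e-6 mm / 1e-6 degrees).
* **Ground truth**: computed from the analytic landmark coordinates —
  never from the meshes — through the measurement definitions, for both
  time points. Treatment motions are per-tooth rigid transforms about
  the crown centroid; the global pose difference between acquisitions is
  a rigid transform standing in for the validated volumetric (voxel)
  superimposition, which the package deliberately represents as an
  injected transform rather than re-implementing greyscale registration.
* **Noise**: Gaussian vertex displacement along surface normals on the
  second acquisition, 0.05 mm SD outside the stable region and 0.02 mm
  inside by default (the stable region is soft tissue, hence separately
  configurable), plus an optional smooth low-frequency palate "drift"
  mode for stress-testing the stable-region assumption. Landmark
  identification noise is injected separately, on landmark coordinates
  only, because the crown-transfer step exists precisely to separate
  those two error sources.
* **Cohorts**: per-subject randomised anatomy (tooth placement within
  ±1.2 mm, angulations within ±3°, dome dimensions within ~±8%, and
  vertical tooth jitter so molar heights vary between subjects),
  treatment motions within ±1.2 mm / ±6°, and global poses of 2–9°
  rotation and 1–4.5 mm translation. Treatment magnitudes are declared
  simulation parameters — typical of fixed-appliance treatment — not
  measured values. All randomness flows through one seeded generator;
  identical seeds give identical STL bytes.

What the phantom does *not* emulate: real anatomical shape variation (no
statistical shape model), cast defects and bubbles, scanner-specific
artefact structure, and genuine soft-tissue remodelling of the rugae.
Passing phantom tests therefore demonstrates the correctness of the
algorithms and the internal consistency of the pipeline, not the clinical
stability of the palatal vault — which only patient data can establish.

## Numerical choices

* Vertex welding on STL read is exact-coordinate, not tolerance-based, so
  landmark-to-surface relationships survive a round trip. ASCII STL is
  written at 17 significant digits (lossless for doubles); binary STL is
  float32 by format, hence quantised at ~1e-7 relative.
* Plane fits and rigid fits use SVD; reflections are rejected by sign
  correction, and every produced rotation satisfies det = +1 (tested).
* Degenerate inputs error early with specific messages: collinear
  landmark constellations, suture perpendicular to the FOP, coincident
  axis endpoints, mesiodistal segments perpendicular to the FOP,
  constant t-test input, missing ICC cells, overlapping crowns after a
  requested treatment motion.
* Ties in ICP trimming are broken by stable ordering; sampling is
  deterministic, so the whole registration is reproducible without a
  seed.

## Problem sizes in the shipped analyses

The default phantom has ~2,500 vertices and ~4,800 faces per model
(≈1,700 stable-region faces); unit tests use a reduced grid. The shipped
validation analyses use: single phantoms for pose recovery and
stable-region insensitivity; a 20-subject zero-noise cohort (with a
10-subject, two-examiner, repeated-session reliability arm) for the
degenerate limit of the report; a 200-subject cohort, measured through
the injected-transform registration route, for landmark-noise parameter
recovery (the quantity under test there is the measurement/statistics
chain, with the registration stages validated separately); and a
20-subject cohort at default noise with 0.2 mm landmark noise for the
realistic-accuracy analogue. These sizes were chosen to give Monte-Carlo
error comfortably below the effects being checked.

## Known limitations

* The palatal-vault surface is smooth, so the fine registration depends
  on a sound landmark seed; there is no global search.
* The reference route's volumetric superimposition is an input, not an
  implementation; errors in it propagate untested.
* Tip/torque are reported in (−90°, 90°] as line angles; teeth rotated
  beyond 90° from upright (not anatomically plausible here) would alias.
* The trimmed-ICP monotonicity guarantee applies to the objective as
  evaluated on each iteration's own correspondence set, the standard
  caveat for trimmed variants.
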