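---
title: "Template-analogy docking of FUR-family dimers and multimer spacing scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-analogy docking of FUR-family dimers and multimer spacing scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

FUR-family metalloregulators (FUR, PerR, Zur and their relatives) are small
homodimeric winged helix-turn-helix (wHTH) proteins that repress
transcription by binding AT-rich operators in bacterial promoters.  For
most of them no experimental structure of the protein-DNA complex exists.
When a regulator of interest has a reliable monomer/dimer model but no
co-crystal, a productive strategy is *template analogy*: find experimental
protein-DNA complexes whose DNA-binding domain shares the wHTH fold, and
transfer the DNA-to-protein geometry by superposing the recognition motif
of the model onto the template's, so that the recognition helix (H4)
inherits the template's major-groove insertion.

`furdock` implements that protocol as a reusable toolkit, together with
the two analyses used to interpret such models:

* **surface statistics** — solvent-accessible surface areas (SASA), the
  contact surface
  $CS = (SASA_{rec} + SASA_{lig} - SASA_{cplx})/2$,
  and per-nucleotide buried-surface DNA footprints (the quantity a DNase
  protection assay reports);
* **multimer spacing scans** — fixing one bound dimer and sliding a copy
  along ideal B-DNA in 1-bp helical increments, classifying every spacing
  as *clash*, *contact* or *separated*, assembling tetramers, hexamers
  (e.g. offsets 0-3-6 or 0-6-12) and longer polymers, and turning the
  protected interval of a multimer into a blocked/free "transcriptional
  switch" verdict for a divergently transcribed gene pair.

A promoter module handles the sequence side: sigma-70 -10/-35 box scans
relative to an experimentally mapped transcription start site (TSS),
AT-only runs, dyad-symmetry scores, GATAAT tandem arrays and 7-1-7
inverted repeats.

## The docking procedure

1. **Template admissibility** (`check_template_criteria()`): a candidate
   template passes when (1) its duplex is at least 20 bp, (2) the bound
   protein is a homodimer (two chains with identical sequences), (3) the
   recognition helix is followed in sequence by two strand ranges
   annotated antiparallel (the wing), and (4) the resolution is at most a
   user threshold (default 3 Å).  Criterion 3 is evaluated from the
   user-supplied `motif_spec()` annotation, not from a secondary-structure
   predictor: motif annotation is an input of this toolkit, and
   fold prediction is out of its scope.
2. **Monomer fitting** (`fit_monomer()`): least-squares (Kabsch)
   superposition of the backbone atoms (N, CA, C, O) of the chosen motif
   segments — `H4S1S2` or `H3H4S1S2` — onto the template's equivalent
   atoms.  Backbone-only superposition is deliberate: side chains differ
   between target and template.  The monomer moves only rigidly, so its
   internal geometry is preserved exactly.
3. **Sequence threading** (`thread_sequence()`): the template's bases are
   replaced by the target operator sequence while the sugar-phosphate
   backbone stays bit-identical; new bases are idealized planar rings
   placed on the replaced base's glycosidic frame (C1' position,
   glycosidic-bond direction, base plane).  This preserves the backbone
   conformation that carries the protein-DNA contacts.
4. **Dimer closure** (`close_dimer()`): the intact dimer is first carried
   onto the placed monomer through its motif backbone (preserving the
   dimerization interface), then a single rigid transform of the whole
   dimer is refined against distance restraints between recognition-helix
   atoms and DNA phosphates.  When no experimental restraints are
   supplied, `default_restraints()` measures them from the template
   between equivalent motif atoms and the nearest phosphates — the
   template's helix-in-groove geometry expressed as distances.
5. **Model selection** (`rank_models()`): candidate models are ranked by
   contact surface (descending), ties broken by restraint rms and then
   input order.  Energy-based rescoring (MM-PBSA and the like) is a
   deliberate non-goal; CS is cheap, deterministic and reproducible.

### The closure optimizer

The restraint refinement is a deterministic, derivative-free minimisation
over the 6 rigid-body parameters (axis-angle rotation about the dimer
centroid + translation): Nelder-Mead multi-started from eight fixed
axis-angle perturbations (identity, ±5° about each axis, 3-3-3°), the
best final objective winning and exact ties resolved by the smaller
parameter norm.  A best-so-far objective trace is logged, so descent is
monotone by construction and inspectable; non-convergence within the
iteration budget is flagged on the returned model, never silent.  A
flexible, energy-minimised refinement is out of scope — replacing it with
a rigid analog is what makes the whole pipeline bit-reproducible.

## Ideal B-DNA and the screw algebra

The multimer scan needs one geometric fact: moving a rigid body "n base
pairs along the DNA" is the screw transform of rotation $n\,\theta$ about
the helix axis plus translation $n\,h$ along it.  Defaults are the
canonical B-form values $h = 3.38$ Å/bp and $\theta = 36°$/bp (10.0
bp/turn), both configurable (e.g. `twist = 360/10.5` for 10.5 bp/turn);
the canonical values are a design decision of this package, not a fit to
any particular system.  `helical_step()` implements the
transform; the transforms form a one-parameter group, which the tests
check numerically.

`build_bdna()` constructs an ideal duplex directly in that frame: the two
glycosidic C1' atoms of every pair sit symmetrically about the axis (so
the C1'-C1' midpoint — the base-pair centroid — lies exactly on it),
successive pairs are related by exactly one helical step, strands are
antiparallel by the dyad, and every nucleotide carries the standard
sugar-phosphate atom names with the phosphate absent at the 5' termini.
Bases are planar rings with standard bond lengths placed by solving the
two-anchor problem (glycosidic nitrogen and Watson-Crick contact atom).
The geometry is *schematic at the covalent level*: canonical helical
radii and atom inventories are exact, but inter-residue covalent details
(O3'-P continuity) are approximate.  Every analysis in this package —
rigid placement, SASA differences, clash counts, footprints — depends on
atom positions and radii at the ~1 Å scale, not on stereochemistry, and
the test suite exercises exactly those properties.  For experimental
(non-ideal) duplexes the helix axis is estimated as the principal axis
through the base-pair centroids (`fit_helix_axis()`); for built DNA this
recovers the construction axis exactly.

## Surface numerics

SASA is Shrake-Rupley sampling with a *deterministic Fibonacci lattice*
(default 960 points/atom, probe 1.4 Å): no random numbers anywhere in the
module, so repeated runs are bit-identical and the acceptance of the
numerics is checked against closed forms — a single atom against
$4\pi(r+p)^2$ within 1%, overlapping pairs against the analytic
two-sphere cap formula within 2%.  Radii are a Bondi-style heavy-atom
table with a united-atom flavour (C 1.70, N 1.55, O 1.52, P 1.80 Å...)
and an explicit `X` fallback; pass a table without `X` to make unknown
elements a hard error.

Design choices worth knowing:

* `contact_surface()` recomputes all three SASA terms; the spacing scan
  caches the isolated dimer's SASA once and reuses it for every offset —
  rigid copies have identical analytic SASA, and the cached value makes
  the per-offset CS differ from a full recomputation only by lattice
  orientation noise (well below the classification margins used
  anywhere).
* `dna_footprint()` reports both the raw protected base-pair set and the
  contiguous first-to-last *span*, because protection assays report a
  single length.  A base pair is protected when either paired nucleotide
  buries more than `buried_threshold` (default 1 Å²) of its naked-DNA
  SASA.  The threshold is a documented default, not a calibration against
  any particular published footprint.

## The spacing scan and the switch model

`scan_spacings()` classifies each offset `s = 1..max_offset`:

* **clash** if any inter-copy atom pair overlaps by more than
  `overlap_tol` (default 0.5 Å beyond van der Waals contact);
* otherwise **contact** if the inter-dimer contact surface `CS_dd` is at
  least `cs_min` (default 1 Å²);
* otherwise **separated**.

The qualitative three-way grouping mirrors how multimer plausibility is
argued for FUR-family regulators (spacings that clash are unrealistic;
spacings with inter-dimer contact can stabilise tetramers; 6-bp spacings
place successive dimers on alternating faces and permit indefinite
polymerisation).  The numeric thresholds are this package's defaults —
the source analyses report only the groups.  Both "DNA overlapped
surface" (total DNA area buried by all copies) and `CS_dd` are emitted,
since both appear in that literature.

`multimer_footprint_span()` is the exact arithmetic connecting footprints
to multimers: copies at `offsets` with single-dimer footprint $w$ protect
$w + \max(\text{offsets})$ bp.  With the canonical $w = 21$ bp this gives
27 bp for a 0-3-6 hexamer and 33 bp for 0-6-12.  `switch_report()` then
intersects a protected interval with each gene's -10/-35 boxes: a gene is
*blocked* when either box is covered.  Re-running with an end dimer
removed recomputes the verdicts — the transcriptional switch.

## Promoter coordinates

Positions follow the biology convention: the TSS is +1, upstream is
negative, and there is no position 0; minus-strand genes are scanned on
the reverse complement with hits reported in that gene's own frame.
`scan_box()` takes IUPAC-with-`n` consensi (`n` is a wildcard that never
counts as a mismatch), so the extended -10 element `TGnTATAAT` works
directly.  The -35 spacing conventions (17 bp canonical, 30 bp variant)
are left to the caller's window.  Mismatch counts are plain Hamming
distances over non-wildcard positions — when a published element is
printed with mixed case, the scanner reports the computed distance rather
than trying to honour the casing.

## What the fixtures emulate — and what they do not

The package is fully testable offline through three generators:

* `make_template_complex()` — a homodimeric pseudo-protein on ideal
  B-DNA, with annotated H1-H5/S1-S2 segments, the recognition helix laid
  against the major-groove face and monomer B the dyad image of monomer
  A.  It passes the template criteria by construction and self-fits with
  zero rmsd, which anchors the fitting tests.
* `make_toy_dimer_complex()` — either two lobes of backbone-hugging
  pseudo-atoms whose footprint is *calibrated at construction time*
  against `dna_footprint()` (the covered base-pair set is adjusted until
  the measured span equals the requested one, or an error is raised), or
  a sphere pair for which every scan quantity has a closed form.
* `make_promoter_sequence()` — a seeded background with exactly planted
  elements and an AT-only run flanked by G/C so the run is maximal;
  the ground truth is attached to the annotation.

These fixtures make the *machinery* falsifiable: parameter recovery
(footprints 5/11/21 bp), oracle equivalence (sphere scans vs closed
form), and planted-truth recovery (promoter elements).  They do not make
the science of any particular regulator reproducible — real template
structures have curved, sequence-dependent DNA, real dimers are not
spheres, and a real footprint depends on the exact atomic model and
NACCESS-style settings, which is why the published per-spacing surface
values of any specific system are not acceptance anchors here.  Passing
tests show the protocol is implemented correctly, not that a particular
biological model is right.

## Determinism, degenerate inputs, problem sizes

There is no RNG outside the seeded fixture generators (which save and
restore the caller's RNG state).  Superposition guards reflections (the
returned rotation always has det +1) and rejects collinear or
under-sized point sets; transforms are re-orthonormalised on composition;
`compose`/`invert`/`helical_step` closure is tested to 1e-9.  Structures
with a single DNA chain get a footprint against that chain alone;
proteins absent means an empty footprint, span 0.

The shipped test-suite sizes are chosen for completeness per minute:
duplexes of 10-84 bp, scans to 30 offsets, SASA at 240-960 points/atom.
They are package choices; everything scales to longer operators by the
same calls.

## Known limitations

* Covalent-level DNA geometry is schematic (see above); do not use the
  built duplexes for stereochemical analysis or simulation input.
* Closure refinement is rigid; induced fit, DNA bending and flexible
  minimisation are out of scope, as are binding free energies.
* `check_template_criteria()` trusts the motif annotation it is given.
* The footprint span is the contiguous first-to-last protected range; a
  multimer with a genuinely discontinuous footprint is summarised by its
  envelope (the raw protected set is returned for such cases).
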