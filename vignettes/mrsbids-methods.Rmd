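---
title: "Validating MRS datasets in BIDS layout: data model, rules, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating MRS datasets in BIDS layout: data model, rules, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsbids)
```

## The problem

In vivo magnetic resonance spectroscopy (MRS) quantifies metabolites from
the nuclear magnetic resonance signal of a localized tissue volume. A
single-voxel acquisition (`svs`) yields one free induction decay (FID) —
a complex time series whose Fourier transform is the spectrum; MRS
imaging (`mrsi`) encodes spectra along one to three spatial dimensions;
unlocalized acquisitions (`unloc`) and water/phantom reference scans
(`mrsref`) complete the picture. Sharing such data requires agreeing on
three things: how files are *named*, how they are *arranged*, and which
*metadata* must travel with them. `mrsbids` implements the MRS flavour of
the Brain Imaging Data Structure — the entity filename grammar, the
sidecar metadata schema, and the NIfTI-MRS container — as parsing,
construction, IO, validation and fixture-generation functions.

## The data model

### Filenames

A name is `<entities>_<suffix>.<extension>`. Entities are `key-value`
pairs; the canonical order is

`sub, ses, task, acq, nuc, voi, rec, run, echo, inv`

with `sub` mandatory and first, `ses` (when used) immediately second, each
key used at most once, labels matching `[A-Za-z0-9]+` and the indices of
`run`, `echo`, `inv` matching `[0-9]+`. Suffixes are `svs`, `mrsi`,
`unloc`, `mrsref`; extensions `.nii`, `.nii.gz` (data) and `.json`
(sidecars). Data files live under `sub-<label>/[ses-<label>]/mrs/`.

Two ordering facts deserve comment. The relative order of `task`, `acq`,
`nuc`, `voi` is fixed by the standard's own worked example
(`sub-06_ses-02_task-nback_acq-slaser_nuc-1H_voi-dlpfc_svs.nii.gz`); the
placement of `rec`, `run`, `echo`, `inv` *after* `voi` follows the
published BIDS MRS filename template. The rule catalog flags MRS103
accordingly. Parsing is strict by default — a validator must never repair
silently. A lenient mode exists purely for interactive inspection (the
`inspect` CLI subcommand): it re-sorts out-of-order entities with a
warning. Index values keep their spelling (`run-01` stays `"01"`) but
compare as integers for duplicate-acquisition detection, so `run-01` and
`run-1` collide.

### Sidecar schema

`sidecarCatalog()` is the machine-readable field table: 33 fields with
requirement level, JSON value type, fixed shape where mandated, units and
suffix applicability. Severity follows the standard's own wording read the
RFC-2119 way: "must" → error, "recommended"/"should" → warning, absent
optional fields → silence, *malformed* optional fields → error. Units
(MHz, Hz, s, mm, ppm) are fixed by the standard, so no conversion is
performed; they do imply sign/domain constraints
(`SpectrometerFrequency > 0`, `SpectralWidth > 0`, `EchoTime ≥ 0`,
`MixingTime ≥ 0`, counts ≥ 1), whose violations are errors (MRS205).
Unknown keys are info notices, never errors — BIDS permits extra metadata.

Conditional rules couple the filename to the sidecar: `nuc-<label>`
requires `ResonantNucleus` with a value equal to the label. Equality is
taken after case-insensitive alphanumeric normalization, and an array
value (dual-tuned acquisitions, e.g. `nuc-1H13C`) compares against the
in-order concatenation of its elements — the standard does not pin down
the dual-tuned encoding, so this is the package's documented choice, and a
mismatch is an error. `voi-<label>` requires `BodyPart` and
`BodyPartDetails` (errors if absent); `BodyPartDetailsOntology` stays
optional and is checked only for URI well-formedness (scheme plus
non-empty remainder) — no ontology lookup. `acq-<label>` without
`PulseSequenceType` is a warning. `PulseSequencePulses` demands an
equal-length `PulseSequenceTiming`. For `mrsi`, the absent trio
`MatrixSize`/`VolumeAffineMatrix`/`EncodingTechnique` draws warnings, and
`NumberOfTransients` (meant for `svs`/`unloc`) draws an info notice.

Whether the four required fields also bind `mrsref` files is not stated
separately anywhere; the catalog applies them to all four suffixes, and
the rule documentation flags this reading. The value types of
`EchoAcquisition` and the three `Edit*` fields are likewise unspecified;
they are accepted as strings or arrays of strings.

### The NIfTI-MRS container

A NIfTI-MRS file is a standard NIfTI file whose data block spans up to
seven axes — three spatial, the fourth the time-domain samples, the last
three free encoding dimensions — holding complex time-domain data (FIDs,
not spectra, keeping the data as raw as practical). The dwell time (the
time-axis grid spacing, reciprocal of the spectral width) sits in the
fourth pixdim slot, a version tag in `intent_name`, and a JSON header
extension with the designated extension code 44 carries embedded metadata
(`SpectrometerFrequency`, `ResonantNucleus` at minimum). IO is built on
RNifti; `readNiftiMrs()` always exposes the padded seven-axis extents
(NIfTI treats absent trailing axes as extent 1, so `(1,1,1,N)` and
`(1,1,1,N,1,1,1)` are the same geometry — the padding-invariance tests
pin this down). Files are written as NIfTI-2 with double-precision
complex data: NIfTI-1 stores pixdim in single precision, which would
truncate the dwell time, and double-precision storage makes the
write/read round trip element-wise exact — a property the test suite
asserts over hundreds of random blocks.

`consistencyCheck()` cross-examines container and sidecar. The
spectral-width check uses a relative tolerance of `1e-3`: wide enough for
rounding in vendor exports, far below any unit mix-up. Disagreements
between the embedded extension and the sidecar are *warnings* — the
standard does not say which source is authoritative, so the package
reports and never auto-resolves. Geometry is checked against the suffix:
any spatial extent above 1 on `svs` data is an error; all-singleton
spatial extents on `mrsi` data a warning.

## Dataset validation

`validateDataset()` walks the tree (skipping `sourcedata/`,
`derivatives/`, `code/` and anything in `.bidsignore`), and runs, per data
file: the grammar, path/entity agreement, sidecar resolution with
inheritance merging, the schema and conditional checks, and the container
checks. Failures short-circuit sensibly: an unparseable name yields
exactly its grammar issue (its stranded sidecar becomes an orphan —
a warning, since the standard requires a sidecar per data file, not the
converse); a missing sidecar yields exactly the missing-sidecar error
without cascading missing-field errors.

Inheritance follows the standard BIDS principle, deliberately narrowed:
fragments at the dataset root, subject and session levels merge into the
file-level sidecar (deepest wins) only when they share the suffix and
their entities are an equal-valued subset of the file's — this prevents
metadata from one acquisition leaking into another. Cross-file rules
resolve `ReferenceSignal` (must reach an existing `mrsref` file) and
`AnatomicalImage` (dataset-relative path, or a file of that name under the
subject's `anat/`; no suffix constraint, since the standard names none).
Paths may carry a `bids::` URI prefix, which is stripped. Dataset-level
rules cover `dataset_description.json` (error if absent),
duplicate acquisition identities, and divergent tissue descriptions for
the same `voi` label (warning).

Reports are deterministic: issues are sorted by (file, rule id, location,
message), paths are dataset-relative (so a copied tree validates
identically apart from its root), and `renderReport()` emits byte-stable
text or JSON. Strict mode promotes warnings to errors, so its error set is
a superset of normal mode's by construction. Individual rules can be
disabled by id. Exit codes in the CLI: 0 pass, 1 errors, 2 usage/IO.

One known gap, documented rather than enforced: whether `task-<label>`
functional MRS requires an accompanying events file is not addressed by
the MRS extension, and no such rule exists here.

## The synthetic generator

`generateDataset()` emulates the *structure* of a small MRS study, not its
physiology. Defaults model a common 3T proton exam: spectrometer frequency
123.25 MHz, spectral width 2000 Hz, 2048 complex points, and three
Lorentzian (damped complex-exponential) components at the classic proton
shifts — NAA 2.01, creatine 3.03, choline 3.20 ppm — expressed as offsets
from water (4.68 ppm), with amplitudes 1.0/0.9/0.7, T2 constants
0.25/0.18/0.22 s and complex Gaussian noise of standard deviation 0.05.
The water reference is a single large on-resonance peak with fast decay.
The FID model is

$$ s[n] = \sum_k A_k\, e^{2\pi i f_k n \Delta t}\, e^{-n\Delta t/T_{2,k}}
          + \sigma(\varepsilon_{re} + i\varepsilon_{im}), \qquad
   \Delta t = 1/\mathrm{SW}. $$

These numbers are plausible configuration, not claims about any scanner.
The generator does **not** simulate lineshape distortion, eddy currents,
J-coupling/multiplets, spectral editing, motion or frequency drift —
passing tests therefore demonstrate structural compliance machinery, not
robustness to physiologically realistic signals. What the generator does
guarantee, and what the tests lean on, is the generator/validator
contract: every unmutated tree validates with zero errors, every sidecar
byte is reproducible from the seed (keys sorted, fixed formatting), and a
single integer seed fixes all randomness (per-file seeds are derived
arithmetically from it).

The mutation registry is the flip side: 18 named, targeted edits — from
`duplicate_entity` through `volumeaffinematrix_3x3` to
`svs_spatial_extent` — each violating exactly one catalogued rule, so the
validator's one-fault diagnosability can be asserted: the mutated tree
must produce precisely the targeted error rule and no other error.

## Numerical and design choices

* **Tolerances.** Spectral width vs dwell time: relative `1e-3`.
  Frequency agreement between embedded extension and sidecar: relative
  `1e-6` (an equality check up to floating-point noise). All other
  comparisons are exact.
* **Degenerate inputs.** A NIfTI file with a non-positive or missing
  fourth pixdim still reads (dwell time falls back to 1 s) so that the
  coherence check can flag it rather than the reader crashing; ragged
  arrays where a 4×4 matrix is expected are shape errors; empty datasets
  scan to empty inventories.
* **Tie-breaks.** Issue ordering is radix-sorted on (file, rule id,
  location, message); catalog and registry orders are fixed in source.
  When a recommended field missing on MRSI would be reported both
  generically and by the MRSI-specific rule, only the specific rule is
  kept.
* **Problem sizes.** The shipped tests and the acceptance script use
  fixtures of 1–3 subjects with 64–2048-point FIDs, 50-spec generator
  sweeps, 200 filename and 500 container round trips — sizes chosen so
  the whole suite exercises every rule in well under a minute while the
  round-trip properties still cover the combinatorics.
* **What lives where.** Container IO delegates to RNifti and JSON to
  jsonlite; the grammar, catalog, rule engine and generator are the
  package's own. The single deliberate deviation from common NIfTI-MRS
  practice is defaulting to NIfTI-2/complex-double storage (see above)
  rather than complex-single; single precision would break exact
  round-tripping and saves little at these sizes.

## Limitations

Beyond the generator's simplifications listed above: the validator checks
non-MRS modalities only for existence (an `AnatomicalImage` target's
content is never inspected); the full NIfTI-MRS dimension-tag vocabulary
(`dim_5_*` etc.) is out of scope, as are vendor-format conversion, MRSI
spatial reconstruction, basis sets and spectral fitting; and ontology
terms in `BodyPartDetailsOntology` are not resolved. The general BIDS
machinery (e.g. `participants.tsv` column semantics) is touched only as
far as MRS files need it.
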