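# mrsbids

Magnetic resonance spectroscopy (MRS) measures metabolite signals in vivo,
but the field has no single convention for organising the resulting data:
every scanner vendor exports its own formats, and study layouts differ
between (and within) labs. The Brain Imaging Data Structure (BIDS) solves
this for neuroimaging by prescribing an entity-based filename grammar, a
fixed directory hierarchy, and JSON sidecar metadata next to every data
file; its MRS extension adds the `mrs/` datatype, the suffixes
`svs`/`mrsi`/`unloc`/`mrsref`, the entities `nuc-<label>` and
`voi-<label>`, and the NIfTI-MRS container — a standard NIfTI file with a
seven-dimensional complex data block (three spatial axes, one time axis,
three free encoding axes) and an embedded JSON header extension.

`mrsbids` implements that standard as a working R toolkit, for anyone who
curates, shares or programmatically checks MRS datasets:

* **Filename grammar** — `parseMrsFilename()`, `buildMrsFilename()`,
  `expectedRelativePath()`: strict tokenization of
  `<entities>_<suffix>.<extension>` names with the canonical entity order
  `sub, ses, task, acq, nuc, voi, rec, run, echo, inv`, alphanumeric
  labels, and nonnegative-integer indices.
* **Sidecar schema** — `sidecarCatalog()`, `validateSidecar()`,
  `checkConditionalRequirements()`, `mergeInherited()`: the full MRS field
  catalog (required: `ResonantNucleus`, `SpectrometerFrequency` (MHz),
  `SpectralWidth` (Hz), `EchoTime` (s)), shape rules (length-3
  `AcquisitionVoxelSize`/`MatrixSize`, 4×4 `VolumeAffineMatrix`), and the
  entity-conditional rules (`nuc` ⇒ matching `ResonantNucleus`; `voi` ⇒
  `BodyPart` + `BodyPartDetails`; `PulseSequencePulses` ⇔ equal-length
  `PulseSequenceTiming`; …).
* **NIfTI-MRS IO** — `readNiftiMrs()`, `writeNiftiMrs()`,
  `consistencyCheck()`: minimal container reading/writing (via RNifti)
  with exact complex round trips, the dwell time in the fourth pixdim
  slot, and the ecode-44 JSON header extension.
* **Dataset validation** — `validateDataset()`, `renderReport()`: the
  whole rule set over a tree, including cross-file checks
  (`ReferenceSignal` must resolve to an existing `mrsref` file,
  `AnatomicalImage` to an existing anatomical image) and deterministic
  text/JSON reports with stable rule ids (`ruleCatalog()`).
* **Synthetic fixtures** — `generateDataset()`, `fixtureSpec()`,
  `generateFid()`, `applyMutation()`: fully synthetic, valid-by-construction
  datasets (damped complex-exponential FIDs,
  `s[n] = Σ_k A_k e^{2πi f_k nΔt} e^{−nΔt/T2_k} + noise`) plus a registry
  of 18 single-rule mutations for testing validators.

## Worked example

```r
library(mrsbids)

root <- file.path(tempdir(), "demo")
generateDataset(fixtureSpec(nSubjects = 1, mrsiMatrix = c(4, 4, 1), seed = 9),
                root)
rep <- validateDataset(root)
rep
#> ValidationReport: /tmp/.../demo
#>   0 error(s), 0 warning(s), 0 info notice(s)
#>   result: PASS

applyMutation(root, "missing_echotime")
issues(validateDataset(root))[, c("rule_id", "severity", "location")]
#>   rule_id severity location
#> 1  MRS201    error EchoTime
```

The generated tree contains, per subject and session, an sLASER-like
single-voxel acquisition, a water reference and (here) a 4×4×1 MRSI
acquisition; the mutated dataset fails with exactly the one targeted rule:
`MRS201`, a missing required sidecar field.

Inspect any file:

```r
x <- readNiftiMrs(file.path(root, "sub-01/ses-01/mrs",
                  "sub-01_ses-01_acq-slaser_nuc-1H_voi-pcc_svs.nii.gz"))
dims(x)        # 1 1 1 2048 1 1 1  — the seven-dimensional data block
dwellTime(x)   # 5e-04 s  (reciprocal of the 2000 Hz spectral width)
headerExt(x)   # $SpectrometerFrequency 123.25; $ResonantNucleus "1H"
```

A thin command-line front end is included:

```sh
Rscript inst/scripts/mrsbids.R example --out ds --subjects 2 --seed 1
Rscript inst/scripts/mrsbids.R validate ds --format json --out report.json
Rscript inst/scripts/mrsbids.R inspect ds/sub-01/ses-01/mrs/*.nii.gz
```

Exit codes: 0 pass, 1 validation errors, 2 usage/IO failure.

## Documentation

See the methods vignette (`vignettes/mrsbids-methods.Rmd`) for the data
model, the rule catalog and its severities, what the synthetic generator
does and does not emulate, and the package's design decisions.
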