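Package: mrsbids
Title: Organise and Validate Magnetic Resonance Spectroscopy Data in BIDS Layout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for working with magnetic resonance spectroscopy (MRS)
    datasets organised under the Brain Imaging Data Structure (BIDS): parse
    and construct entity-based filenames and their expected directory paths,
    validate JSON sidecar metadata against the MRS field catalog including
    conditional requirements, read and write minimal NIfTI-MRS containers
    (seven-dimensional complex data block with an embedded JSON header
    extension), validate whole dataset trees with cross-file checks, and
    generate fully synthetic compliant datasets plus targeted single-rule
    mutations for testing validators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'entities.R'
    'catalog.R'
    'sidecar.R'
    'niftimrs.R'
    'scan.R'
    'validator.R'
    'report.R'
    'fid.R'
    'fixtures.R'
    'mutations.R'
    'mrsbids-package.R'
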