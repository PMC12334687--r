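# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from stored files.

# Generate a dataset under a fresh temp dir that is removed when the
# calling test finishes.
localDataset <- function(..., env = parent.frame()) {
  root <- tempfile("mrsbids-ds-")
  withr::defer(unlink(root, recursive = TRUE), envir = env)
  generateDataset(fixtureSpec(...), root)
  root
}

minimalRequired <- function() {
  list(ResonantNucleus = "1H", SpectrometerFrequency = 123.25,
       SpectralWidth = 2000, EchoTime = 0.03)
}

docFor <- function(content, name = "sub-01_svs.nii.gz", file = "x.json") {
  sidecarDocument(content, context = parseMrsFilename(name),
                  sourcePaths = file)
}

errorsOf <- function(df) df[df$severity == "error", , drop = FALSE]
warningsOf <- function(df) df[df$severity == "warning", , drop = FALSE]

# A random valid entity set (always includes sub; ses et al. drawn at
# random), used for parse/build round-trip properties.
randomEntitySet <- function() {
  tab <- entityDescriptors()
  keys <- tab$key[c(TRUE, stats::runif(nrow(tab) - 1L) < 0.4)]
  vals <- vapply(keys, function(k) {
    if (tab$kind[tab$key == k] == "index") {
      as.character(sample(0:99, 1L))
    } else {
      paste(sample(c(letters, LETTERS, 0:9), sample(1:8, 1L), replace = TRUE),
            collapse = "")
    }
  }, character(1))
  stats::setNames(vals, keys)
}

randomSuffix <- function() sample(mrsSuffixes(), 1L)
randomExtension <- function() sample(mrsExtensions(), 1L)
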