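#' Simulate a free induction decay
#'
#' Generates a synthetic complex time-domain MR signal as a sum of damped
#' complex exponentials plus complex Gaussian noise:
#' \deqn{s[n] = \sum_k A_k \exp(2\pi i f_k n \Delta t)
#'   \exp(-n \Delta t / T_{2,k}) + \sigma(\epsilon_{re} + i\,\epsilon_{im})}
#' with \eqn{\Delta t = 1/\mathrm{spectralWidth}} and \eqn{\epsilon}
#' standard normal. The same seed always yields the identical series; the
#' calling session's RNG state is left untouched.
#'
#' @param nPoints Number of complex samples (>= 2).
#' @param spectralWidth Sampled bandwidth in Hz (> 0).
#' @param metabolites \code{data.frame} with one row per signal component
#'   and columns \code{amplitude}, \code{freqOffsetHz}, \code{t2} (decay
#'   constant in s; \code{Inf} for no decay).
#' @param noiseSd Standard deviation \eqn{\sigma} of the additive noise in
#'   each of the real and imaginary channels (>= 0).
#' @param seed Integer seed for the noise draw.
#' @return Complex vector of length \code{nPoints}.
#' @examples
#' ## one undamped on-resonance component, no noise: constant 1+0i
#' fid <- generateFid(16, 2000,
#'   data.frame(amplitude = 1, freqOffsetHz = 0, t2 = Inf), noiseSd = 0)
#' all(fid == 1 + 0i)
#' @export
generateFid <- function(nPoints, spectralWidth, metabolites, noiseSd = 0,
                        seed = 1L) {
  if (!is.numeric(nPoints) || length(nPoints) != 1L || nPoints < 2L ||
      nPoints != floor(nPoints))
    mrsStop("BadParameters", "nPoints must be an integer >= 2")
  if (!is.numeric(spectralWidth) || length(spectralWidth) != 1L ||
      spectralWidth <= 0)
    mrsStop("BadParameters", "spectralWidth must be > 0")
  if (!is.data.frame(metabolites) ||
      !all(c("amplitude", "freqOffsetHz", "t2") %in% names(metabolites)))
    mrsStop("BadParameters",
            "metabolites needs columns amplitude, freqOffsetHz, t2")
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || noiseSd < 0)
    mrsStop("BadParameters", "noiseSd must be >= 0")
  dt <- 1 / spectralWidth
  n <- seq_len(nPoints) - 1
  s <- complex(real = rep(0, nPoints), imaginary = rep(0, nPoints))
  for (k in seq_len(nrow(metabolites))) {
    A <- metabolites$amplitude[k]
    f <- metabolites$freqOffsetHz[k]
    t2 <- metabolites$t2[k]
    decay <- if (is.finite(t2)) exp(-n * dt / t2) else rep(1, nPoints)
    s <- s + A * exp(2i * pi * f * n * dt) * decay
  }
  if (noiseSd > 0) {
    s <- s + withLocalSeed(seed, {
      complex(real = stats::rnorm(nPoints, sd = noiseSd),
              imaginary = stats::rnorm(nPoints, sd = noiseSd))
    })
  }
  s
}

## Evaluate expr under set.seed(seed) and restore the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
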