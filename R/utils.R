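#' @keywords internal
"_PACKAGE"

#' @useDynLib cisim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd fft convolve approx predict coef residuals
#' @importFrom utils head tail
NULL

#' Derive a child seed from a master seed and a stage label
#'
#' All stochastic stages take explicit seeds derived from one master seed so
#' that whole experiments are reproducible end to end. The derivation hashes
#' the label into the master seed; the result is always a valid 32-bit R
#' integer.
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. "degeneration", "noise").
#' @return a single integer seed in [0, 2^31 - 1].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste(label, collapse = ":"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

#' Root-mean-square level of a waveform in dB full scale
#'
#' Convention: dBFS = 20*log10(RMS); a full-scale sine is approximately
#' -3 dBFS under this convention and digital silence is -Inf.
#'
#' @param x numeric waveform.
#' @return level in dBFS.
#' @export
dbfs <- function(x) {
  r <- sqrt(mean(x^2))
  if (r <= 0) return(-Inf)
  20 * log10(r)
}

#' Scale a waveform to a target RMS level in dBFS
#'
#' @param x numeric waveform.
#' @param level_dbfs target level, dBFS.
#' @return rescaled waveform.
#' @export
set_level <- function(x, level_dbfs) {
  r <- sqrt(mean(x^2))
  if (r <= 0) stop("cannot set the level of a silent signal")
  x * 10^(level_dbfs / 20) / r
}

## run a function under a local RNG seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
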