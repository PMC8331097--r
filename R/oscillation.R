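#' Cycle-based oscillation amplitude of a series
#'
#' Amplitude metric shared by the calibration objectives (dopamine
#' oscillation) and the tremor quantification (endpoint displacement).
#' The series is detrended by subtracting its mean; cycles are delimited by
#' upward zero crossings of the detrended series; within each complete cycle
#' the peak-to-peak excursion is measured; the amplitude is half the mean
#' peak-to-peak excursion. For a pure sinusoid this recovers the sinusoid's
#' amplitude. With fewer than two zero crossings (no complete cycle) the
#' metric is 0 and the result carries attribute `no_cycles = TRUE`.
#'
#' @param x Numeric series, regularly sampled.
#' @return Non-negative scalar with attributes `n_cycles` and `no_cycles`.
#' @examples
#' oscillation_amplitude(0.01 * sin(2 * pi * seq(0, 10, by = 0.01)))
#' @export
oscillation_amplitude <- function(x) {
  x <- as.numeric(x)
  d <- x - mean(x)
  n <- length(d)
  up <- which(d[-1] >= 0 & d[-n] < 0)
  if (length(up) < 2) {
    return(structure(0, n_cycles = 0L, no_cycles = TRUE))
  }
  pp <- vapply(seq_len(length(up) - 1), function(k) {
    seg <- d[up[k]:up[k + 1]]
    max(seg) - min(seg)
  }, numeric(1))
  structure(mean(pp) / 2, n_cycles = length(pp), no_cycles = FALSE)
}
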