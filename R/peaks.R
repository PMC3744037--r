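#' Strict-local-maxima peak detection with prominence and separation rules
#'
#' The deterministic peak operator underlying [detect_packets()]. The rules,
#' fixed exactly so that independent implementations can reproduce them:
#'
#' 1. Candidates are strict local maxima: samples greater than both
#'    neighbours (endpoints are never peaks).
#' 2. Prominence of a peak at `i`: walk left from `i` to the nearest sample
#'    strictly higher than `v[i]` (or the start of the series) and take the
#'    minimum value on that stretch; same to the right; prominence is
#'    `v[i] - max(left_min, right_min)`. Peaks with prominence below
#'    `min_prominence` are dropped.
#' 3. Minimum separation: surviving peaks are visited in order of
#'    decreasing value (ties: earlier sample first); a peak is kept only if
#'    no already-kept peak lies within `min_separation` samples
#'    (`|i - j| < min_separation` discards).
#'
#' @param values Numeric vector.
#' @param min_prominence Prominence floor (same units as `values`).
#' @param min_separation Minimum index separation between kept peaks
#'   (samples; 1 disables the rule).
#' @return Data frame with columns `index`, `value`, `prominence`, ordered
#'   by `index`.
#' @export
find_peaks <- function(values, min_prominence = 0, min_separation = 1) {
  n <- length(values)
  if (n < 3) return(data.frame(index = integer(0), value = numeric(0),
                               prominence = numeric(0)))
  i <- 2:(n - 1)
  cand <- i[values[i] > values[i - 1] & values[i] > values[i + 1]]
  if (!length(cand)) return(data.frame(index = integer(0),
                                       value = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(p) {
    vp <- values[p]
    higher_l <- which(values[seq_len(p - 1)] > vp)
    j <- if (length(higher_l)) max(higher_l) + 1L else 1L
    left_min <- min(values[j:p])
    higher_r <- which(values[(p + 1):n] > vp)
    k <- if (length(higher_r)) p + min(higher_r) - 1L else n
    right_min <- min(values[p:k])
    vp - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) && min_separation > 1) {
    ord <- order(-values[cand], cand)
    kept <- integer(0)
    for (p in cand[ord]) {
      if (!length(kept) || all(abs(kept - p) >= min_separation))
        kept <- c(kept, p)
    }
    sel <- cand %in% kept
    cand <- cand[sel]; prom <- prom[sel]
  }
  data.frame(index = cand, value = values[cand], prominence = prom)
}

# Gaussian smoothing with edge renormalisation; sd in samples.
# sd = 0 returns the input unchanged.
gaussian_smooth <- function(values, sd_samples) {
  if (sd_samples <= 0) return(values)
  half <- max(1L, ceiling(4 * sd_samples))
  kern <- exp(-((-half):half)^2 / (2 * sd_samples^2))
  kern <- kern / sum(kern)
  n <- length(values)
  padded <- c(rep(values[1], half), values, rep(values[n], half))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}
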