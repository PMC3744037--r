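# Independent brute-force peak scanner used as the oracle for the package's
# peak operator: same published rules (strict local maxima; prominence =
# peak minus the higher of the two walk-to-higher-sample side minima;
# greedy min-separation by decreasing value), implemented naively with
# explicit walks.
brute_peaks <- function(values, min_prominence = 0, min_separation = 1) {
  n <- length(values)
  peaks <- integer(0); proms <- numeric(0)
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (!(values[i] > values[i - 1] && values[i] > values[i + 1])) next
      left_min <- values[i]
      j <- i - 1
      while (j >= 1 && values[j] <= values[i]) {
        if (values[j] < left_min) left_min <- values[j]
        j <- j - 1
      }
      right_min <- values[i]
      j <- i + 1
      while (j <= n && values[j] <= values[i]) {
        if (values[j] < right_min) right_min <- values[j]
        j <- j + 1
      }
      p <- values[i] - max(left_min, right_min)
      if (p >= min_prominence) {
        peaks <- c(peaks, i); proms <- c(proms, p)
      }
    }
  }
  if (length(peaks) && min_separation > 1) {
    ord <- order(-values[peaks], peaks)
    kept <- integer(0)
    for (p in peaks[ord]) {
      conflict <- FALSE
      for (q in kept) if (abs(q - p) < min_separation) conflict <- TRUE
      if (!conflict) kept <- c(kept, p)
    }
    sel <- peaks %in% kept
    peaks <- peaks[sel]; proms <- proms[sel]
  }
  data.frame(index = peaks, prominence = proms)
}

# random test traces of varied character for property tests
random_trace_values <- function(n) {
  switch(sample(3, 1),
         stats::rnorm(n),
         cumsum(stats::rnorm(n)),
         stats::runif(n) + 2 * sin(seq_len(n) / 5))
}
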