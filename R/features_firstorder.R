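#' First-order intensity features
#'
#' The 18 standard first-order statistics of the in-ROI intensity
#' distribution. `Entropy` and `Uniformity` are computed on the discretized
#' gray levels; everything else on the raw intensities. Skewness and
#' kurtosis use population moments (kurtosis is not excess-corrected, so a
#' normal sample gives ~3); both are defined as 0 for a constant ROI so
#' feature tables stay complete.
#'
#' @param x numeric vector of in-ROI intensities.
#' @param levels integer vector of in-ROI discretized gray levels.
#' @param voxel_volume_mm3 volume of one voxel, mm^3 (for `TotalEnergy`).
#' @return Named numeric vector of length 18.
#' @export
first_order_features <- function(x, levels, voxel_volume_mm3 = 1) {
  stop_if_not(length(x) > 0, "empty ROI")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  sub <- x[x >= qs[1] & x <= qs[5]]
  p <- tabulate(levels) / length(levels)
  p <- p[p > 0]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume_mm3 * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(sub - mean(sub))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = skew,
    Kurtosis = kurt,
    Uniformity = sum(p^2))
}
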