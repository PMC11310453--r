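#' Shared color scheme for all HDX plots and PyMOL scripts
#'
#' One scheme object is consumed by every plot builder and by
#' [pymolScript()], so significant peptides look the same everywhere:
#' blue = protection (deltaD < 0, slower exchange in the test state),
#' red = deprotection (deltaD > 0), grey = not significant. A diverging
#' blue-white-red gradient encodes deltaD magnitude in heatmaps and
#' gradient-mode PyMOL scripts, and an ordered palette distinguishes
#' timepoints.
#'
#' @param protect color for significant protection (deltaD < 0).
#' @param deprotect color for significant deprotection (deltaD > 0).
#' @param ns color for non-significant elements.
#' @param neutral neutral color for uncovered residues on structures.
#' @param timepointColors base colors for timepoint series (interpolated
#'   when more timepoints are drawn than colors given).
#' @param gradient length-3 vector (low, mid, high) for the diverging
#'   deltaD color map.
#' @return A list of class `HDXColorScheme`.
#' @export
hdxColorScheme <- function(protect = "#2166AC", deprotect = "#B2182B",
                           ns = "grey60", neutral = "grey80",
                           timepointColors = c("#1B9E77", "#D95F02",
                                               "#7570B3", "#E7298A",
                                               "#66A61E", "#E6AB02",
                                               "#A6761D", "#666666"),
                           gradient = c("#2166AC", "#FFFFFF", "#B2182B")) {
  stopifnot(length(gradient) == 3, length(timepointColors) >= 1)
  structure(list(protect = protect, deprotect = deprotect, ns = ns,
                 neutral = neutral, timepointColors = timepointColors,
                 gradient = gradient),
            class = "HDXColorScheme")
}

# n timepoint colors, interpolating beyond the base palette
timepointPalette <- function(scheme, n) {
  base <- scheme$timepointColors
  if (n <= length(base)) base[seq_len(n)]
  else grDevices::colorRampPalette(base)(n)
}

# map values in [-maxAbs, maxAbs] onto the diverging gradient
gradientColors <- function(scheme, values, maxAbs = max(abs(values), na.rm = TRUE)) {
  if (!is.finite(maxAbs) || maxAbs == 0) maxAbs <- 1
  ramp <- grDevices::colorRamp(scheme$gradient)
  v <- pmin(pmax(values / maxAbs, -1), 1)
  out <- rep(NA_character_, length(v))
  okv <- !is.na(v)
  if (any(okv)) {
    rgb <- ramp((v[okv] + 1) / 2)
    out[okv] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  out
}
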