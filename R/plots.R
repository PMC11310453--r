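#' Volcano plot of uptake differences
#'
#' Plots deltaD (test - reference, Da) against -log10(p) for one comparison,
#' with vertical guides at the critical interval (+/- ciDa) and a horizontal
#' guide at -log10(alpha). Points passing the hybrid test are colored
#' protect/deprotect by the sign of deltaD; others use the non-significant
#' color. Zero p-values are clipped to the smallest positive representable
#' number before the log.
#'
#' @param x an [HDXComparisonSet-class].
#' @param comparison test-state label; default the first comparison.
#' @param timepoint optional exposure filter (default: all timepoints).
#' @param scheme an [hdxColorScheme()].
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, a data.frame of the plotted points
#'   (`deltaDa`, `negLog10P`, `significant`, `color`) plus the guide
#'   positions as attributes `ciDa` and `alphaLine`.
#' @export
plotVolcano <- function(x, comparison = NULL, timepoint = NULL,
                        scheme = hdxColorScheme(), ...) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  r <- x@results
  if (is.null(comparison)) comparison <- r$comparison[1]
  r <- r[r$comparison == comparison, , drop = FALSE]
  if (!is.null(timepoint)) r <- r[r$timepoint %in% timepoint, , drop = FALSE]
  r <- r[r$tested & !is.na(r$pValue), , drop = FALSE]
  if (nrow(r) == 0) stop("no tested results for this comparison")
  ci <- x@intervals$ciDa[x@intervals$comparison == comparison]
  p <- pmax(r$pValue, .Machine$double.xmin)
  y <- -log10(p)
  col <- ifelse(r$significant, ifelse(r$deltaDa > 0, scheme$deprotect,
                                      scheme$protect), scheme$ns)
  xlim <- range(c(r$deltaDa, -ci, ci), finite = TRUE) * 1.1
  graphics::plot(r$deltaDa, y, pch = 19, col = col, xlim = xlim,
                 xlab = expression(Delta * D ~ "(Da)"),
                 ylab = expression(-log[10] ~ italic(p)),
                 main = paste0(comparison, " vs ", x@states[1]), ...)
  graphics::abline(v = c(-ci, ci), lty = 2, col = "grey40")
  graphics::abline(h = -log10(x@alpha), lty = 2, col = "grey40")
  out <- data.frame(deltaDa = r$deltaDa, negLog10P = y,
                    significant = r$significant, color = col)
  attr(out, "ciDa") <- ci
  attr(out, "alphaLine") <- -log10(x@alpha)
  invisible(out)
}

#' Woods plot of uptake differences along the sequence
#'
#' Draws one horizontal segment per peptide from its start to its end
#' residue at height deltaD (Da) for a single comparison and timepoint,
#' with the +/- critical-interval band shaded. `mode = "significant"`
#' draws only peptides flagged by the hybrid test (the band is always
#' drawn, so a null comparison yields empty axes with the band).
#'
#' @param x an [HDXComparisonSet-class].
#' @param comparison test-state label; default the first comparison.
#' @param timepoint exposure in seconds; default the first timepoint.
#' @param mode `"all"` or `"significant"`.
#' @param scheme an [hdxColorScheme()].
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, the data.frame of drawn segments
#'   (`start`, `end`, `deltaDa`, `significant`, `color`).
#' @export
plotWoods <- function(x, comparison = NULL, timepoint = NULL,
                      mode = c("all", "significant"),
                      scheme = hdxColorScheme(), ...) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  mode <- match.arg(mode)
  r <- x@results
  if (is.null(comparison)) comparison <- r$comparison[1]
  if (is.null(timepoint)) timepoint <- min(r$timepoint)
  if (!timepoint %in% r$timepoint) stop("unknown timepoint")
  r <- r[r$comparison == comparison & r$timepoint == timepoint, , drop = FALSE]
  ci <- x@intervals$ciDa[x@intervals$comparison == comparison]
  seg <- r[!is.na(r$deltaDa), , drop = FALSE]
  if (mode == "significant") seg <- seg[seg$significant %in% TRUE, , drop = FALSE]
  col <- if (nrow(seg)) ifelse(seg$significant %in% TRUE,
                               ifelse(seg$deltaDa > 0, scheme$deprotect,
                                      scheme$protect), scheme$ns)
         else character(0)
  xlim <- c(min(r$start), max(r$end))
  ylim <- range(c(seg$deltaDa, -ci, ci, 0), finite = TRUE) * 1.15
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "Residue",
                 ylab = expression(Delta * D ~ "(Da)"),
                 main = sprintf("%s vs %s, %gs", comparison, x@states[1],
                                timepoint), ...)
  graphics::rect(xlim[1] - 1e3, -ci, xlim[2] + 1e3, ci,
                 col = grDevices::adjustcolor("grey80", 0.5), border = NA)
  graphics::abline(h = 0, col = "grey40")
  if (nrow(seg))
    graphics::segments(seg$start, seg$deltaDa, seg$end, seg$deltaDa,
                       col = col, lwd = 2)
  out <- data.frame(start = seg$start, end = seg$end, deltaDa = seg$deltaDa,
                    significant = seg$significant, color = col)
  attr(out, "ciDa") <- ci
  invisible(out)
}

#' Robot plot: mirrored percent-deuteration comparison of two states
#'
#' A modified butterfly plot for one comparison. The x-axis is residue
#' number; the reference state is drawn on the positive y-axis and the test
#' state mirrored on the negative y-axis, both in percent deuteration. Only
#' peptides significant at one or more timepoints of the comparison are
#' drawn. For each included peptide and timepoint a horizontal bar spans
#' start..end at the state's mean %D, a vertical bar at the peptide
#' midpoint shows +/- SD of %D, and a dot at the midpoint is colored by
#' the timepoint palette when the hybrid test flags that timepoint, grey
#' otherwise.
#'
#' @param x an [HDXComparisonSet-class].
#' @param comparison test-state label; required when the set holds more
#'   than one comparison (invoke per comparison).
#' @param scheme an [hdxColorScheme()].
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, the data.frame of drawn elements: one row per
#'   (peptide, timepoint, side) with `start`, `end`, `mid`, `y`, `sd`,
#'   `timepoint`, `significant`, `dotColor`; empty when no peptide is
#'   significant in the time course.
#' @export
plotRobot <- function(x, comparison = NULL, scheme = hdxColorScheme(), ...) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  cmps <- unique(x@results$comparison)
  if (is.null(comparison)) {
    if (length(cmps) > 1)
      stop("comparison set holds ", length(cmps), " comparisons; robot ",
           "plots compare exactly two states - invoke per comparison")
    comparison <- cmps[1]
  }
  r <- x@results[x@results$comparison == comparison, , drop = FALSE]
  if (nrow(r) == 0) stop("unknown comparison label")
  tps <- sort(unique(r$timepoint))
  pal <- timepointPalette(scheme, length(tps))
  sig <- significantPeptides(x, comparison)[[1]]
  keyOf <- function(d) paste(d$sequence, d$start, d$end, sep = "\r")
  r <- r[keyOf(r) %in% keyOf(sig), , drop = FALSE]

  ymax <- max(c(r$meanPctRef + r$sdPctRef, r$meanPctTest + r$sdPctTest,
                10), na.rm = TRUE)
  xlim <- if (nrow(r)) c(min(r$start), max(r$end))
          else c(min(x@results$start), max(x@results$end))
  graphics::plot(NA, xlim = xlim, ylim = c(-ymax, ymax) * 1.05,
                 xlab = "Residue", ylab = "Deuteration (%)",
                 main = sprintf("%s (down) vs %s (up)", comparison,
                                x@states[1]), ...)
  graphics::abline(h = 0, col = "grey40")
  if (nrow(r) == 0) return(invisible(
    data.frame(start = integer(0), end = integer(0), mid = numeric(0),
               y = numeric(0), sd = numeric(0), timepoint = numeric(0),
               significant = logical(0), dotColor = character(0))))

  mid <- (r$start + r$end) / 2
  tpCol <- pal[match(r$timepoint, tps)]
  dotCol <- ifelse(r$significant %in% TRUE, tpCol, scheme$ns)
  draw <- function(y, sd) {
    graphics::segments(r$start, y, r$end, y, col = tpCol, lwd = 2)
    graphics::segments(mid, y - sd, mid, y + sd, col = tpCol)
    graphics::points(mid, y, pch = 19, col = dotCol, cex = 0.8)
  }
  draw(r$meanPctRef, r$sdPctRef)
  draw(-r$meanPctTest, r$sdPctTest)
  graphics::legend("topright", legend = sprintf("%gs", tps), col = pal,
                   lwd = 2, cex = 0.7, bty = "n")
  out <- rbind(
    data.frame(start = r$start, end = r$end, mid = mid, y = r$meanPctRef,
               sd = r$sdPctRef, timepoint = r$timepoint,
               significant = r$significant, dotColor = dotCol,
               side = "reference"),
    data.frame(start = r$start, end = r$end, mid = mid, y = -r$meanPctTest,
               sd = r$sdPctTest, timepoint = r$timepoint,
               significant = r$significant, dotColor = dotCol,
               side = "test"))
  invisible(out)
}

# First-fit greedy interval packing: assign each interval (ordered by
# start, then end) to the lowest row whose previous interval it does not
# overlap (1-based inclusive coordinates: overlap iff start <= row end).
#' Pack peptide intervals into non-overlapping display rows
#'
#' @param start,end integer vectors of 1-based inclusive residue spans.
#' @return Integer vector of row assignments (1 = bottom row), in input
#'   order.
#' @export
packIntervals <- function(start, end) {
  stopifnot(length(start) == length(end), all(end >= start))
  o <- order(start, end)
  rowEnd <- numeric(0)
  rows <- integer(length(start))
  for (i in o) {
    slot <- which(rowEnd < start[i])
    if (length(slot) == 0) {
      rowEnd <- c(rowEnd, end[i])
      rows[i] <- length(rowEnd)
    } else {
      rows[i] <- slot[1]
      rowEnd[slot[1]] <- end[i]
    }
  }
  rows
}

#' Coverage map of peptides color-coded by significance
#'
#' Draws every matched peptide of one comparison and timepoint as a
#' horizontal segment, stacked into non-overlapping rows by first-fit
#' greedy packing, colored protect/deprotect when the hybrid test flags the
#' peptide and grey otherwise.
#'
#' @param x an [HDXComparisonSet-class].
#' @param comparison test-state label; default the first comparison.
#' @param timepoint exposure in seconds; default the first timepoint.
#' @param scheme an [hdxColorScheme()].
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, the data.frame of drawn segments with their packed
#'   `row` assignments.
#' @export
plotSignificantPeptideMap <- function(x, comparison = NULL, timepoint = NULL,
                                      scheme = hdxColorScheme(), ...) {
  stopifnot(methods::is(x, "HDXComparisonSet"))
  r <- x@results
  if (is.null(comparison)) comparison <- r$comparison[1]
  if (is.null(timepoint)) timepoint <- min(r$timepoint)
  r <- r[r$comparison == comparison & r$timepoint == timepoint, , drop = FALSE]
  if (nrow(r) == 0) stop("no results for this comparison/timepoint")
  r$row <- packIntervals(r$start, r$end)
  col <- ifelse(r$significant %in% TRUE,
                ifelse(r$deltaDa > 0, scheme$deprotect, scheme$protect),
                scheme$ns)
  graphics::plot(NA, xlim = c(min(r$start), max(r$end)),
                 ylim = c(0.5, max(r$row) + 0.5), yaxt = "n",
                 xlab = "Residue", ylab = "",
                 main = sprintf("Peptide map: %s vs %s, %gs", comparison,
                                x@states[1], timepoint), ...)
  graphics::rect(r$start - 0.4, r$row - 0.35, r$end + 0.4, r$row + 0.35,
                 col = col, border = "grey30")
  out <- data.frame(sequence = r$sequence, start = r$start, end = r$end,
                    row = r$row, significant = r$significant, color = col)
  invisible(out)
}

#' Uptake time course of one peptide across all states
#'
#' Mean deuterium uptake (Da) versus exposure time on a log-scaled x-axis,
#' one series per state, with error bars of +/- one replicate SD. A 0 s
#' exposure cannot sit on a log axis; it is drawn at a pseudo-position one
#' decade left of the earliest nonzero timepoint and labeled "0".
#'
#' @param table a [MatchedUptake-class].
#' @param sequence,start,end the peptide key to plot.
#' @param scheme an [hdxColorScheme()]; states are colored from the
#'   timepoint palette.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, a data.frame with one row per (state, timepoint):
#'   `state`, `timepoint`, `mean`, `sd`, `n`.
#' @export
plotUptake <- function(table, sequence, start, end,
                       scheme = hdxColorScheme(), ...) {
  stopifnot(methods::is(table, "MatchedUptake"))
  pep <- table@peptides
  pi <- which(pep$sequence == sequence & pep$start == start & pep$end == end)
  if (length(pi) != 1)
    stop("peptide ", sequence, " (", start, "-", end, ") not in table")
  tps <- table@timepoints
  states <- table@states
  rows <- do.call(rbind, lapply(seq_along(states), function(si) {
    vals <- matrix(table@uptake[pi, si, , ], nrow = length(tps))
    data.frame(state = states[si], timepoint = tps,
               mean = apply(vals, 1, mean, na.rm = TRUE),
               sd = apply(vals, 1, stats::sd, na.rm = TRUE),
               n = apply(!is.na(vals), 1, sum))
  }))
  posTps <- tps[tps > 0]
  x0 <- if (length(posTps)) min(posTps) / 10 else 1
  xpos <- ifelse(rows$timepoint == 0, x0, rows$timepoint)
  cols <- timepointPalette(scheme, length(states))
  ylim <- range(c(rows$mean - rows$sd, rows$mean + rows$sd, 0), na.rm = TRUE)
  graphics::plot(NA, xlim = range(xpos), ylim = ylim, log = "x",
                 xlab = "Exposure (s)", ylab = "Uptake (Da)", xaxt = "n",
                 main = sprintf("%s (%d-%d)", sequence, start, end), ...)
  ticks <- sort(unique(xpos))
  graphics::axis(1, at = ticks,
                 labels = ifelse(ticks == x0 & any(tps == 0), "0",
                                 format(ticks, trim = TRUE)))
  for (si in seq_along(states)) {
    sub <- rows[rows$state == states[si], ]
    sx <- ifelse(sub$timepoint == 0, x0, sub$timepoint)
    graphics::lines(sx, sub$mean, col = cols[si], type = "b", pch = 19)
    ok <- !is.na(sub$sd) & sub$sd > 0
    if (any(ok))
      graphics::arrows(sx[ok], sub$mean[ok] - sub$sd[ok], sx[ok],
                       sub$mean[ok] + sub$sd[ok], angle = 90, code = 3,
                       length = 0.03, col = cols[si])
  }
  graphics::legend("topleft", legend = states, col = cols, lwd = 1,
                   pch = 19, cex = 0.7, bty = "n")
  invisible(rows)
}

#' Residue-level heatmap of uptake differences
#'
#' Renders a [residueMatrix()] as an image: residues on the x-axis, columns
#' (timepoints or comparisons) on the y-axis, deltaD on the diverging
#' gradient of the scheme; uncovered residues are left blank.
#'
#' @param m a matrix from [residueMatrix()].
#' @param scheme an [hdxColorScheme()].
#' @param ... further arguments to [graphics::image()].
#' @return Invisibly, `m`.
#' @export
plotResidueHeatmap <- function(m, scheme = hdxColorScheme(), ...) {
  stopifnot(is.matrix(m))
  vals <- abs(m[!is.na(m)])
  maxAbs <- if (length(vals) && max(vals) > 0) max(vals) else 1
  pal <- grDevices::colorRampPalette(scheme$gradient)(101)
  graphics::image(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                  zlim = c(-maxAbs, maxAbs), col = pal, xlab = "Residue",
                  ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  invisible(m)
}
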