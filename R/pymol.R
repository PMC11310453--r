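#' Merge residue indices into maximal consecutive runs
#'
#' Collapses a set of residue indices into the minimal list of maximal
#' consecutive runs, the form PyMOL `resi` selections expect
#' (`10-12`, `40`).
#'
#' @param residues integer vector of residue indices (any order, duplicates
#'   ignored).
#' @return data.frame with columns `from`, `to`, one row per maximal run;
#'   zero rows for empty input.
#' @examples
#' mergeResidueRuns(c(10, 11, 12, 40))
#' @export
mergeResidueRuns <- function(residues) {
  r <- sort(unique(as.integer(residues)))
  if (length(r) == 0)
    return(data.frame(from = integer(0), to = integer(0)))
  breaks <- which(diff(r) > 1L)
  from <- r[c(1L, breaks + 1L)]
  to <- r[c(breaks, length(r))]
  data.frame(from = from, to = to)
}

# "10-12+40" style selection text from a run table
runsToSelection <- function(runs, offset = 0L) {
  if (nrow(runs) == 0) return("")
  paste(ifelse(runs$from == runs$to,
               sprintf("%d", runs$from + offset),
               sprintf("%d-%d", runs$from + offset, runs$to + offset)),
        collapse = "+")
}

# parse a "10-12+40" selection back into residue indices (used by the
# round-trip tests)
parseResiSelection <- function(sel) {
  if (identical(sel, "") || length(sel) == 0) return(integer(0))
  parts <- strsplit(sel, "+", fixed = TRUE)[[1]]
  sort(unique(unlist(lapply(parts, function(p) {
    ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(ab) == 1) ab else ab[1]:ab[2]
  }))))
}

hexToPymolColor <- function(hex) {
  rgb <- grDevices::col2rgb(hex) / 255
  sprintf("[%.3f, %.3f, %.3f]", rgb[1], rgb[2], rgb[3])
}

#' Generate a PyMOL residue-coloring script
#'
#' Builds a self-contained `.pml` command script coloring residues of an
#' already-loaded structure by differential HDX. Coloring is by residue
#' (via the residue-level projection of [residueMatrix()]), which resolves
#' overlapping peptides deterministically. The script defines its custom
#' colors before use, contains no `load` line and no absolute paths, and
#' colors everything neutral first so uncovered residues are visually
#' distinct.
#'
#' Two modes: `"significant"` colors residues covered by significant
#' peptides protect/deprotect by the sign of the residue-mean deltaD and
#' everything else neutral; `"gradient"` assigns each covered residue its
#' own color from the diverging deltaD gradient. Consecutive residues are
#' merged into `resi a-b` ranges.
#'
#' @param values named or plain numeric vector of per-residue deltaD (Da),
#'   position i = residue i, `NA` = uncovered — typically one column of a
#'   [residueMatrix()] (mode `"significant"` expects the
#'   significant-only matrix).
#' @param scheme an [hdxColorScheme()].
#' @param mode `"significant"` or `"gradient"`.
#' @param comparison,timepoint labels recorded in the object and the script
#'   header comment.
#' @param chain optional chain identifier to restrict the selections to.
#' @param offset integer added to residue numbering (structure numbering
#'   minus peptide numbering).
#' @return A [PymolScript-class].
#' @examples
#' v <- rep(NA_real_, 50); v[10:12] <- 0.8; v[40] <- -0.5
#' pymolScript(v, comparison = "bound", timepoint = 60)
#' @export
pymolScript <- function(values, scheme = hdxColorScheme(),
                        mode = c("significant", "gradient"),
                        comparison = "comparison", timepoint = NA_real_,
                        chain = NULL, offset = 0L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(values))
  sel <- function(resiText) {
    if (is.null(chain)) sprintf("resi %s", resiText)
    else sprintf("chain %s and resi %s", chain, resiText)
  }
  header <- c(
    sprintf("# differential HDX coloring: %s%s", comparison,
            if (is.na(timepoint)) "" else sprintf(" at %gs", timepoint)),
    sprintf("# mode: %s; residues colored by mean uptake difference", mode),
    sprintf("set_color hdx_protect, %s", hexToPymolColor(scheme$protect)),
    sprintf("set_color hdx_deprotect, %s", hexToPymolColor(scheme$deprotect)),
    sprintf("set_color hdx_neutral, %s", hexToPymolColor(scheme$neutral)),
    "color hdx_neutral, polymer")

  covered <- which(!is.na(values))
  if (mode == "significant") {
    protect <- which(!is.na(values) & values < 0)
    deprotect <- which(!is.na(values) & values > 0)
    body <- character(0)
    if (length(protect))
      body <- c(body, sprintf("color hdx_protect, %s",
                              sel(runsToSelection(mergeResidueRuns(protect),
                                                  offset))))
    if (length(deprotect))
      body <- c(body, sprintf("color hdx_deprotect, %s",
                              sel(runsToSelection(mergeResidueRuns(deprotect),
                                                  offset))))
    if (length(protect) + length(deprotect) == 0)
      body <- "# no significant residues for this comparison"
  } else {
    if (length(covered) == 0) {
      body <- "# no covered residues for this comparison"
    } else {
      cols <- gradientColors(scheme, values[covered])
      body <- as.vector(rbind(
        sprintf("set_color hdx_res_%d, %s", covered + offset,
                vapply(cols, hexToPymolColor, "")),
        sprintf("color hdx_res_%d, %s", covered + offset,
                sel(as.character(covered + offset)))))
    }
  }
  methods::new("PymolScript", lines = c(header, body), mode = mode,
               comparison = comparison, timepoint = as.numeric(timepoint))
}

#' Write a PyMOL script to a `.pml` file
#'
#' @param script a [PymolScript-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writePymolScript <- function(script, path) {
  stopifnot(methods::is(script, "PymolScript"))
  writeLines(script@lines, path)
  invisible(path)
}
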