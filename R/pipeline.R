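#' Run the full differential HDX-MS analysis pipeline
#'
#' End-to-end driver: reads an HDExaminer-style export, matches peptides
#' across states, runs the hybrid significance analysis against the
#' reference state, and writes every standard output into `outputDir`:
#' the matched-peptide CSV, one verbose statistics CSV per comparison, the
#' publication summary table, the plot suite (volcano, Woods, robot,
#' significant-peptide map, residue heatmap; one file per comparison) and
#' one PyMOL script per comparison. Peptide-drop and significance counts
#' are logged via messages. On any error the partial outputs created by
#' this invocation are removed before the error propagates.
#'
#' Given identical inputs and configuration the tabular and PyMOL outputs
#' are byte-identical across runs (PDF plot files embed a creation
#' timestamp in their header and are identical in content only).
#'
#' @param inputPath path to the export file.
#' @param outputDir directory for outputs (created if absent).
#' @param reference reference state label; default the first state in the
#'   file.
#' @param alpha hybrid-test significance level.
#' @param proteinLength protein length in residues; default inferred.
#' @param dialect an [hdxDialect()].
#' @param scheme an [hdxColorScheme()].
#' @param significantOnly restrict Woods plots and heatmaps to significant
#'   peptides.
#' @param plots,pymol logical toggles for the plot suite and PyMOL scripts.
#' @return Invisibly, a list with the `HDXDataSet`, `MatchedUptake`,
#'   `HDXComparisonSet`, summary data.frame and the vector of files
#'   written.
#' @export
runPipeline <- function(inputPath, outputDir, reference = NULL,
                        alpha = 0.01, proteinLength = NULL,
                        dialect = hdxDialect(), scheme = hdxColorScheme(),
                        significantOnly = FALSE, plots = TRUE,
                        pymol = TRUE) {
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(outputDir, name)
    written <<- c(written, p)
    p
  }
  safe <- function(s) gsub("[^A-Za-z0-9._-]", "_", s)
  result <- tryCatch({
    ds <- readHDExaminer(inputPath, dialect)
    mt <- matchPeptides(ds, reference = reference)
    cs <- compareStates(mt, alpha = alpha)
    sm <- buildSummary(mt, ds, proteinLength = proteinLength, alpha = alpha)

    writeMatchedCsv(mt, out("matched_uptake.csv"))
    writePublicationTable(sm, out("summary_table.csv"))
    cmps <- stateLabels(cs)[-1]
    nSig <- integer(0)
    for (cmp in cmps) {
      writeVerboseCsv(cs, out(sprintf("verbose_%s.csv", safe(cmp))),
                      comparison = cmp)
      nSig[cmp] <- nrow(significantPeptides(cs, cmp)[[1]])
    }
    message("runPipeline: significant peptides per comparison: ",
            paste(sprintf("%s=%d", names(nSig), nSig), collapse = ", "))

    if (plots) {
      mode <- if (significantOnly) "significant" else "all"
      for (cmp in cmps) {
        f <- out(sprintf("volcano_%s.pdf", safe(cmp)))
        grDevices::pdf(f, width = 6, height = 5)
        plotVolcano(cs, cmp, scheme = scheme)
        grDevices::dev.off()
        f <- out(sprintf("woods_%s.pdf", safe(cmp)))
        grDevices::pdf(f, width = 7, height = 5)
        for (tp in sort(unique(cs@results$timepoint)))
          plotWoods(cs, cmp, tp, mode = mode, scheme = scheme)
        grDevices::dev.off()
        f <- out(sprintf("robot_%s.pdf", safe(cmp)))
        grDevices::pdf(f, width = 8, height = 5)
        plotRobot(cs, cmp, scheme = scheme)
        grDevices::dev.off()
        f <- out(sprintf("peptide_map_%s.pdf", safe(cmp)))
        grDevices::pdf(f, width = 8, height = 4)
        plotSignificantPeptideMap(cs, cmp, scheme = scheme)
        grDevices::dev.off()
        f <- out(sprintf("heatmap_%s.pdf", safe(cmp)))
        grDevices::pdf(f, width = 8, height = 3)
        m <- residueMatrix(cs, comparison = cmp, mode = mode,
                           proteinLength = proteinLength)
        plotResidueHeatmap(m, scheme = scheme,
                           main = sprintf("%s vs %s", cmp, stateLabels(cs)[1]))
        grDevices::dev.off()
      }
    }
    if (pymol) {
      for (cmp in cmps) {
        for (tp in sort(unique(cs@results$timepoint))) {
          m <- residueMatrix(cs, comparison = cmp, timepoint = tp,
                             mode = "significant",
                             proteinLength = proteinLength)
          sc <- pymolScript(m[, 1], scheme = scheme, mode = "significant",
                            comparison = cmp, timepoint = tp)
          writePymolScript(sc, out(sprintf("pymol_%s_%gs.pml", safe(cmp), tp)))
        }
      }
    }
    list(dataset = ds, matched = mt, comparisons = cs, summary = sm,
         files = written)
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    stop("runPipeline failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
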