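#' Describe the column layout of an HDExaminer-style export
#'
#' HDExaminer "all results" exports vary in header spelling, time-unit
#' conventions and decimal separators across versions and localisations.
#' A dialect maps the canonical fields used by [readHDExaminer()] onto the
#' header strings actually present in the file. Header matching is
#' case-insensitive after trimming; each canonical field may list several
#' candidate headers, the first one found wins.
#'
#' Canonical fields: `state`, `sequence`, `start`, `end`, `charge`,
#' `exposure`, `replicate`, `uptake`, `percentD`. `charge`, `replicate` and
#' one of `uptake`/`percentD` are optional in the file.
#'
#' @param state,sequence,start,end,charge,exposure,replicate,uptake,percentD
#'   character vectors of candidate header strings for each canonical field.
#' @param timeUnit unit assumed for bare numeric exposure values:
#'   `"seconds"`, `"minutes"` or `"hours"`. Suffixed tokens such as `"30s"`,
#'   `"5m"`, `"1h"` always override this.
#' @param decimalSeparator decimal mark used in numeric fields (`"."` or `","`).
#' @param fdStates state labels treated as fully-deuterated (FD) controls.
#' @return A named list of class parameters, passed to [readHDExaminer()].
#' @examples
#' d <- hdxDialect(timeUnit = "minutes")
#' d$timeUnit
#' @export
hdxDialect <- function(state = c("Protein State", "State", "Protein"),
                       sequence = c("Sequence", "Peptide"),
                       start = c("Start", "Start RT", "First Residue"),
                       end = c("End", "Last Residue"),
                       charge = c("Charge", "z"),
                       exposure = c("Deut Time", "Exposure", "Time",
                                    "Deut Time (sec)"),
                       replicate = c("Replicate", "File", "Experiment"),
                       uptake = c("#D", "# Deut", "Uptake", "D"),
                       percentD = c("%D", "% Deut", "Percent D"),
                       timeUnit = c("seconds", "minutes", "hours"),
                       decimalSeparator = ".",
                       fdStates = c("FD", "Full Deuteration", "Full-D",
                                    "MaxD", "Fully Deuterated")) {
  timeUnit <- match.arg(timeUnit)
  stopifnot(decimalSeparator %in% c(".", ","))
  list(map = list(state = state, sequence = sequence, start = start,
                  end = end, charge = charge, exposure = exposure,
                  replicate = replicate, uptake = uptake,
                  percentD = percentD),
       timeUnit = timeUnit,
       decimalSeparator = decimalSeparator,
       fdStates = fdStates)
}

# Parse exposure tokens like "0s", "30s", "5m", "1.5h", "10 min" or bare
# numbers (interpreted in `unit`). Returns seconds; NA when unparseable.
parseExposure <- function(x, unit = "seconds") {
  x <- trimws(as.character(x))
  unitFactor <- c(seconds = 1, minutes = 60, hours = 3600)[[unit]]
  m <- regmatches(x, regexec(
    "^([0-9]*\\.?[0-9]+)\\s*(s|sec|secs|seconds|m|min|mins|minutes|h|hr|hrs|hours)?$",
    x, ignore.case = TRUE))
  vapply(m, function(g) {
    if (length(g) == 0) return(NA_real_)
    v <- as.numeric(g[2])
    suf <- tolower(g[3])
    f <- if (suf == "") unitFactor
         else if (startsWith(suf, "s")) 1
         else if (startsWith(suf, "m")) 60
         else 3600
    v * f
  }, numeric(1))
}

# Resolve dialect header candidates against the file header.
# Returns named list canonical -> column index (NA when absent).
resolveColumns <- function(header, dialect) {
  norm <- tolower(trimws(header))
  lapply(dialect$map, function(cands) {
    hit <- match(tolower(trimws(cands)), norm)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
}
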