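# Shared fixture builders: all fixtures are generated in code at test time.

# Write a tiny hand-rolled export file; rows is a data.frame with columns
# state, sequence, start, end, charge, time, replicate, uptake, percentD
# (character-friendly: values are written as given).
writeTinyExport <- function(rows, path = tempfile(fileext = ".csv"),
                            sep = ",") {
  header <- c("Protein State", "Sequence", "Start", "End", "Charge",
              "Deut Time", "Replicate", "#D", "%D")
  lines <- c(paste(header, collapse = sep),
             apply(rows, 1, paste, collapse = sep))
  writeLines(lines, path)
  path
}

# A 4-row fixture: 2 states x 1 timepoint x 2 replicates of one peptide.
tinyRows <- function() {
  data.frame(
    state = rep(c("apo", "bound"), each = 2),
    sequence = "ACDEFGHIK", start = 10, end = 18, charge = 2,
    time = "60s", replicate = c(1, 2, 1, 2),
    uptake = c("1.10", "1.20", "2.10", "2.20"),
    percentD = c("15.7", "17.1", "30.0", "31.4"),
    stringsAsFactors = FALSE)
}

# Records data.frame for direct matchPeptides() input.
makeRecords <- function(state, sequence, start, end, exposure, replicate,
                        uptake, percentD = NA_real_, charge = 2L,
                        isFD = FALSE) {
  data.frame(state = state, sequence = sequence, start = start, end = end,
             charge = charge, exposure = exposure, replicate = replicate,
             uptake = uptake,
             percentD = if (all(is.na(percentD))) uptake * 10 else percentD,
             isFD = isFD, stringsAsFactors = FALSE)
}

# Fully crossed records for given peptide keys/states/timepoints/replicates,
# uptake from a supplied function f(state, peptideIndex, timepoint, replicate).
crossedRecords <- function(peptides, states, timepoints, replicates, f) {
  g <- expand.grid(p = seq_len(nrow(peptides)), s = states, t = timepoints,
                   r = seq_len(replicates), stringsAsFactors = FALSE)
  makeRecords(state = g$s, sequence = peptides$sequence[g$p],
              start = peptides$start[g$p], end = peptides$end[g$p],
              exposure = g$t, replicate = g$r,
              uptake = mapply(f, g$s, g$p, g$t, g$r))
}

pepKey <- function(df) paste(df$sequence, df$start, df$end, sep = "\r")
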