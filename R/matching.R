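#' Match peptides across protein states into an aligned uptake table
#'
#' Builds the [MatchedUptake-class] used by all downstream statistics: the
#' set of peptides (sequence + 1-based inclusive residue span) observed in
#' every protein state at every shared exposure time. Fully-deuterated
#' control rows are excluded. Multiple charge-state rows for the same
#' (state, peptide, exposure, replicate) are averaged into one observation
#' before matching, so the matching key is purely the biological identity
#' of the peptide. Peptides excluded by the intersection are counted per
#' state and reported via a message.
#'
#' @param x an [HDXDataSet-class] from [readHDExaminer()], or a data.frame
#'   with the same record columns (as returned in the `records` element of
#'   [simulateHDXExport()] output).
#' @param reference state label to use as the comparison reference; defaults
#'   to the first state encountered in the records.
#' @param timeTolerance absolute tolerance in seconds when intersecting
#'   exposure times across states (default 0: exact matching after unit
#'   normalisation).
#' @return A [MatchedUptake-class] with states ordered reference-first.
#' @examples
#' sim <- simulateHDXExport(hdxSimConfig(nStates = 3, nPeptides = 12, seed = 7))
#' mt <- matchPeptides(sim$records)
#' mt
#' @export
matchPeptides <- function(x, reference = NULL, timeTolerance = 0) {
  rec <- if (methods::is(x, "HDXDataSet")) peptideRecords(x) else x
  stopifnot(is.data.frame(rec))
  rec <- rec[!rec$isFD, , drop = FALSE]
  if (nrow(rec) == 0) stop("no non-FD records to match")

  states <- unique(rec$state)
  if (!is.null(reference)) {
    if (!reference %in% states)
      stop("reference state ", shQuote(reference), " not present; states: ",
           paste(states, collapse = ", "))
    states <- c(reference, setdiff(states, reference))
  }

  # average across charge states first
  agg <- stats::aggregate(
    cbind(uptake, percentD) ~ state + sequence + start + end + exposure + replicate,
    data = rec, na.action = stats::na.pass,
    FUN = function(v) { m <- mean(v, na.rm = TRUE); if (is.nan(m)) NA_real_ else m })

  # shared timepoints: intersection across states (with optional tolerance)
  tpByState <- lapply(states, function(s) sort(unique(agg$exposure[agg$state == s])))
  shared <- Reduce(function(a, b) {
    if (timeTolerance == 0) intersect(a, b)
    else a[vapply(a, function(t) any(abs(b - t) <= timeTolerance), logical(1))]
  }, tpByState)
  shared <- sort(unique(shared))
  if (length(shared) == 0)
    stop("states share no exposure times; cannot match")
  if (timeTolerance > 0) {
    # snap each observation's exposure onto the shared grid
    snap <- vapply(agg$exposure, function(t) {
      i <- which(abs(shared - t) <= timeTolerance)
      if (length(i) == 0) NA_real_ else shared[which.min(abs(shared - t))]
    }, numeric(1))
    agg$exposure <- snap
    agg <- agg[!is.na(agg$exposure), , drop = FALSE]
  } else {
    agg <- agg[agg$exposure %in% shared, , drop = FALSE]
  }

  key <- paste(agg$sequence, agg$start, agg$end, sep = "\r")
  # per state: peptides observed at every shared timepoint
  eligible <- lapply(states, function(s) {
    sub <- agg[agg$state == s, , drop = FALSE]
    k <- paste(sub$sequence, sub$start, sub$end, sep = "\r")
    tpPerKey <- tapply(sub$exposure, k, function(e) length(unique(e)))
    names(tpPerKey)[tpPerKey == length(shared)]
  })
  matched <- Reduce(intersect, eligible)
  if (length(matched) == 0) {
    worst <- states[which.min(lengths(eligible))]
    stop("peptide intersection across states is empty; state with least ",
         "overlap: ", shQuote(worst))
  }
  allKeysByState <- lapply(states, function(s) unique(key[agg$state == s]))
  dropped <- stats::setNames(
    as.integer(lengths(allKeysByState) - length(matched)), states)
  if (sum(dropped) > 0)
    message("matchPeptides: dropped peptides per state: ",
            paste(sprintf("%s=%d", states, dropped), collapse = ", "))

  parts <- strsplit(matched, "\r", fixed = TRUE)
  pep <- data.frame(sequence = vapply(parts, `[`, "", 1),
                    start = as.integer(vapply(parts, `[`, "", 2)),
                    end = as.integer(vapply(parts, `[`, "", 3)),
                    stringsAsFactors = FALSE)
  o <- order(pep$start, pep$end, pep$sequence)
  pep <- pep[o, , drop = FALSE]
  rownames(pep) <- NULL
  pepKey <- paste(pep$sequence, pep$start, pep$end, sep = "\r")

  sub <- agg[key %in% matched, , drop = FALSE]
  subKey <- paste(sub$sequence, sub$start, sub$end, sep = "\r")
  pi <- match(subKey, pepKey)
  si <- match(sub$state, states)
  ti <- match(sub$exposure, shared)
  # rank replicates within each cell by their replicate id (stable)
  cell <- paste(pi, si, ti, sep = ":")
  rr <- as.integer(stats::ave(sub$replicate, cell,
                              FUN = function(r) rank(r, ties.method = "first")))
  maxRep <- max(rr)
  dims <- c(length(pepKey), length(states), length(shared), maxRep)
  up <- array(NA_real_, dims,
              dimnames = list(NULL, states, shared, NULL))
  pc <- array(NA_real_, dims, dimnames = dimnames(up))
  idx <- cbind(pi, si, ti, rr)
  up[idx] <- sub$uptake
  pc[idx] <- sub$percentD

  methods::new("MatchedUptake", peptides = pep, states = states,
               timepoints = shared, uptake = up, percentD = pc,
               dropped = dropped)
}

#' Change the reference state of a matched table
#'
#' Returns an otherwise identical [MatchedUptake-class] with the states
#' rotated so that `newReference` comes first; the relative order of the
#' remaining states is preserved and no values are touched.
#'
#' @param table a [MatchedUptake-class].
#' @param newReference a state label present in the table.
#' @return A [MatchedUptake-class].
#' @export
reorderReference <- function(table, newReference) {
  stopifnot(methods::is(table, "MatchedUptake"))
  states <- table@states
  if (!newReference %in% states)
    stop("state ", shQuote(newReference), " not in table; states: ",
         paste(states, collapse = ", "))
  neworder <- c(newReference, setdiff(states, newReference))
  perm <- match(neworder, states)
  methods::new("MatchedUptake", peptides = table@peptides,
               states = neworder, timepoints = table@timepoints,
               uptake = table@uptake[, perm, , , drop = FALSE],
               percentD = table@percentD[, perm, , , drop = FALSE],
               dropped = table@dropped[perm])
}
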