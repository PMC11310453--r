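#' Configuration for the synthetic HDX-MS export generator
#'
#' Defines the simulated experiment: its defaults mirror a realistic
#' multi-state comparison campaign (eight protein states, four exposure
#' times, four technical replicates, replicate noise of 0.05 Da — the scale
#' typical of peptide-level HDX-MS uptake SDs). The seed fully determines
#' the output, including the protein sequence, peptide map and exchange
#' kinetics.
#'
#' @param nStates number of protein states (the first is the reference).
#' @param nTimepoints number of nonzero exposure times; used only when
#'   `timepoints` is NULL.
#' @param nReplicates technical replicates per state.
#' @param nPeptides number of peptides in the map.
#' @param proteinLength protein length in residues.
#' @param timepoints explicit nonzero exposure times in seconds; default
#'   log-spaced between 30 s and 14400 s.
#' @param effects data.frame describing injected uptake differences, with
#'   columns `peptide` (index into the generated peptide map), `state`
#'   (label or index >= 2), `deltaDa`, and optionally `timepoint` (seconds;
#'   `NA`/absent = all timepoints). `NULL` for null data.
#' @param noiseSd replicate noise SD in Da.
#' @param backExchangePct simulated back exchange in percent (uniform over
#'   peptides).
#' @param includeFd also emit a fully-deuterated control state.
#' @param stateNames state labels; default `State1..StateN`.
#' @param seed integer RNG seed.
#' @return A list of class `HDXSimConfig`.
#' @export
hdxSimConfig <- function(nStates = 8, nTimepoints = 4, nReplicates = 4,
                         nPeptides = 50, proteinLength = 250,
                         timepoints = NULL, effects = NULL,
                         noiseSd = 0.05, backExchangePct = 15,
                         includeFd = TRUE, stateNames = NULL, seed = 1) {
  stopifnot(nStates >= 1, nTimepoints >= 1, nReplicates >= 1, nPeptides >= 1,
            proteinLength >= 25, noiseSd >= 0,
            backExchangePct >= 0, backExchangePct < 100)
  if (is.null(timepoints))
    timepoints <- round(10^seq(log10(30), log10(14400),
                               length.out = nTimepoints))
  stopifnot(all(timepoints > 0), !anyDuplicated(timepoints))
  if (is.null(stateNames)) stateNames <- paste0("State", seq_len(nStates))
  stopifnot(length(stateNames) == nStates)
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects),
              all(c("peptide", "state", "deltaDa") %in% names(effects)))
    if (!"timepoint" %in% names(effects)) effects$timepoint <- NA_real_
  }
  structure(list(nStates = nStates, nTimepoints = length(timepoints),
                 nReplicates = nReplicates, nPeptides = nPeptides,
                 proteinLength = proteinLength,
                 timepoints = sort(timepoints), effects = effects,
                 noiseSd = noiseSd, backExchangePct = backExchangePct,
                 includeFd = includeFd, stateNames = stateNames,
                 seed = as.integer(seed)),
            class = "HDXSimConfig")
}

# amino-acid alphabet with rough natural frequencies (prolines ~5%)
aaAlphabet <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9,
                E = 6.8, G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8,
                M = 2.4, F = 3.9, P = 4.7, S = 6.6, T = 5.3, W = 1.1,
                Y = 2.9, V = 6.9)

#' Generate a synthetic HDExaminer-style export with known ground truth
#'
#' Simulates a complete multi-state HDX-MS experiment and (optionally)
#' writes it in the default export dialect, so that every downstream module
#' can be validated against known truth. The peptide map is a set of random
#' 8-20-residue spans tiling the protein; per-peptide exchange follows a
#' saturating single-exponential uptake curve
#' `D(t) = maxUptake * (1 - exp(-k t))` with rate `k` log-uniform in
#' `[1e-4, 1e-1] /s`, attenuated by the configured back exchange. Injected
#' effects shift the test-state mean uptake by `deltaDa` at the affected
#' timepoints; replicate values add i.i.d. Gaussian noise (clamped at 0 Da,
#' the physical floor). Percent deuteration is uptake over the peptide's
#' exchangeable-amide count. With `includeFd`, a "Full Deuteration" control
#' state is emitted at a long exposure.
#'
#' The same seed yields a byte-identical file.
#'
#' @param config an [hdxSimConfig()].
#' @param path output file path, or `NULL` to skip writing.
#' @return A list with `records` (a records data.frame directly usable by
#'   [matchPeptides()]), `peptides` (map with per-peptide `maxUptake` and
#'   rate `k`), `trueMeans` (data.frame of noise-free mean uptake per
#'   state x peptide x timepoint, effects included), `effects` (normalised
#'   effect table with state labels), `config`, and `path`.
#' @examples
#' sim <- simulateHDXExport(hdxSimConfig(nStates = 2, nPeptides = 8, seed = 2))
#' head(sim$records)
#' @export
simulateHDXExport <- function(config, path = NULL) {
  stopifnot(inherits(config, "HDXSimConfig"))
  set.seed(config$seed)
  L <- config$proteinLength
  protein <- paste(sample(names(aaAlphabet), L, replace = TRUE,
                          prob = aaAlphabet), collapse = "")

  # peptide map: random 8-20-residue spans tiling the protein
  starts <- sort(sample.int(L - 20L, config$nPeptides, replace = TRUE))
  lens <- sample(8:20, config$nPeptides, replace = TRUE)
  ends <- pmin(starts + lens - 1L, L)
  pep <- unique(data.frame(start = starts, end = ends))
  while (nrow(pep) < config$nPeptides) {
    s <- sample.int(L - 20L, 1L)
    e <- min(s + sample(8:20, 1L) - 1L, L)
    pep <- unique(rbind(pep, data.frame(start = s, end = e)))
  }
  pep <- pep[order(pep$start, pep$end), , drop = FALSE][
    seq_len(config$nPeptides), , drop = FALSE]
  rownames(pep) <- NULL
  pep$sequence <- substring(protein, pep$start, pep$end)
  pep$maxUptake <- maxExchangeableAmides(pep$sequence)
  # guard against degenerate spans with no exchangeable amides
  pep$maxUptake <- pmax(pep$maxUptake, 1L)
  pep$k <- 10^stats::runif(config$nPeptides, -4, -1)

  # normalise effect table to state labels and timepoint vectors
  eff <- config$effects
  if (!is.null(eff) && nrow(eff) > 0) {
    if (is.numeric(eff$state)) {
      if (any(eff$state < 2 | eff$state > config$nStates))
        stop("effects reference state index outside 2..nStates")
      eff$state <- config$stateNames[eff$state]
    }
    if (!all(eff$state %in% config$stateNames[-1]))
      stop("effects must target a non-reference state present in the config")
    if (any(eff$peptide < 1 | eff$peptide > config$nPeptides))
      stop("effects reference a peptide index outside the map")
    if (any(!is.na(eff$timepoint) &
            !eff$timepoint %in% config$timepoints))
      stop("effects reference an exposure time not in the config")
  }

  beFactor <- 1 - config$backExchangePct / 100
  tps <- config$timepoints
  grid <- expand.grid(peptide = seq_len(config$nPeptides),
                      state = config$stateNames,
                      timepoint = tps, stringsAsFactors = FALSE)
  base <- pep$maxUptake[grid$peptide] *
    (1 - exp(-pep$k[grid$peptide] * grid$timepoint)) * beFactor
  shift <- numeric(nrow(grid))
  if (!is.null(eff) && nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      hit <- grid$peptide == eff$peptide[i] & grid$state == eff$state[i] &
        (is.na(eff$timepoint[i]) | grid$timepoint == eff$timepoint[i])
      shift[hit] <- shift[hit] + eff$deltaDa[i]
    }
  }
  trueMeans <- data.frame(grid, meanUptake = pmax(base + shift, 0),
                          stringsAsFactors = FALSE)

  nRep <- config$nReplicates
  repGrid <- trueMeans[rep(seq_len(nrow(trueMeans)), each = nRep), ]
  repGrid$replicate <- rep(seq_len(nRep), nrow(trueMeans))
  noise <- if (config$noiseSd > 0)
    stats::rnorm(nrow(repGrid), 0, config$noiseSd) else 0
  uptake <- pmax(repGrid$meanUptake + noise, 0)
  maxU <- pep$maxUptake[repGrid$peptide]
  records <- data.frame(
    state = repGrid$state,
    sequence = pep$sequence[repGrid$peptide],
    start = pep$start[repGrid$peptide],
    end = pep$end[repGrid$peptide],
    charge = 2L,
    exposure = repGrid$timepoint,
    replicate = repGrid$replicate,
    uptake = uptake,
    percentD = 100 * uptake / maxU,
    isFD = FALSE, stringsAsFactors = FALSE)

  if (config$includeFd) {
    fdU <- pmax(pep$maxUptake * beFactor +
                  if (config$noiseSd > 0)
                    stats::rnorm(config$nPeptides, 0, config$noiseSd) else 0,
                0)
    fd <- data.frame(state = "Full Deuteration", sequence = pep$sequence,
                     start = pep$start, end = pep$end, charge = 2L,
                     exposure = 86400, replicate = 1L, uptake = fdU,
                     percentD = 100 * fdU / pep$maxUptake, isFD = TRUE,
                     stringsAsFactors = FALSE)
    records <- rbind(records, fd)
  }
  rownames(records) <- NULL

  if (!is.null(path)) {
    out <- data.frame(
      `Protein State` = records$state, Sequence = records$sequence,
      Start = records$start, End = records$end, Charge = records$charge,
      `Deut Time` = sprintf("%gs", records$exposure),
      Replicate = records$replicate,
      `#D` = sprintf("%.4f", records$uptake),
      `%D` = sprintf("%.2f", records$percentD),
      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE, eol = "\n")
  }

  list(records = records,
       peptides = pep,
       trueMeans = trueMeans,
       effects = eff,
       protein = protein,
       config = config,
       path = path)
}
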