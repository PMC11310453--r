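# All plot builders return their drawn geometry invisibly; tests assert on
# that data. Drawing goes to a throwaway PDF device.
withDevice <- function(expr) {
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  on.exit({
    grDevices::dev.off()
    unlink(f)
  })
  expr
}

effectSet <- function(seed = 91) {
  cfg <- hdxSimConfig(nStates = 2, nTimepoints = 4, nReplicates = 3,
                      nPeptides = 30, noiseSd = 0.05, includeFd = FALSE,
                      seed = seed,
                      effects = data.frame(peptide = c(5, 12),
                                           state = 2,
                                           deltaDa = c(1.0, -1.0)))
  sim <- simulateHDXExport(cfg)
  list(sim = sim, cs = compareStates(matchPeptides(sim$records)),
       mt = matchPeptides(sim$records))
}

test_that("residue matrix averages delta-D of covering peptides, NA = uncovered", {
  es <- effectSet()
  m <- residueMatrix(es$cs, comparison = "State2", mode = "all",
                     proteinLength = es$sim$config$proteinLength)
  expect_equal(dim(m), c(250L, 4L))
  # brute-force recomputation per residue/timepoint
  r <- comparisonResults(es$cs)
  set.seed(5)
  for (tp in unique(r$timepoint)) {
    sub <- r[r$timepoint == tp, ]
    for (res in sample(250, 25)) {
      cover <- sub$start <= res & sub$end >= res
      want <- if (any(cover)) mean(sub$deltaDa[cover]) else NA_real_
      expect_equal(unname(m[res, as.character(tp)]), want)
    }
  }
  # significant-only mode: uncovered everywhere there is no significant peptide
  ms <- residueMatrix(es$cs, comparison = "State2", mode = "significant",
                      proteinLength = 250)
  sig <- significantPeptides(es$cs)[[1]]
  coveredRows <- which(!is.na(ms[, 1]))
  inSig <- unlist(mapply(seq, sig$start, sig$end, SIMPLIFY = FALSE))
  expect_true(all(coveredRows %in% inSig))
  # two significant peptides with known shifts average where they overlap
  nullCs <- compareStates(matchPeptides(simulateHDXExport(
    hdxSimConfig(nStates = 2, nPeptides = 10, nReplicates = 3,
                 includeFd = FALSE, seed = 92))$records))
  m0 <- residueMatrix(nullCs, comparison = "State2", mode = "significant")
  expect_true(all(is.na(m0)))
})

test_that("residue aggregation of overlapping peptides is the unweighted mean", {
  # direct arithmetic check: +0.4 and +0.6 overlapping -> +0.5
  res <- data.frame(
    comparison = "B", sequence = c("AAAAAAAAAA", "CCCCCCCCCC"),
    start = c(1, 6), end = c(10, 15), timepoint = 60,
    meanRef = 1, meanTest = 1.5, deltaDa = c(0.4, 0.6),
    sdRef = 0.1, sdTest = 0.1, nRef = 3, nTest = 3,
    tStat = 5, df = 4, pValue = 0.001, ciDa = 0.2,
    tested = TRUE, significant = TRUE,
    meanPctRef = 10, meanPctTest = 15, sdPctRef = 1, sdPctTest = 1)
  cs <- methods::new("HDXComparisonSet", results = res,
                     intervals = data.frame(comparison = "B", alpha = 0.01,
                                            sdPooledRef = 0.1,
                                            sdPooledTest = 0.1, nRef = 3,
                                            nTest = 3, dfPool = 4,
                                            ciDa = 0.2),
                     alpha = 0.01, states = c("A", "B"))
  m <- residueMatrix(cs, comparison = "B", proteinLength = 20)
  expect_equal(unname(m[3, 1]), 0.4)
  expect_equal(unname(m[8, 1]), 0.5)
  expect_equal(unname(m[12, 1]), 0.6)
  expect_true(is.na(m[16, 1]))
})

test_that("volcano plot colors by the hybrid test and places guides at CI and alpha", {
  es <- effectSet()
  pts <- withDevice(plotVolcano(es$cs, "State2"))
  ci <- criticalIntervals(es$cs)$ciDa
  expect_equal(attr(pts, "ciDa"), ci)
  expect_equal(attr(pts, "alphaLine"), -log10(0.01))
  scheme <- hdxColorScheme()
  expect_true(all(pts$color[pts$significant & pts$deltaDa > 0] ==
                    scheme$deprotect))
  expect_true(all(pts$color[pts$significant & pts$deltaDa < 0] ==
                    scheme$protect))
  expect_true(all(pts$color[!pts$significant] == scheme$ns))
  # significant points sit outside both guides by construction
  sig <- pts[pts$significant, ]
  expect_true(all(abs(sig$deltaDa) > ci))
  expect_true(all(sig$negLog10P > -log10(0.01)))
  # injected +1 Da peptide appears in the upper-right region
  expect_true(any(sig$deltaDa > ci & sig$negLog10P > 2))
})

test_that("woods plot draws matched peptides as segments with ci band", {
  es <- effectSet()
  tp <- exposureTimes(es$mt)[2]
  segAll <- withDevice(plotWoods(es$cs, "State2", tp, mode = "all"))
  expect_equal(nrow(segAll), nrow(peptideKeys(es$mt)))
  segSig <- withDevice(plotWoods(es$cs, "State2", tp, mode = "significant"))
  expect_true(all(pepKey(segSig) %in% pepKey(segAll)))
  expect_true(all(segSig$significant))
  # heights and extents equal the comparison results
  r <- comparisonResults(es$cs)
  r <- r[r$timepoint == tp, ]
  o <- order(r$start, r$end)
  oa <- order(segAll$start, segAll$end)
  expect_equal(segAll$deltaDa[oa], r$deltaDa[o])
  # zero significant peptides -> empty axes, band still drawn
  nullCs <- compareStates(matchPeptides(simulateHDXExport(
    hdxSimConfig(nStates = 2, nPeptides = 10, nReplicates = 3,
                 includeFd = FALSE, seed = 94))$records))
  seg0 <- withDevice(plotWoods(nullCs, "State2", mode = "significant"))
  expect_equal(nrow(seg0), 0)
  expect_gt(attr(seg0, "ciDa"), 0)
})

test_that("robot plot mirrors the two states and colors dots per timepoint", {
  cfg <- hdxSimConfig(nStates = 2, nTimepoints = 4, nReplicates = 3,
                      nPeptides = 20, noiseSd = 0.05, includeFd = FALSE,
                      seed = 95,
                      effects = data.frame(
                        peptide = 8, state = 2, deltaDa = 1.2,
                        timepoint = NA))
  # restrict the effect to timepoints 1 and 3 of the grid
  cfg$effects <- data.frame(peptide = 8, state = 2, deltaDa = 1.2,
                            timepoint = cfg$timepoints[c(1, 3)])
  sim <- simulateHDXExport(cfg)
  cs <- compareStates(matchPeptides(sim$records))
  el <- withDevice(plotRobot(cs))
  # only the injected peptide is drawn (significant at >= 1 timepoint)
  expect_true(all(el$start == sim$peptides$start[8]))
  expect_true(all(el$y[el$side == "reference"] >= 0))
  expect_true(all(el$y[el$side == "test"] <= 0))
  # dots colored at significant timepoints, grey otherwise
  scheme <- hdxColorScheme()
  sigTp <- sort(unique(el$timepoint[el$significant]))
  expect_equal(sigTp, sort(cfg$timepoints[c(1, 3)]))
  expect_true(all(el$dotColor[!el$significant] == scheme$ns))
  expect_true(all(el$dotColor[el$significant] != scheme$ns))
  # null data -> empty plot body, no error
  nullCs <- compareStates(matchPeptides(simulateHDXExport(
    hdxSimConfig(nStates = 2, nPeptides = 10, nReplicates = 3,
                 includeFd = FALSE, seed = 96))$records))
  el0 <- withDevice(plotRobot(nullCs))
  expect_equal(nrow(el0), 0)
  # more than two states requires per-comparison invocation
  cs3 <- compareStates(matchPeptides(simulateHDXExport(
    hdxSimConfig(nStates = 3, nPeptides = 10, nReplicates = 3,
                 includeFd = FALSE, seed = 97))$records))
  expect_error(withDevice(plotRobot(cs3)), "per comparison")
})

test_that("interval packing is first-fit and never overlaps within a row", {
  # non-overlapping peptides stay on one row
  expect_equal(packIntervals(c(1, 20, 40), c(10, 30, 50)), c(1, 1, 1))
  # three mutually overlapping peptides need three rows
  expect_equal(sort(packIntervals(c(1, 5, 8), c(20, 25, 30))), 1:3)
  # property: no two intervals in the same row overlap (100 random maps)
  set.seed(61)
  for (i in 1:100) {
    n <- sample(2:40, 1)
    start <- sample.int(300, n, replace = TRUE)
    end <- start + sample(5:30, n, replace = TRUE)
    rows <- packIntervals(start, end)
    for (rw in unique(rows)) {
      idx <- which(rows == rw)
      if (length(idx) < 2) next
      o <- idx[order(start[idx])]
      expect_true(all(start[o][-1] > end[o][-length(o)]))
    }
  }
})

test_that("significant-peptide map packs all matched peptides with hybrid colors", {
  es <- effectSet()
  seg <- withDevice(plotSignificantPeptideMap(es$cs, "State2"))
  expect_equal(nrow(seg), nrow(peptideKeys(es$mt)))
  scheme <- hdxColorScheme()
  expect_true(all(seg$color[!seg$significant] == scheme$ns))
  expect_true(all(seg$color[seg$significant] %in%
                    c(scheme$protect, scheme$deprotect)))
})

test_that("uptake plot reports the cell means and SDs of the matched table", {
  es <- effectSet()
  pk <- peptideKeys(es$mt)[3, ]
  rows <- withDevice(plotUptake(es$mt, pk$sequence, pk$start, pk$end))
  u <- uptakeArray(es$mt)
  for (i in seq_len(nrow(rows))) {
    vals <- u[3, rows$state[i], as.character(rows$timepoint[i]), ]
    expect_equal(rows$mean[i], mean(vals, na.rm = TRUE))
    expect_equal(rows$sd[i], sd(vals, na.rm = TRUE))
  }
  # states share the x positions of the matched timepoints
  expect_equal(sort(unique(rows$timepoint)), exposureTimes(es$mt))
  expect_error(withDevice(plotUptake(es$mt, "NOPE", 1, 4)), "not in table")
})

test_that("plot builders are pure: identical inputs give identical geometry", {
  es <- effectSet()
  a <- withDevice(plotVolcano(es$cs, "State2"))
  b <- withDevice(plotVolcano(es$cs, "State2"))
  expect_identical(a, b)
  ra <- withDevice(plotRobot(es$cs))
  rb <- withDevice(plotRobot(es$cs))
  expect_identical(ra, rb)
})
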