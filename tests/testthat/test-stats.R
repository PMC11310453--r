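# Independent textbook implementation of the Welch formulas, kept naive on
# purpose: this is the oracle the vectorised implementation is checked
# against.
oracleWelch <- function(m1, s1, n1, m2, s2, n2) {
  se1 <- s1 * s1 / n1
  se2 <- s2 * s2 / n2
  t <- (m2 - m1) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  # two-sided tail via the incomplete-beta identity
  # P(|T| > t) = I_x(df/2, 1/2), x = df / (df + t^2)
  p <- pbeta(df / (df + t^2), df / 2, 0.5)
  c(t = t, df = df, p = p)
}

test_that("welchT reproduces hand-computed closed-form values", {
  r <- welchT(5.0, 0.1, 3, 5.5, 0.1, 3)
  expect_equal(r$tStat, 6.123724356958, tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$pValue, 0.0036022326091, tolerance = 1e-9)
  # equal means give t = 0, p = 1 whatever the SDs
  r0 <- welchT(2.2, 0.3, 4, 2.2, 0.9, 6)
  expect_equal(r0$tStat, 0)
  expect_equal(r0$pValue, 1)
  # equal n and equal SDs reduce Welch df to the pooled n1 + n2 - 2
  re <- welchT(1, 0.2, 5, 1.4, 0.2, 5)
  expect_equal(re$df, 8)
})

test_that("welchT matches an independent brute-force oracle on 1000 draws", {
  set.seed(101)
  n <- 1000
  m1 <- runif(n, -5, 5); m2 <- runif(n, -5, 5)
  s1 <- runif(n, 0.01, 2); s2 <- runif(n, 0.01, 2)
  n1 <- sample(2:8, n, replace = TRUE); n2 <- sample(2:8, n, replace = TRUE)
  got <- welchT(m1, s1, n1, m2, s2, n2)
  want <- t(mapply(oracleWelch, m1, s1, n1, m2, s2, n2))
  expect_lt(max(abs(got$tStat - want[, "t"]) / abs(want[, "t"])), 1e-10)
  expect_lt(max(abs(got$df - want[, "df"]) / want[, "df"]), 1e-10)
  expect_lt(max(abs(got$pValue - want[, "p"]) /
                  pmax(want[, "p"], 1e-300)), 1e-8)
  expect_true(all(got$pValue >= 0 & got$pValue <= 1))
})

test_that("zero variance in both groups follows the documented convention", {
  expect_warning(r <- welchT(1, 0, 3, 1, 0, 3), "zero variance")
  expect_equal(r$pValue, 1)
  expect_equal(r$tStat, 0)
  expect_warning(r2 <- welchT(1, 0, 3, 2, 0, 3), "zero variance")
  expect_equal(r2$pValue, 0)
  expect_equal(r2$df, 4)
})

test_that("critical interval matches the closed form on a one-cell table", {
  # replicates engineered so the sample SD is exactly 0.1 in both states
  rec <- makeRecords(state = rep(c("ref", "test"), each = 3),
                     sequence = "ACDEFGHIK", start = 1, end = 9,
                     exposure = 60, replicate = rep(1:3, 2),
                     uptake = c(4.9, 5.0, 5.1, 5.4, 5.5, 5.6))
  mt <- matchPeptides(rec)
  ci <- criticalInterval(mt, "test", alpha = 0.01)
  expect_equal(ci$sdPooledRef, 0.1, tolerance = 1e-12)
  expect_equal(ci$sdPooledTest, 0.1, tolerance = 1e-12)
  expect_equal(ci$dfPool, 4)
  # qt(0.995, 4) * 0.1 * sqrt(2/3), computed independently
  expect_equal(ci$ciDa, 0.375922772072, tolerance = 1e-9)
  expect_error(criticalInterval(mt, "ref"), "non-reference")
})

test_that("critical interval is zero iff replicates are identical, and scales with the data", {
  peps <- data.frame(sequence = c("AAAK", "CCDE"), start = c(1, 10),
                     end = c(4, 13))
  recConst <- crossedRecords(peps, c("A", "B"), c(30, 300), 3,
                             function(s, p, t, r) p)
  mt <- matchPeptides(recConst)
  expect_equal(criticalInterval(mt, "B")$ciDa, 0)

  recNoisy <- crossedRecords(peps, c("A", "B"), c(30, 300), 3,
                             function(s, p, t, r) p + 0.05 * r)
  mt1 <- matchPeptides(recNoisy)
  recDoubled <- recNoisy
  recDoubled$uptake <- recNoisy$uptake * 2
  mt2 <- matchPeptides(recDoubled)
  expect_equal(criticalInterval(mt2, "B")$ciDa,
               2 * criticalInterval(mt1, "B")$ciDa, tolerance = 1e-12)
})

test_that("an 8-state table yields 7 comparisons and a self-comparison flags nothing", {
  cfg <- hdxSimConfig(nStates = 8, nTimepoints = 2, nReplicates = 3,
                      nPeptides = 12, includeFd = FALSE, seed = 17)
  sim <- simulateHDXExport(cfg)
  cs <- compareStates(matchPeptides(sim$records))
  expect_equal(length(unique(comparisonResults(cs)$comparison)), 7)
  expect_equal(nrow(criticalIntervals(cs)), 7)

  # duplicated data under two labels: all deltas 0, nothing significant
  sim2 <- simulateHDXExport(hdxSimConfig(nStates = 1, nTimepoints = 3,
                                         nReplicates = 3, nPeptides = 10,
                                         includeFd = FALSE, seed = 18))
  dup <- sim2$records
  dup$state <- "copy"
  cs2 <- compareStates(matchPeptides(rbind(sim2$records, dup)))
  r2 <- comparisonResults(cs2)
  expect_true(all(r2$deltaDa == 0))
  expect_false(any(r2$significant))
})

test_that("a large injected effect is flagged at exactly the right peptide", {
  cfg <- hdxSimConfig(nStates = 2, nTimepoints = 4, nReplicates = 3,
                      nPeptides = 30, noiseSd = 0.05, includeFd = FALSE,
                      seed = 23,
                      effects = data.frame(peptide = 7, state = 2,
                                           deltaDa = 1.0))
  sim <- simulateHDXExport(cfg)
  cs <- compareStates(matchPeptides(sim$records))
  r <- comparisonResults(cs)
  target <- sim$peptides[7, ]
  hit <- r$start == target$start & r$end == target$end
  expect_true(all(r$significant[hit]))          # all timepoints flagged
  sig <- significantPeptides(cs)[[1]]
  expect_equal(nrow(sig), 1)
  expect_equal(sig$start, target$start)
})

test_that("significant-at-any-timepoint equals the brute-force union of flags", {
  cfg <- hdxSimConfig(nStates = 3, nTimepoints = 4, nReplicates = 3,
                      nPeptides = 40, noiseSd = 0.08, includeFd = FALSE,
                      seed = 31,
                      effects = data.frame(peptide = c(3, 9, 9),
                                           state = c(2, 2, 3),
                                           deltaDa = c(0.6, -0.8, 0.5),
                                           timepoint = c(NA, 235, NA)))
  sim <- simulateHDXExport(cfg)
  cs <- compareStates(matchPeptides(sim$records))
  r <- comparisonResults(cs)
  for (cmp in unique(r$comparison)) {
    sub <- r[r$comparison == cmp, ]
    want <- sort(unique(pepKey(sub[sub$significant %in% TRUE, ])))
    got <- sort(pepKey(significantPeptides(cs, cmp)[[1]]))
    expect_equal(got, want)
  }
  expect_equal(nrow(significantPeptides(cs, "State3")[[1]]) >= 1, TRUE)
  # no significant results -> empty set
  null <- simulateHDXExport(hdxSimConfig(nStates = 2, nPeptides = 10,
                                         nReplicates = 3, includeFd = FALSE,
                                         seed = 32))
  csNull <- compareStates(matchPeptides(null$records))
  expect_equal(nrow(significantPeptides(csNull)[[1]]), 0)
})

test_that("swapping reference and test negates delta and t, preserves p and flags", {
  cfg <- hdxSimConfig(nStates = 2, nTimepoints = 3, nReplicates = 3,
                      nPeptides = 15, includeFd = FALSE, seed = 41,
                      effects = data.frame(peptide = 2, state = 2,
                                           deltaDa = 0.7))
  sim <- simulateHDXExport(cfg)
  mt <- matchPeptides(sim$records)
  fw <- comparisonResults(compareStates(mt))
  bw <- comparisonResults(compareStates(reorderReference(mt, "State2")))
  o <- order(fw$start, fw$end, fw$timepoint)
  ob <- order(bw$start, bw$end, bw$timepoint)
  expect_equal(bw$deltaDa[ob], -fw$deltaDa[o])
  expect_equal(bw$tStat[ob], -fw$tStat[o])
  expect_equal(bw$pValue[ob], fw$pValue[o])
  expect_equal(bw$significant[ob], fw$significant[o])
})

test_that("power is monotone in effect size at fixed noise", {
  flagged <- vapply(c(0, 0.2, 0.5, 1.0), function(eff) {
    effects <- if (eff > 0)
      data.frame(peptide = 1:200, state = 2, deltaDa = eff) else NULL
    cfg <- hdxSimConfig(nStates = 2, nTimepoints = 2, nReplicates = 3,
                        nPeptides = 200, noiseSd = 0.1, includeFd = FALSE,
                        seed = 55, effects = effects)
    sim <- simulateHDXExport(cfg)
    r <- comparisonResults(compareStates(matchPeptides(sim$records)))
    mean(r$significant)
  }, numeric(1))
  expect_true(all(diff(flagged) >= 0))
  expect_lt(flagged[1], 0.02)
  expect_gt(flagged[4], 0.9)
})

test_that("cells with a single replicate are kept for plotting but never tested", {
  peps <- data.frame(sequence = c("AAAK", "CCDE"), start = c(1, 10),
                     end = c(4, 13))
  rec <- crossedRecords(peps, c("A", "B"), c(30, 300), 3,
                        function(s, p, t, r) p + 0.03 * r)
  # peptide 2 in state B at 300 s: keep only replicate 1
  drop <- rec$state == "B" & rec$start == 10 & rec$exposure == 300 &
    rec$replicate > 1
  cs <- compareStates(matchPeptides(rec[!drop, ]))
  r <- comparisonResults(cs)
  single <- r$start == 10 & r$timepoint == 300
  expect_false(any(r$tested[single]))
  expect_false(any(r$significant[single]))
  expect_false(any(is.na(r$deltaDa[single])))   # mean still reported
  expect_true(all(r$tested[!single]))
})
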