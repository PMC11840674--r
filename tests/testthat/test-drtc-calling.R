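test_that("exact two-sided binomial p-values match hand-derived values", {
  # symmetric null, both tails equal: 2 * (1/2)^5
  expect_equal(binomTwoSidedP(5, 0, 1000, 1000), 0.0625)
  # asymmetric null p0 = 0.25: P(3) + P(4)
  expect_equal(binomTwoSidedP(3, 1, 1000, 3000), 0.05078125)
  # observed count at the mode: every outcome qualifies
  expect_equal(binomTwoSidedP(2, 2, 1000, 1000), 1)
  expect_error(binomTwoSidedP(0, 0, 10, 10), "undefined")
})

test_that("minimum-likelihood p-values agree with binom.test on a grid", {
  totals <- list(c(100, 900), c(250, 750), c(500, 500), c(900, 100))
  for (tt in totals) {
    for (n in c(1, 2, 5, 13, 30)) {
      for (k in 0:n) {
        p0 <- tt[1] / sum(tt)
        expect_equal(binomTwoSidedP(k, n - k, tt[1], tt[2]),
                     binom.test(k, n, p0)$p.value, tolerance = 1e-12)
      }
    }
  }
})

test_that("tail-doubling option gives the doubled smaller tail", {
  expect_equal(binomTwoSidedP(5, 0, 1000, 1000, method = "doubling"),
               0.0625)
  # doubling can exceed minlike but is capped at 1
  expect_equal(binomTwoSidedP(2, 2, 1000, 1000, method = "doubling"), 1)
  p <- binomTwoSidedP(7, 3, 1000, 3000, method = "doubling")
  expect_equal(p, 2 * pbinom(6, 10, 0.25, lower.tail = FALSE))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(0.01), 0.01)
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03)), c(0.015, 0.015, 0.03))
  expect_equal(bhAdjust(rep(0.5, 10)), rep(0.5, 10))
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone in p and never below p
  set.seed(42)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

.balancedPair <- function(extraMlr = c(), extraUnstim = c()) {
  base <- setNames(rep(100L, 60), sprintf("BG%02d", 1:60))
  mlr <- exampleSample(c(base, extraMlr), sampleId = "mlr",
                       compartment = "mlr_sort", subset = "cd4")
  unstim <- exampleSample(c(base * 10L, extraUnstim), sampleId = "unstim")
  list(mlr = mlr, unstim = unstim)
}

test_that("callDRTC applies the count floor, FDR and fold gates", {
  pair <- .balancedPair(extraMlr = c(SPIKE = 50L, LOW = 4L))
  d <- callDRTC(pair$mlr, pair$unstim)
  res <- drtcResults(d)
  expect_s4_class(d, "DRTCSet")
  # a clone newly detected in the MLR at high count is a DRTC
  # (zero-denominator fold convention, no pseudocount)
  expect_equal(res$call[res$rearrangement == "SPIKE"], "drtc")
  expect_true(is.infinite(res$fold[res$rearrangement == "SPIKE"]))
  # combined count 4 < 5: never tested, no p-value
  expect_equal(res$call[res$rearrangement == "LOW"], "below_count_floor")
  expect_true(is.na(res$p_value[res$rearrangement == "LOW"]))
  # perfectly balanced clones are not significant
  expect_true(all(res$call[startsWith(res$rearrangement, "BG")] ==
                    "not_significant"))
  # BH multiplicity counts only tested clones of this comparison
  tested <- !is.na(res$p_value)
  expect_equal(res$q_value[tested], bhAdjust(res$p_value[tested]))
})

test_that("identical samples yield no calls and equal-frequency clones are null", {
  s <- zipfSample(200, 5000, sampleId = "a", compartment = "mlr_sort",
                  subset = "cd8")
  d <- callDRTC(s, s)
  expect_equal(unname(classifyScatter(d)["drtc"]), 0L)
  pair <- .balancedPair()
  res <- drtcResults(callDRTC(pair$mlr, pair$unstim))
  expect_true(all(abs(res$fold - 1) < 1e-12))
})

test_that("swapping the samples mirrors the calls and keeps p-values", {
  set.seed(7)
  a <- zipfSample(300, 8000, sampleId = "a", compartment = "mlr_sort",
                  subset = "cd4")
  b <- zipfSample(300, 3000, sampleId = "b")
  d1 <- drtcResults(callDRTC(a, b))
  d2 <- drtcResults(callDRTC(b, a))
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$q_value, d2$q_value)
  expect_equal(d1$call == "drtc", d2$call == "enriched_unstim")
  expect_equal(d1$call == "enriched_unstim", d2$call == "drtc")
})

test_that("call classes partition the clone universe", {
  pair <- .balancedPair(extraMlr = c(S1 = 80L, S2 = 60L, LOW = 2L),
                        extraUnstim = c(DEP = 5000L))
  d <- callDRTC(pair$mlr, pair$unstim)
  counts <- classifyScatter(d)
  expect_equal(sum(counts), nrow(drtcResults(d)))
  expect_named(counts, c("drtc", "enriched_unstim", "not_significant",
                         "below_count_floor"))
  # empty result table gives all-zero counts
  empty <- drtcResults(d)[0, ]
  expect_equal(sum(classifyScatter(empty)), 0L)
})

test_that("parameter validation rejects bad thresholds", {
  pair <- .balancedPair()
  expect_error(callDRTC(pair$mlr, pair$unstim, alpha = 1.5), "alpha")
  expect_error(callDRTC(pair$mlr, pair$unstim, alpha = 0), "alpha")
  expect_error(callDRTC(pair$mlr, pair$unstim, countFloor = 0), "countFloor")
})

test_that("DRTC result tables round-trip through the tsv writer", {
  pair <- .balancedPair(extraMlr = c(SPIKE = 50L))
  d <- callDRTC(pair$mlr, pair$unstim)
  p <- tempfile(fileext = ".tsv")
  writeDRTCTable(d, p)
  lines <- readLines(p)
  expect_true(startsWith(lines[1], "#"))
  tab <- read.delim(p, comment.char = "#", colClasses = "character")
  expect_equal(nrow(tab), nrow(drtcResults(d)))
  expect_true("inf" %in% tab$fold)
})
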