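# a DRTCSet with a prescribed member list, for tracking tests
fakeDrtcSet <- function(keys, subject = "SUBJ", subset = "cd8") {
  n <- length(keys)
  res <- data.frame(
    rearrangement = keys, count_mlr = rep(50L, n),
    count_unstim = rep(0L, n), total_mlr = rep(1000L, n),
    total_unstim = rep(10000L, n), freq_mlr = rep(0.05, n),
    freq_unstim = rep(0, n), fold = rep(Inf, n),
    p_value = rep(1e-10, n), q_value = rep(1e-9, n),
    call = rep("drtc", n), stringsAsFactors = FALSE)
  new("DRTCSet", subjectId = subject, subset = subset, results = res,
      parameters = list(alpha = 0.01, foldMin = 2, countFloor = 5L,
                        method = "minlike"))
}

subjSample <- function(counts, sampleId, timepoint = "pre_tx",
                       compartment = "pbmc", subject = "SUBJ") {
  exampleSample(counts, sampleId = sampleId, subjectId = subject,
                timepoint = timepoint, compartment = compartment)
}

test_that("tracking tables form a complete chronologically ordered grid", {
  drtc <- fakeDrtcSet(c("a", "b", "c"))
  samples <- list(
    subjSample(c(a = 5, x = 95), "pre", "pre_tx"),
    subjSample(c(b = 2, x = 98), "m3", "m3"),
    subjSample(c(a = 1, b = 1, x = 8), "m12", "m12"),
    subjSample(c(x = 10), "wk2", "wk2", compartment = "urine"))
  tt <- buildTracking(drtc, samples)
  expect_s4_class(tt, "TrackingTable")
  expect_equal(dim(trackingMatrix(tt, "counts")), c(3L, 4L))
  expect_equal(trackingSamples(tt)$sample_id, c("pre", "wk2", "m3", "m12"))
  # absence is an explicit (FALSE, 0, 0) cell
  expect_false(trackingMatrix(tt, "present")["a", "m3"])
  expect_equal(trackingMatrix(tt, "counts")["a", "m3"], 0L)
  expect_equal(trackingMatrix(tt, "freqs")["a", "pre"], 0.05)
  expect_true(all(trackingMatrix(tt, "present") ==
                    (trackingMatrix(tt, "counts") >= 1)))
})

test_that("tracking rejects foreign subjects and tolerates empty DRTC sets", {
  drtc <- fakeDrtcSet(c("a"))
  other <- subjSample(c(a = 1), "x", subject = "OTHER")
  expect_error(buildTracking(drtc, list(other)), "another subject")
  tt <- buildTracking(fakeDrtcSet(character(0)),
                      list(subjSample(c(a = 1), "pre")))
  expect_equal(nrow(trackingMatrix(tt, "counts")), 0L)
})

test_that("graft-infiltrating clones are categorized into the four-way partition", {
  drtc <- fakeDrtcSet(c("a", "b", "c", "d"))
  graft <- subjSample(c(a = 1, b = 1, c = 1, d = 1, g = 6), "graft", "m3",
                      "biopsy")
  pre <- subjSample(c(a = 5, b = 5, x = 90), "pre")
  post <- subjSample(c(b = 3, c = 3, x = 94), "post", "m3")
  cat4 <- categorizeGraftClones(drtc, graft, pre, post)
  got <- setNames(cat4$perClone$category, cat4$perClone$rearrangement)
  expect_equal(got[c("a", "b", "c", "d")],
               c(a = "pre_only", b = "pre_and_post", c = "post_only",
                 d = "graft_only"))
  expect_equal(unname(cat4$shares), rep(0.25, 4))
  expect_equal(cat4$cumulativePreShare, 0.5)
  expect_equal(sum(cat4$shares), 1)

  # all clones in both blood samples
  both <- categorizeGraftClones(
    drtc, graft, subjSample(c(a = 1, b = 1, c = 1, d = 1), "pre2"),
    subjSample(c(a = 1, b = 1, c = 1, d = 1), "post2", "m3"))
  expect_equal(unname(both$shares["pre_and_post"]), 1)
  expect_equal(both$cumulativePreShare, 1)

  # clones below blood detection exist only in the kidney
  none <- categorizeGraftClones(
    drtc, graft, subjSample(c(x = 1), "pre3"),
    subjSample(c(x = 1), "post3", "m3"))
  expect_equal(unname(none$shares["graft_only"]), 1)
})

test_that("categorization degrades explicitly without a post-transplant sample", {
  drtc <- fakeDrtcSet(c("a", "b"))
  graft <- subjSample(c(a = 1, b = 1), "graft", "m3", "biopsy")
  pre <- subjSample(c(a = 5, x = 95), "pre")
  cat3 <- categorizeGraftClones(drtc, graft, pre, NULL)
  expect_true(cat3$partial)
  expect_equal(sort(names(cat3$shares)), c("pre_only", "undetermined"))
  expect_equal(cat3$cumulativePreShare, 0.5)
  expect_equal(sum(cat3$shares), 1)
})

test_that("an empty graft universe is a defined degenerate result", {
  drtc <- fakeDrtcSet(c("a"))
  graft <- subjSample(c(z = 5), "graft", "m3", "biopsy")
  pre <- subjSample(c(a = 5), "pre")
  out <- categorizeGraftClones(drtc, graft, pre,
                               subjSample(c(a = 1), "post", "m3"))
  expect_true(out$degenerate)
  expect_equal(out$n, 0L)
  expect_true(all(is.na(out$shares)))
})

test_that("exclusive shares always partition and pre-detection is cumulative", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    inPre <- runif(n) < 0.5
    inPost <- runif(n) < 0.5
    cats <- categorizePresence(inPre, inPost)
    tab <- table(factor(cats, levels = c("pre_only", "pre_and_post",
                                         "post_only", "graft_only")))
    expect_equal(sum(tab) / n, 1)
    expect_equal(unname((tab["pre_only"] + tab["pre_and_post"]) / n),
                 mean(inPre))
  }
})

test_that("urine overlap reports clones reappearing in later biopsies", {
  drtc <- fakeDrtcSet(sprintf("u%d", 1:6))
  urine <- subjSample(c(u1 = 2, u2 = 1, u3 = 1, u4 = 3, u5 = 1, x = 10),
                      "urine", "wk2", "urine")
  bio1 <- subjSample(c(u1 = 4, u4 = 2, z = 100), "bio1", "m3", "biopsy")
  bio2 <- subjSample(c(u4 = 1, z = 50), "bio2", "rejection", "biopsy")
  out <- urineGraftOverlap(drtc, urine, list(bio1, bio2))
  expect_equal(out$nUrineDetected, 5L)
  expect_equal(out$nAlsoInBiopsy, 2L)
  # consistency: every detail row re-looks-up as present in both samples
  for (i in seq_len(nrow(out$detail))) {
    key <- out$detail$rearrangement[i]
    expect_gte(cloneTable(urine)$templates[
      cloneTable(urine)$rearrangement == key], 1L)
    b <- if (out$detail$biopsy[i] == "bio1") bio1 else bio2
    expect_gte(cloneTable(b)$templates[cloneTable(b)$rearrangement == key],
               1L)
  }
  # degenerate cases
  none <- urineGraftOverlap(fakeDrtcSet("q"), urine, list(bio1))
  expect_equal(c(none$nUrineDetected, none$nAlsoInBiopsy), c(0L, 0L))
  # chronological order enforced
  early <- subjSample(c(u1 = 1), "bad", "pre_tx", "biopsy")
  expect_error(urineGraftOverlap(drtc, urine, list(early)), "follow")
})

test_that("longitudinal summaries order timepoints and mirror metrics", {
  drtc <- fakeDrtcSet(c("a", "b"))
  pre <- subjSample(c(a = 10, b = 10, x = 80), "pre")
  post <- subjSample(c(a = 1, x = 99), "post", "m3")
  out <- longitudinalDrtcSummary(drtc, list(post, pre))
  expect_equal(out$timepoint, c("pre_tx", "m3"))
  expect_equal(out$n_detected, c(2L, 1L))
  expect_equal(out$depth, c(0.2, 0.01))
  # identical samples give identical metrics
  out2 <- longitudinalDrtcSummary(drtc, list(
    pre, subjSample(c(a = 10, b = 10, x = 80), "pre2", "m3")))
  expect_equal(out2$n_detected[1], out2$n_detected[2])
  expect_equal(out2$depth[1], out2$depth[2])
})

test_that("depletion reduces detected DRTC in the simulated post sample", {
  cfg <- smallConfig(nSubjects = 2L, campathFraction = 1,
                     campathDepletion = 0.9)
  sim <- simulateSubject(cfg, 1L)
  drtc <- callDRTC(sim$samples$mlr_cd4, sim$samples$pre_pbmc)
  out <- longitudinalDrtcSummary(drtc, list(sim$samples$pre_pbmc,
                                            sim$samples$post_pbmc))
  expect_lt(out$n_detected[out$timepoint == "m3"],
            out$n_detected[out$timepoint == "pre_tx"])
})
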