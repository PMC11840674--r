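#' Configuration for the synthetic transplant cohort generator
#'
#' The generator emulates the specimen set of a kidney-transplant
#' alloreactivity study: per subject, an unstimulated pre-transplant PBMC
#' repertoire, MLR-sorted CD4+ and CD8+ populations carrying an expanded
#' alloreactive subset, and post-transplant PBMC, allograft biopsy and
#' 2-week urine samples with configurable depletion, infiltration and
#' shedding dynamics. Ground truth (which clones are alloreactive, with
#' their generative frequencies) is recorded before sampling noise and is
#' never consumed by the analysis path.
#'
#' Baseline clone sizes follow a Zipf law (frequency of rank r proportional
#' to r^-s). Alloreactive clones are drawn from ranks in
#' \code{alloreactiveRankRange} — alloreactive precursors circulate at low
#' frequency, so the hyperexpanded top of the repertoire is excluded by
#' default — and are split CD4:CD8 at \code{cd4Share} (default 2:1,
#' mirroring the larger alloreactive CD4+ compartment).
#'
#' Two MLR models are available. \code{"sorted"} (default) emulates the
#' flow-sort itself: the sorted sample is a mixture in which the
#' proliferated alloreactive population — weighted baseline frequency times
#' a lognormal per-clone expansion factor — occupies \code{sortPurity} of
#' the sorted template mass, the remainder being non-proliferating
#' baseline carry-over. \code{"multiplicative"} leaves the baseline in
#' place and merely multiplies alloreactive frequencies by their expansion
#' factors before renormalising; it is the idealised spike-in model used
#' for recovery benchmarking.
#'
#' Post-transplant, lymphodepletional induction removes
#' \code{campathDepletion} of clone identities (\code{nonCampathDepletion}
#' otherwise). Subjects flagged as rejecting have their CD8+ alloreactive
#' baseline boosted \code{rejectionCd8BaselineBoost}-fold (pre-existing
#' high-frequency donor-reactive memory), their biopsy enriched for
#' alloreactive clones at \code{graftInfiltrationFactor} times the
#' pre-transplant frequency, and a random \code{urineSheddingFraction} of
#' the infiltrating clones shed into the 2-week urine where they occupy
#' \code{urineSheddingMass} of the urine template mass.
#'
#' @param nSubjects cohort size (default 12).
#' @param nClones clones per subject baseline repertoire (default 10000).
#' @param zipfExponent Zipf/power-law exponent s (default 1.5).
#' @param alloreactiveFraction fraction of clones that are alloreactive
#'   (default 0.02).
#' @param cd4Share CD4 share of the alloreactive clones (default 2/3).
#' @param alloreactiveRankRange integer range of Zipf ranks alloreactive
#'   clones are drawn from; \code{NA} upper bound means \code{nClones}.
#' @param mlrExpansionMeanlog,mlrExpansionSdlog lognormal expansion-factor
#'   distribution (median 8 by default).
#' @param mlrModel \code{"sorted"} or \code{"multiplicative"}.
#' @param sortPurity sorted-mass share of the proliferated population in
#'   the \code{"sorted"} model (default 0.9).
#' @param depthPbmc,depthMlr,depthBiopsy,depthUrine template sampling
#'   depths (defaults 100000, 20000, 3000, 500).
#' @param campathFraction fraction of subjects receiving lymphodepletional
#'   induction (default 0.5).
#' @param campathDepletion,nonCampathDepletion fraction of clone identities
#'   removed post-transplant (defaults 0.9, 0.1).
#' @param rejectionFraction fraction of non-lymphodepleted subjects flagged
#'   as rejecting (default 0.5).
#' @param graftInfiltrationFactor biopsy over-representation of
#'   alloreactive clones in rejecting subjects (default 20).
#' @param urineSheddingFraction fraction of infiltrating alloreactive
#'   clones shed into the 2-week urine (default 0.3).
#' @param urineSheddingMass urine template-mass share of the shed clones
#'   (default 0.5).
#' @param rejectionCd8BaselineBoost pre-transplant CD8 alloreactive
#'   baseline boost in rejecting subjects (default 5).
#' @param nonproductiveCloneFraction,nonproductiveMass extra out-of-frame
#'   clones carried by every sample and their template-mass share relative
#'   to the productive depth (defaults 0.05, 0.05).
#' @param seed global seed; per-subject child seeds are derived
#'   deterministically, so any subject is reproducible in isolation.
#' @return a validated \code{simulationConfig} list.
#' @export
simulationConfig <- function(nSubjects = 12L, nClones = 10000L,
                             zipfExponent = 1.5,
                             alloreactiveFraction = 0.02, cd4Share = 2 / 3,
                             alloreactiveRankRange = c(501L, NA),
                             mlrExpansionMeanlog = log(8),
                             mlrExpansionSdlog = 0.75,
                             mlrModel = c("sorted", "multiplicative"),
                             sortPurity = 0.9,
                             depthPbmc = 100000L, depthMlr = 20000L,
                             depthBiopsy = 3000L, depthUrine = 500L,
                             campathFraction = 0.5,
                             campathDepletion = 0.9,
                             nonCampathDepletion = 0.1,
                             rejectionFraction = 0.5,
                             graftInfiltrationFactor = 20,
                             urineSheddingFraction = 0.3,
                             urineSheddingMass = 0.5,
                             rejectionCd8BaselineBoost = 5,
                             nonproductiveCloneFraction = 0.05,
                             nonproductiveMass = 0.05,
                             seed = 1L) {
  mlrModel <- match.arg(mlrModel)
  if (is.na(alloreactiveRankRange[2L]))
    alloreactiveRankRange[2L] <- nClones
  cfg <- list(nSubjects = as.integer(nSubjects),
              nClones = as.integer(nClones),
              zipfExponent = zipfExponent,
              alloreactiveFraction = alloreactiveFraction,
              cd4Share = cd4Share,
              alloreactiveRankRange = as.integer(alloreactiveRankRange),
              mlrExpansionMeanlog = mlrExpansionMeanlog,
              mlrExpansionSdlog = mlrExpansionSdlog,
              mlrModel = mlrModel, sortPurity = sortPurity,
              depthPbmc = as.integer(depthPbmc),
              depthMlr = as.integer(depthMlr),
              depthBiopsy = as.integer(depthBiopsy),
              depthUrine = as.integer(depthUrine),
              campathFraction = campathFraction,
              campathDepletion = campathDepletion,
              nonCampathDepletion = nonCampathDepletion,
              rejectionFraction = rejectionFraction,
              graftInfiltrationFactor = graftInfiltrationFactor,
              urineSheddingFraction = urineSheddingFraction,
              urineSheddingMass = urineSheddingMass,
              rejectionCd8BaselineBoost = rejectionCd8BaselineBoost,
              nonproductiveCloneFraction = nonproductiveCloneFraction,
              nonproductiveMass = nonproductiveMass,
              seed = as.integer(seed))
  fracs <- c(alloreactiveFraction = cfg$alloreactiveFraction,
             cd4Share = cfg$cd4Share, sortPurity = cfg$sortPurity,
             campathFraction = cfg$campathFraction,
             campathDepletion = cfg$campathDepletion,
             nonCampathDepletion = cfg$nonCampathDepletion,
             rejectionFraction = cfg$rejectionFraction,
             urineSheddingFraction = cfg$urineSheddingFraction,
             urineSheddingMass = cfg$urineSheddingMass,
             nonproductiveCloneFraction = cfg$nonproductiveCloneFraction,
             nonproductiveMass = cfg$nonproductiveMass)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad))
    stop("fraction parameter(s) outside [0, 1]: ",
         paste(bad, collapse = ", "))
  depths <- c(cfg$depthPbmc, cfg$depthMlr, cfg$depthBiopsy, cfg$depthUrine)
  if (any(depths <= 0L)) stop("sampling depths must be positive")
  if (max(depths) > 50L * cfg$nClones)
    stop("sampling depth implausibly large for a universe of ",
         cfg$nClones, " clones")
  if (cfg$nSubjects < 0L) stop("nSubjects must be >= 0")
  if (cfg$alloreactiveRankRange[1L] < 1L ||
      cfg$alloreactiveRankRange[2L] > cfg$nClones ||
      cfg$alloreactiveRankRange[1L] > cfg$alloreactiveRankRange[2L])
    stop("alloreactiveRankRange must be within 1..nClones")
  structure(cfg, class = "simulationConfig")
}

#' Deterministic group assignment for a simulated cohort
#'
#' The first \code{round(campathFraction * nSubjects)} subjects receive
#' lymphodepletional induction; among the remaining (non-lymphodepleted)
#' subjects the first \code{round(rejectionFraction * k)} are flagged as
#' rejecting. Assignment is a pure function of the configuration so group
#' labels never depend on the random stream.
#'
#' @param config a [simulationConfig()].
#' @return data.frame: \code{subject_id, induction_group, rejection,
#'   biopsy_status}.
#' @export
cohortAssignments <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  n <- config$nSubjects
  ids <- sprintf("S%02d", seq_len(n))
  nCampath <- round(config$campathFraction * n)
  induction <- rep("non_campath", n)
  if (nCampath > 0) induction[seq_len(nCampath)] <- "campath"
  rejection <- rep(FALSE, n)
  nonCampath <- which(induction == "non_campath")
  nRej <- round(config$rejectionFraction * length(nonCampath))
  if (nRej > 0) rejection[nonCampath[seq_len(nRej)]] <- TRUE
  data.frame(subject_id = ids, induction_group = induction,
             rejection = rejection,
             biopsy_status = ifelse(rejection, "acute_rejection", "stable"),
             stringsAsFactors = FALSE)
}

## stop-free codons (61) for generating in-frame rearrangements
.CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

## random in-frame 87-nt rearrangements (29 codons); identity, not
## biological V/J realism, is what downstream computations consume
.randomRearrangements <- function(n, nCodons = 29L) {
  repeat {
    m <- matrix(sample(.CODONS, n * nCodons, replace = TRUE),
                nrow = n, ncol = nCodons)
    seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

## CDR3 amino acids: translate the embedded 15-codon junction region
.cdr3FromNt <- function(nt) {
  region <- substr(nt, 31L, 75L)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(region)))
}

.V_GENES <- sprintf("TCRBV%02d-01", 1:30)
.J_GENES <- as.vector(outer(sprintf("TCRBJ%02d", 1:2),
                            sprintf("-%02d", 1:6), paste0))

## child seed derivation: deterministic, subject-index specific, < 2^31
.childSeed <- function(seed, subjectIndex) {
  as.integer((as.double(seed) * 1009 + as.double(subjectIndex) * 9973 +
                104729) %% 2147483647)
}

## multinomial template draw over a clone universe -> RepertoireSample,
## with a small out-of-frame clone set appended for parser realism
.drawSample <- function(probs, depth, pool, np, npDepth,
                        sampleId, subjectId, timepoint, compartment,
                        subset, tcellFrac) {
  counts <- as.integer(stats::rmultinom(1L, depth, probs))
  keep <- counts > 0L
  clones <- data.frame(
    rearrangement = pool$rearrangement[keep],
    cdr3_aa = pool$cdr3_aa[keep],
    v_gene = pool$v_gene[keep], j_gene = pool$j_gene[keep],
    productive = TRUE, templates = counts[keep],
    stringsAsFactors = FALSE)
  if (!is.null(np) && npDepth > 0L && nrow(np)) {
    npCounts <- as.integer(stats::rmultinom(1L, npDepth, np$weight))
    nkeep <- npCounts > 0L
    if (any(nkeep))
      clones <- rbind(clones, data.frame(
        rearrangement = np$rearrangement[nkeep],
        cdr3_aa = np$cdr3_aa[nkeep],
        v_gene = np$v_gene[nkeep], j_gene = np$j_gene[nkeep],
        productive = FALSE, templates = npCounts[nkeep],
        stringsAsFactors = FALSE))
  }
  ge <- as.integer(round(sum(clones$templates) / tcellFrac))
  RepertoireSample(sampleId = sampleId, subjectId = subjectId,
                   timepoint = timepoint, compartment = compartment,
                   subset = subset, clones = clones,
                   genomeEquivalents = ge)
}

#' Simulate one subject's specimen set
#'
#' Generates the full per-subject sample collection with recorded ground
#' truth: \code{pre_pbmc} (unstimulated pre-transplant), \code{mlr_cd4} and
#' \code{mlr_cd8} (sorted MLR populations), \code{post_pbmc} (3-month
#' blood), \code{biopsy} (3-month allograft) and \code{urine_wk2}. The
#' subject's child seed is derived deterministically from the global seed
#' and the subject index, so the same call always returns a bit-identical
#' subject.
#'
#' @param config a [simulationConfig()].
#' @param subjectIndex 1-based subject index within the cohort.
#' @return list with \code{samples} (named list of
#'   \linkS4class{RepertoireSample}), \code{truth} (alloreactive clone keys
#'   per subset, expansion factors, generative frequencies per sample,
#'   post-transplant removals, shed clones) and \code{assignment} (the
#'   subject's cohort row).
#' @export
simulateSubject <- function(config, subjectIndex) {
  stopifnot(inherits(config, "simulationConfig"),
            subjectIndex >= 1L, subjectIndex <= max(config$nSubjects, 1L))
  assign <- cohortAssignments(config)
  if (nrow(assign) == 0L)
    stop("config has no subjects")
  arow <- assign[subjectIndex, ]
  subj <- arow$subject_id
  campath <- arow$induction_group == "campath"
  rejection <- arow$rejection
  set.seed(.childSeed(config$seed, subjectIndex))

  nC <- config$nClones
  pool <- data.frame(
    rearrangement = .randomRearrangements(nC),
    stringsAsFactors = FALSE)
  pool$cdr3_aa <- .cdr3FromNt(pool$rearrangement)
  pool$v_gene <- sample(.V_GENES, nC, replace = TRUE)
  pool$j_gene <- sample(.J_GENES, nC, replace = TRUE)

  ## Zipf baseline: clone i has rank i
  baseline <- seq_len(nC)^(-config$zipfExponent)
  baseline <- baseline / sum(baseline)

  nAllo <- round(config$alloreactiveFraction * nC)
  rng <- config$alloreactiveRankRange
  alloIdx <- if (nAllo > 0)
    sample(seq(rng[1L], rng[2L]), nAllo) else integer(0)
  nCd4 <- round(config$cd4Share * nAllo)
  cd4Idx <- alloIdx[seq_len(nCd4)]
  cd8Idx <- setdiff(alloIdx, cd4Idx)

  if (rejection && length(cd8Idx)) {
    baseline[cd8Idx] <- baseline[cd8Idx] * config$rejectionCd8BaselineBoost
    baseline <- baseline / sum(baseline)
  }

  expansion <- stats::setNames(
    stats::rlnorm(nAllo, config$mlrExpansionMeanlog,
                  config$mlrExpansionSdlog),
    pool$rearrangement[alloIdx])

  .mlrProbs <- function(subsetIdx) {
    if (!length(subsetIdx)) return(baseline)
    E <- expansion[pool$rearrangement[subsetIdx]]
    if (config$mlrModel == "multiplicative") {
      w <- baseline
      w[subsetIdx] <- w[subsetIdx] * E
      return(w / sum(w))
    }
    pa <- numeric(nC)
    pa[subsetIdx] <- baseline[subsetIdx] * E
    pa <- pa / sum(pa)
    bg <- baseline
    bg[subsetIdx] <- 0
    bg <- bg / sum(bg)
    config$sortPurity * pa + (1 - config$sortPurity) * bg
  }
  mlrCd4Probs <- .mlrProbs(cd4Idx)
  mlrCd8Probs <- .mlrProbs(cd8Idx)

  depletion <- if (campath) config$campathDepletion else
    config$nonCampathDepletion
  removed <- sample(nC, round(depletion * nC))
  postBaseline <- baseline
  postBaseline[removed] <- 0
  postBaseline <- postBaseline / sum(postBaseline)

  graftProbs <- postBaseline
  shedIdx <- integer(0)
  if (rejection && length(alloIdx)) {
    graftProbs[alloIdx] <- baseline[alloIdx] * config$graftInfiltrationFactor
    graftProbs <- graftProbs / sum(graftProbs)
    shedIdx <- sample(alloIdx,
                      round(config$urineSheddingFraction * length(alloIdx)))
  }
  urineProbs <- if (length(shedIdx)) {
    shed <- numeric(nC)
    shed[shedIdx] <- graftProbs[shedIdx]
    shed <- shed / sum(shed)
    config$urineSheddingMass * shed +
      (1 - config$urineSheddingMass) * postBaseline
  } else postBaseline

  nNP <- round(config$nonproductiveCloneFraction * nC)
  np <- if (nNP > 0) {
    npSeq <- .randomRearrangements(nNP, nCodons = 29L)
    data.frame(rearrangement = npSeq,
               cdr3_aa = paste0(substr(.cdr3FromNt(npSeq), 1L, 14L), "*"),
               v_gene = sample(.V_GENES, nNP, replace = TRUE),
               j_gene = sample(.J_GENES, nNP, replace = TRUE),
               weight = seq_len(nNP)^(-config$zipfExponent),
               stringsAsFactors = FALSE)
  } else NULL
  .np <- function(depth) as.integer(round(config$nonproductiveMass * depth))

  sampleDefs <- list(
    pre_pbmc = list(probs = baseline, depth = config$depthPbmc,
                    timepoint = "pre_tx", compartment = "pbmc",
                    subset = "bulk", frac = 0.25),
    mlr_cd4 = list(probs = mlrCd4Probs, depth = config$depthMlr,
                   timepoint = "pre_tx", compartment = "mlr_sort",
                   subset = "cd4", frac = 0.9),
    mlr_cd8 = list(probs = mlrCd8Probs, depth = config$depthMlr,
                   timepoint = "pre_tx", compartment = "mlr_sort",
                   subset = "cd8", frac = 0.9),
    post_pbmc = list(probs = postBaseline, depth = config$depthPbmc,
                     timepoint = "m3", compartment = "pbmc",
                     subset = "bulk", frac = if (campath) 0.05 else 0.2),
    biopsy = list(probs = graftProbs, depth = config$depthBiopsy,
                  timepoint = "m3", compartment = "biopsy",
                  subset = "bulk", frac = 0.05),
    urine_wk2 = list(probs = urineProbs, depth = config$depthUrine,
                     timepoint = "wk2", compartment = "urine",
                     subset = "bulk", frac = 0.02))
  samples <- lapply(names(sampleDefs), function(nm) {
    d <- sampleDefs[[nm]]
    .drawSample(d$probs, d$depth, pool, np, .np(d$depth),
                sampleId = paste(subj, nm, sep = "_"), subjectId = subj,
                timepoint = d$timepoint, compartment = d$compartment,
                subset = d$subset, tcellFrac = d$frac)
  })
  names(samples) <- names(sampleDefs)

  truth <- list(
    alloCd4 = pool$rearrangement[cd4Idx],
    alloCd8 = pool$rearrangement[cd8Idx],
    expansion = expansion,
    generative = stats::setNames(
      lapply(sampleDefs, function(d)
        stats::setNames(d$probs, pool$rearrangement)),
      names(sampleDefs)),
    removedPost = pool$rearrangement[removed],
    shed = pool$rearrangement[shedIdx])

  list(samples = samples, truth = truth, assignment = arow)
}

#' Simulate a cohort and write it to disk
#'
#' Writes each subject's clonotype tables (immunoSEQ dialect), a validated
#' sample manifest (with the genome-equivalents column) and a ground-truth
#' sidecar table. The output is consumed by [readManifest()] /
#' [runCohort()] exactly like real data; the sidecar is only for
#' benchmarking and is never read by the analysis path. File content is
#' fully determined by the configuration (including its seed).
#'
#' @param config a [simulationConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with \code{manifest} (path),
#'   \code{groundTruth} (path) and \code{assignments}.
#' @export
simulateCohort <- function(config, outDir) {
  stopifnot(inherits(config, "simulationConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  assign <- cohortAssignments(config)
  manifestPath <- file.path(outDir, "manifest.tsv")
  truthPath <- file.path(outDir, "ground_truth.tsv")
  if (config$nSubjects == 0L) {
    warning("nSubjects = 0: writing an empty manifest")
    empty <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.MANIFEST_COLUMNS)),
      .MANIFEST_COLUMNS))
    .writeTsvWithHeader(empty, manifestPath)
    return(invisible(list(manifest = manifestPath, groundTruth = NULL,
                          assignments = assign)))
  }
  rows <- list(); truthRows <- list()
  for (i in seq_len(config$nSubjects)) {
    sim <- simulateSubject(config, i)
    subj <- sim$assignment$subject_id
    subjDir <- file.path(outDir, subj)
    dir.create(subjDir, showWarnings = FALSE)
    for (nm in names(sim$samples)) {
      s <- sim$samples[[nm]]
      rel <- file.path(subj, paste0(nm, ".tsv"))
      ok <- tryCatch(
        writeClonotypeTable(s, file.path(outDir, rel)),
        error = function(e) stop("while writing ", file.path(outDir, rel),
                                 ": ", conditionMessage(e), call. = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sampleId(s), path = rel, subject_id = subj,
        timepoint = timepoint(s), compartment = compartment(s),
        subset = subsetLabel(s),
        induction_group = sim$assignment$induction_group,
        biopsy_status = sim$assignment$biopsy_status,
        genome_equivalents = genomeEquivalents(s),
        stringsAsFactors = FALSE)
    }
    for (ss in c("cd4", "cd8")) {
      keys <- if (ss == "cd4") sim$truth$alloCd4 else sim$truth$alloCd8
      if (length(keys))
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          subject_id = subj, subset = ss, rearrangement = keys,
          expansion = unname(sim$truth$expansion[keys]),
          stringsAsFactors = FALSE)
    }
  }
  .writeTsvWithHeader(do.call(rbind, rows), manifestPath)
  truthDf <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(subject_id = character(0), subset = character(0),
               rearrangement = character(0), expansion = numeric(0))
  .writeTsvWithHeader(truthDf, truthPath)
  invisible(list(manifest = manifestPath, groundTruth = truthPath,
                 assignments = assign))
}
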