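#' Analysis parameters for the DRTC pipeline
#'
#' @param alpha FDR threshold on the BH-adjusted p-value (default 0.01).
#' @param foldMin minimum frequency fold change (default 2).
#' @param countFloor minimum combined template count (default 5).
#' @param method two-sided p-value rule, see [binomTwoSidedP()].
#' @param qcThreshold different-subject Morisita flag threshold for
#'   [qcPairwise()].
#' @return a named list of validated parameters.
#' @export
drtcParams <- function(alpha = 0.01, foldMin = 2, countFloor = 5L,
                       method = c("minlike", "doubling"),
                       qcThreshold = 0.2) {
  list(alpha = alpha, foldMin = foldMin, countFloor = as.integer(countFloor),
       method = match.arg(method), qcThreshold = qcThreshold)
}

## locate the roles a subject's samples play in the analysis
.subjectRoles <- function(samples) {
  tp <- vapply(samples, timepoint, character(1))
  cp <- vapply(samples, compartment, character(1))
  ss <- vapply(samples, subsetLabel, character(1))
  unstim <- which(cp == "pbmc" & tp == "pre_tx" & ss == "bulk")
  post <- which(cp == "pbmc" & tp != "pre_tx" & ss == "bulk")
  if (length(post) > 1L)
    post <- post[order(.timepointRank(tp[post]))]
  biopsies <- which(cp == "biopsy")
  if (length(biopsies) > 1L)
    biopsies <- biopsies[order(.timepointRank(tp[biopsies]))]
  urine <- which(cp == "urine" & tp == "wk2")
  list(unstim = if (length(unstim)) unstim[1L] else NA_integer_,
       mlr = list(cd4 = which(cp == "mlr_sort" & ss == "cd4")[1L],
                  cd8 = which(cp == "mlr_sort" & ss == "cd8")[1L]),
       postPbmc = if (length(post)) post[1L] else NA_integer_,
       ## samples from the first rejection episode (or the earliest
       ## protocol biopsy) are used for primary analyses
       firstBiopsy = if (length(biopsies)) biopsies[1L] else NA_integer_,
       biopsies = biopsies,
       urine = if (length(urine)) urine[1L] else NA_integer_)
}

#' Run the full DRTC analysis for one subject
#'
#' Requires an unstimulated pre-transplant PBMC sample and at least one
#' MLR-sorted sample; per available sorted subset it calls DRTC, builds the
#' tracking table, evaluates longitudinal metrics over the blood series,
#' categorizes graft-infiltrating clones (when a biopsy exists; the
#' partition is partial when the paired post-transplant PBMC is missing)
#' and computes the 2-week urine to later-biopsy overlap (when both
#' exist). Partial specimen sets produce partial reports with explicit
#' gaps, never errors.
#'
#' @param samples list of \linkS4class{RepertoireSample} objects, all from
#'   one subject.
#' @param params a [drtcParams()] list.
#' @return subject report: list with \code{subject_id}, \code{skipped}
#'   (with \code{reason} when no unstimulated sample exists),
#'   \code{subsets} (per-subset list of \code{drtc}, \code{tracking},
#'   \code{longitudinal}, \code{categorization}, \code{urineOverlap},
#'   \code{gaps}) and \code{bulkSummary}.
#' @export
runSubject <- function(samples, params = drtcParams()) {
  stopifnot(length(samples) >= 1L)
  subj <- unique(vapply(samples, subjectId, character(1)))
  if (length(subj) != 1L)
    stop("samples from multiple subjects passed to runSubject: ",
         paste(subj, collapse = ", "))
  roles <- .subjectRoles(samples)
  if (is.na(roles$unstim)) {
    message("subject ", subj,
            ": skipped (no unstimulated pre-transplant PBMC sample)")
    return(list(subject_id = subj, skipped = TRUE,
                reason = "missing pre-transplant unstimulated PBMC"))
  }
  unstim <- samples[[roles$unstim]]
  bulkSummary <- do.call(rbind, lapply(samples, repertoireSummary))
  rownames(bulkSummary) <- NULL

  subsets <- list()
  for (ss in c("cd4", "cd8")) {
    idx <- roles$mlr[[ss]]
    if (is.na(idx)) next
    drtc <- callDRTC(samples[[idx]], unstim, alpha = params$alpha,
                     foldMin = params$foldMin,
                     countFloor = params$countFloor, method = params$method)
    ## tracking covers every non-MLR sample of the subject
    trackIdx <- which(vapply(samples, compartment,
                             character(1)) != "mlr_sort")
    tracking <- buildTracking(drtc, samples[trackIdx])
    pbmcIdx <- c(roles$unstim,
                 if (!is.na(roles$postPbmc)) roles$postPbmc)
    longitudinal <- longitudinalDrtcSummary(drtc, samples[pbmcIdx])
    gaps <- character(0)
    categorization <- NULL
    if (!is.na(roles$firstBiopsy)) {
      post <- if (!is.na(roles$postPbmc)) samples[[roles$postPbmc]] else NULL
      if (is.null(post))
        gaps <- c(gaps,
                  "no post-transplant PBMC: graft categorization is partial")
      categorization <- categorizeGraftClones(
        drtc, samples[[roles$firstBiopsy]], unstim, post)
    } else gaps <- c(gaps, "no biopsy: graft categorization absent")
    urineOverlap <- NULL
    if (!is.na(roles$urine) && length(roles$biopsies)) {
      urineOverlap <- urineGraftOverlap(drtc, samples[[roles$urine]],
                                        samples[roles$biopsies])
    } else if (is.na(roles$urine))
      gaps <- c(gaps, "no 2-week urine sample: urine overlap absent")
    subsets[[ss]] <- list(drtc = drtc, tracking = tracking,
                          longitudinal = longitudinal,
                          categorization = categorization,
                          urineOverlap = urineOverlap, gaps = gaps)
  }
  if (!length(subsets))
    message("subject ", subj, ": no MLR-sorted samples, DRTC not called")
  list(subject_id = subj, skipped = FALSE, subsets = subsets,
       bulkSummary = bulkSummary)
}

## one summary row per (subject, subset) for the cohort roll-up
.subjectSummaryRows <- function(report, induction, biopsyStatus, preMI) {
  rows <- list()
  for (ss in names(report$subsets)) {
    sub <- report$subsets[[ss]]
    res <- sub$longitudinal
    pre <- res[res$timepoint == "pre_tx", , drop = FALSE]
    post <- res[res$timepoint != "pre_tx", , drop = FALSE]
    cat4 <- sub$categorization
    uo <- sub$urineOverlap
    ## biopsy detection metrics come from the tracking table
    tt <- sub$tracking
    bIdx <- which(trackingSamples(tt)$compartment == "biopsy")
    nBiopsy <- if (length(bIdx))
      sum(trackingMatrix(tt, "present")[, bIdx[1L]]) else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = report$subject_id, subset = ss,
      induction_group = induction, biopsy_status = biopsyStatus,
      n_drtc = length(drtcClones(sub$drtc)),
      pre_n_detected = if (nrow(pre)) pre$n_detected[1L] else NA_integer_,
      pre_breadth = if (nrow(pre)) pre$breadth[1L] else NA_real_,
      pre_depth = if (nrow(pre)) pre$depth[1L] else NA_real_,
      post_n_detected = if (nrow(post)) post$n_detected[1L] else NA_integer_,
      post_breadth = if (nrow(post)) post$breadth[1L] else NA_real_,
      post_depth = if (nrow(post)) post$depth[1L] else NA_real_,
      pre_post_morisita = preMI,
      biopsy_n_detected = nBiopsy,
      urine_n_detected = if (is.null(uo)) NA_integer_ else uo$nUrineDetected,
      urine_biopsy_overlap = if (is.null(uo)) NA_integer_ else
        uo$nAlsoInBiopsy,
      cat_pre_only = if (is.null(cat4)) NA_real_ else
        unname(cat4$shares["pre_only"]),
      cat_pre_and_post = if (is.null(cat4) || cat4$partial) NA_real_ else
        unname(cat4$shares["pre_and_post"]),
      cat_post_only = if (is.null(cat4) || cat4$partial) NA_real_ else
        unname(cat4$shares["post_only"]),
      cat_graft_only = if (is.null(cat4) || cat4$partial) NA_real_ else
        unname(cat4$shares["graft_only"]),
      cumulative_pre_share = if (is.null(cat4)) NA_real_ else
        cat4$cumulativePreShare,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## cohort-level group comparisons mirroring the study's stratifications
.cohortComparisons <- function(summary) {
  out <- list()
  .add <- function(gc) out[[length(out) + 1L]] <<- .comparisonRow(gc)
  .try2 <- function(x, y, metric, groups) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) >= 2L && length(y) >= 2L)
      .add(mannWhitneyU(x, y, metric = metric, groups = groups))
    else warning("skipping comparison '", metric,
                 "': a group has fewer than 2 values", call. = FALSE)
  }
  cd4 <- summary[summary$subset == "cd4", , drop = FALSE]
  camp <- cd4$induction_group == "campath"
  .try2(cd4$pre_post_morisita[camp], cd4$pre_post_morisita[!camp],
        "pre_post_morisita", c("campath", "non_campath"))
  nonCampath <- summary[summary$induction_group == "non_campath", ,
                        drop = FALSE]
  for (ss in c("cd4", "cd8")) {
    g <- nonCampath[nonCampath$subset == ss, , drop = FALSE]
    st <- g$biopsy_status == "stable"
    .try2(g$pre_depth[!st], g$pre_depth[st],
          paste0("pre_tx_", ss, "_drtc_depth"),
          c("non_stable", "stable"))
    .try2(g$biopsy_n_detected[!st], g$biopsy_n_detected[st],
          paste0("biopsy_", ss, "_drtc_count"),
          c("non_stable", "stable"))
    .try2(g$urine_n_detected[!st], g$urine_n_detected[st],
          paste0("urine_wk2_", ss, "_drtc_count"),
          c("non_stable", "stable"))
    ## paired pre vs post DRTC counts, per induction group
    for (ind in c("campath", "non_campath")) {
      gg <- summary[summary$subset == ss &
                      summary$induction_group == ind, , drop = FALSE]
      ok <- !is.na(gg$pre_n_detected) & !is.na(gg$post_n_detected)
      if (sum(ok) >= 2L)
        .add(wilcoxonSignedRank(gg$pre_n_detected[ok],
                                gg$post_n_detected[ok],
                                metric = paste0(ind, "_", ss,
                                                "_n_drtc_pre_vs_post")))
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Run the DRTC pipeline over a cohort manifest
#'
#' Loads every sample referenced by the manifest, runs the pairwise
#' sample-identity QC, analyses each subject independently (BH multiplicity
#' is never pooled across subjects) and writes deterministic tab-separated
#' reports: per-subject DRTC result tables, a cohort summary (one row per
#' subject and subset), group comparisons stratified by induction group and
#' biopsy status, and the QC pair table. All outputs carry '#'-prefixed
#' provenance headers echoing the parameters; given identical inputs the
#' outputs are byte-identical across runs.
#'
#' @param manifestPath path to a manifest readable by [readManifest()].
#' @param outDir output directory for the report files.
#' @param params a [drtcParams()] list.
#' @return invisibly, a list with the per-subject reports, the cohort
#'   summary data.frame, the comparisons data.frame and the QC result.
#' @export
runCohort <- function(manifestPath, outDir, params = drtcParams()) {
  manifest <- readManifest(manifestPath)
  if (nrow(manifest) == 0L) stop("empty manifest: ", manifestPath)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  message("loading ", nrow(manifest), " samples from ", manifestPath)
  samples <- loadManifestSamples(manifest)
  qc <- qcPairwise(samples, threshold = params$qcThreshold)
  provenance <- sprintf(
    "# alloTCR cohort report: alpha=%g foldMin=%g countFloor=%d method=%s qcThreshold=%g",
    params$alpha, params$foldMin, params$countFloor, params$method,
    params$qcThreshold)
  .writeTsvWithHeader(qc$pairs, file.path(outDir, "qc_pairs.tsv"),
                      provenance)
  if (any(qc$pairs$flagged))
    warning("QC flagged ", sum(qc$pairs$flagged),
            " cross-subject sample pair(s); check qc_pairs.tsv")

  subjects <- unique(manifest$subject_id)
  reports <- list(); summaryRows <- list(); bulkRows <- list()
  for (subj in subjects) {
    message("analysing subject ", subj)
    sIdx <- manifest$subject_id == subj
    rep <- runSubject(samples[manifest$sample_id[sIdx]], params)
    reports[[subj]] <- rep
    if (isTRUE(rep$skipped)) next
    bulkRows[[subj]] <- rep$bulkSummary
    ## pre/post bulk-blood Morisita for the induction-effect comparison
    subjSamples <- samples[manifest$sample_id[sIdx]]
    roles <- .subjectRoles(subjSamples)
    preMI <- if (!is.na(roles$unstim) && !is.na(roles$postPbmc))
      morisitaIndex(subjSamples[[roles$unstim]],
                    subjSamples[[roles$postPbmc]]) else NA_real_
    arow <- manifest[sIdx, ][1L, ]
    summaryRows[[subj]] <- .subjectSummaryRows(
      rep, arow$induction_group, arow$biopsy_status, preMI)
    for (ss in names(rep$subsets))
      writeDRTCTable(rep$subsets[[ss]]$drtc,
                     file.path(outDir,
                               sprintf("%s_%s_drtc.tsv", subj, ss)))
  }
  summary <- if (length(summaryRows)) do.call(rbind, summaryRows) else NULL
  comparisons <- NULL
  if (!is.null(summary)) {
    rownames(summary) <- NULL
    .writeTsvWithHeader(summary, file.path(outDir, "cohort_summary.tsv"),
                        provenance)
    bulk <- do.call(rbind, bulkRows)
    rownames(bulk) <- NULL
    .writeTsvWithHeader(bulk, file.path(outDir, "bulk_summary.tsv"),
                        provenance)
    if (length(unique(summary$subject_id)) >= 2L) {
      comparisons <- withCallingHandlers(
        .cohortComparisons(summary),
        warning = function(w) {
          message("note: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (!is.null(comparisons))
        .writeTsvWithHeader(comparisons,
                            file.path(outDir, "comparisons.tsv"),
                            provenance)
    } else {
      message("single-subject cohort: group comparisons skipped")
    }
  }
  invisible(list(reports = reports, summary = summary,
                 comparisons = comparisons, qc = qc))
}
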