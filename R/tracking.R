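#' Build a clone-by-sample tracking table for a DRTC set
#'
#' Serially monitors the presence and frequency of a subject's
#' pre-identified DRTC across that subject's longitudinal samples. Samples
#' are ordered chronologically (pre-transplant, 2 weeks, 3/6/12 months,
#' rejection episodes last) and, within a timepoint, by compartment. A
#' clone absent from a sample is recorded as (absent, 0 templates,
#' frequency 0); the grid is always complete.
#'
#' @param drtc a \linkS4class{DRTCSet}.
#' @param samples list of \linkS4class{RepertoireSample} objects, all from
#'   the DRTC set's subject.
#' @return a \linkS4class{TrackingTable}.
#' @export
buildTracking <- function(drtc, samples) {
  stopifnot(is(drtc, "DRTCSet"), length(samples) >= 1L)
  subj <- vapply(samples, subjectId, character(1))
  if (any(subj != drtc@subjectId))
    stop("sample(s) from another subject: ",
         paste(sQuote(unique(subj[subj != drtc@subjectId])), collapse = ", "))
  ord <- order(.timepointRank(vapply(samples, timepoint, character(1))),
               match(vapply(samples, compartment, character(1)),
                     .COMPARTMENTS))
  samples <- samples[ord]
  clones <- sort(drtcClones(drtc))
  meta <- do.call(rbind, lapply(samples, function(s) data.frame(
    sample_id = s@sampleId, timepoint = s@timepoint,
    compartment = s@compartment, subset = s@subset,
    total_templates = totalTemplates(s), stringsAsFactors = FALSE)))
  counts <- matrix(0L, nrow = length(clones), ncol = length(samples),
                   dimnames = list(clones, meta$sample_id))
  freqs <- matrix(0, nrow = length(clones), ncol = length(samples),
                  dimnames = dimnames(counts))
  for (j in seq_along(samples)) {
    cl <- samples[[j]]@clones
    cl <- cl[cl$productive, , drop = FALSE]
    hit <- match(clones, cl$rearrangement)
    cnt <- cl$templates[hit]
    cnt[is.na(cnt)] <- 0L
    counts[, j] <- cnt
    tot <- sum(cl$templates)
    freqs[, j] <- if (tot > 0) cnt / tot else 0
  }
  new("TrackingTable", subjectId = drtc@subjectId, subset = drtc@subset,
      samples = meta, present = counts >= 1L, counts = counts,
      freqs = freqs)
}

.GRAFT_CATEGORIES <- c("pre_only", "pre_and_post", "post_only", "graft_only")

#' Categorize presence patterns of graft-detected clones
#'
#' The elementary four-way rule behind [categorizeGraftClones()]: a
#' graft-detected clone seen in the pre-transplant blood only is
#' \code{pre_only}; in both blood samples \code{pre_and_post}; newly in the
#' post-transplant blood \code{post_only}; in neither \code{graft_only}
#' (present in the kidney at a frequency too low for blood detection).
#'
#' @param inPre,inPost logical vectors (equal length): detection in the
#'   pre- and post-transplant PBMC samples.
#' @return character vector of exclusive category labels.
#' @examples
#' categorizePresence(c(TRUE, TRUE, FALSE, FALSE),
#'                    c(FALSE, TRUE, TRUE, FALSE))
#' @export
categorizePresence <- function(inPre, inPost) {
  stopifnot(is.logical(inPre), is.logical(inPost),
            length(inPre) == length(inPost))
  ifelse(inPre & inPost, "pre_and_post",
         ifelse(inPre, "pre_only",
                ifelse(inPost, "post_only", "graft_only")))
}

#' Categorize graft-infiltrating DRTC by circulating detectability
#'
#' For the DRTC detected in an allograft biopsy, assigns each clone one
#' exclusive label by its presence (count >= 1) in the pre-transplant and
#' paired post-transplant PBMC samples, and reports the category shares
#' plus the cumulative pre-transplant detection share
#' (\code{pre_only + pre_and_post}), so both the exclusive partition and
#' the cumulative presentation are available.
#'
#' When the paired post-transplant PBMC sample is missing the partition
#' degrades to \{\code{pre_only}, \code{undetermined}\} (a clone undetected
#' pre-transplant cannot be split into \code{post_only} vs
#' \code{graft_only}) and \code{partial} is set; nothing is imputed. The
#' cumulative pre-transplant share remains exact in either mode.
#'
#' @param drtc a \linkS4class{DRTCSet}.
#' @param graft allograft biopsy \linkS4class{RepertoireSample}.
#' @param prePbmc pre-transplant PBMC sample.
#' @param postPbmc paired post-transplant PBMC sample, or \code{NULL} when
#'   unavailable.
#' @return list with \code{perClone} (clone-level data.frame),
#'   \code{shares} (named numeric, sums to 1 when n > 0), \code{counts},
#'   \code{cumulativePreShare}, \code{n}, \code{partial} and
#'   \code{degenerate} (TRUE when no DRTC is detected in the graft, in
#'   which case shares are \code{NA}).
#' @export
categorizeGraftClones <- function(drtc, graft, prePbmc, postPbmc = NULL) {
  stopifnot(is(drtc, "DRTCSet"), is(graft, "RepertoireSample"),
            is(prePbmc, "RepertoireSample"))
  for (s in c(list(graft, prePbmc),
              if (!is.null(postPbmc)) list(postPbmc)))
    if (subjectId(s) != drtc@subjectId)
      stop("sample '", sampleId(s), "' belongs to subject '",
           subjectId(s), "', not '", drtc@subjectId, "'")
  universe <- intersect(drtcClones(drtc), .detectedKeys(graft))
  partial <- is.null(postPbmc)
  cats <- if (partial) c("pre_only", "undetermined") else .GRAFT_CATEGORIES
  if (length(universe) == 0L) {
    return(list(
      perClone = data.frame(rearrangement = character(0),
                            in_pre = logical(0), in_post = logical(0),
                            category = character(0),
                            stringsAsFactors = FALSE),
      shares = stats::setNames(rep(NA_real_, length(cats)), cats),
      counts = stats::setNames(integer(length(cats)), cats),
      cumulativePreShare = NA_real_, n = 0L,
      partial = partial, degenerate = TRUE))
  }
  inPre <- universe %in% .detectedKeys(prePbmc)
  if (partial) {
    inPost <- rep(NA, length(universe))
    category <- ifelse(inPre, "pre_only", "undetermined")
  } else {
    inPost <- universe %in% .detectedKeys(postPbmc)
    category <- categorizePresence(inPre, inPost)
  }
  counts <- stats::setNames(integer(length(cats)), cats)
  tab <- table(factor(category, levels = cats))
  counts[names(tab)] <- as.integer(tab)
  shares <- counts / length(universe)
  list(
    perClone = data.frame(rearrangement = universe, in_pre = inPre,
                          in_post = inPost, category = category,
                          stringsAsFactors = FALSE),
    shares = shares,
    counts = counts,
    cumulativePreShare = mean(inPre),
    n = length(universe),
    partial = partial,
    degenerate = FALSE)
}

#' Overlap of early urinary DRTC with later allograft biopsies
#'
#' Counts the DRTC detected in an early (typically 2-week) urine sample and
#' reports which of those clones reappear in at least one later biopsy,
#' with clone-level detail. The urine sample must chronologically precede
#' every biopsy in the list.
#'
#' @param drtc a \linkS4class{DRTCSet}.
#' @param urine urine \linkS4class{RepertoireSample}.
#' @param laterBiopsies list of biopsy samples taken after the urine
#'   sample.
#' @return list with \code{nUrineDetected}, \code{nAlsoInBiopsy} and
#'   \code{detail} (data.frame: rearrangement, urine_count, biopsy id,
#'   biopsy_count; one row per clone-biopsy detection, empty when none).
#' @export
urineGraftOverlap <- function(drtc, urine, laterBiopsies) {
  stopifnot(is(drtc, "DRTCSet"), is(urine, "RepertoireSample"),
            length(laterBiopsies) >= 1L)
  uRank <- .timepointRank(urine@timepoint)
  for (b in laterBiopsies) {
    stopifnot(is(b, "RepertoireSample"))
    if (.timepointRank(b@timepoint) <= uRank)
      stop("biopsy '", sampleId(b), "' (", timepoint(b),
           ") does not follow the urine sample (", urine@timepoint, ")")
  }
  urineKeys <- intersect(drtcClones(drtc), .detectedKeys(urine))
  uCounts <- urine@clones$templates[match(urineKeys,
                                          urine@clones$rearrangement)]
  rows <- list()
  for (b in laterBiopsies) {
    cl <- b@clones[b@clones$productive & b@clones$templates >= 1L, ,
                   drop = FALSE]
    hit <- urineKeys[urineKeys %in% cl$rearrangement]
    if (length(hit))
      rows[[length(rows) + 1L]] <- data.frame(
        rearrangement = hit,
        urine_count = uCounts[match(hit, urineKeys)],
        biopsy = sampleId(b),
        biopsy_count = cl$templates[match(hit, cl$rearrangement)],
        stringsAsFactors = FALSE)
  }
  detail <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rearrangement = character(0), urine_count = integer(0),
               biopsy = character(0), biopsy_count = integer(0),
               stringsAsFactors = FALSE)
  list(nUrineDetected = length(urineKeys),
       nAlsoInBiopsy = length(unique(detail$rearrangement)),
       detail = detail)
}

#' Per-timepoint DRTC metrics along a sample series
#'
#' Evaluates [drtcMetrics()] for each sample of a longitudinal series
#' (ordered chronologically), yielding the (absolute number, breadth,
#' depth) triplets used for paired pre/post comparisons. Missing timepoints
#' are simply absent from the series; nothing is imputed.
#'
#' @param drtc a \linkS4class{DRTCSet}.
#' @param samples list of \linkS4class{RepertoireSample} objects from the
#'   DRTC set's subject.
#' @return data.frame, one row per sample in chronological order:
#'   \code{sample_id, timepoint, compartment, subset, n_detected, breadth,
#'   depth}.
#' @export
longitudinalDrtcSummary <- function(drtc, samples) {
  stopifnot(is(drtc, "DRTCSet"), length(samples) >= 1L)
  subj <- vapply(samples, subjectId, character(1))
  if (any(subj != drtc@subjectId))
    stop("sample(s) from another subject")
  ord <- order(.timepointRank(vapply(samples, timepoint, character(1))))
  samples <- samples[ord]
  out <- do.call(rbind, lapply(samples, function(s) {
    m <- drtcMetrics(drtc, s)
    cbind(data.frame(sample_id = s@sampleId, timepoint = s@timepoint,
                     compartment = s@compartment, stringsAsFactors = FALSE),
          m[, c("subset", "n_detected", "breadth", "depth")])
  }))
  rownames(out) <- NULL
  out
}
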