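#' Morisita-Horn overlap of two repertoires
#'
#' Abundance-weighted similarity on productive clone frequencies over the
#' union of clone keys:
#' \deqn{MH = \frac{2 \sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}}
#' Scores 0 for completely divergent repertoires and 1 for identical ones.
#' The classical Morisita index needs integer dispersion terms and can
#' exceed 1; the Morisita-Horn form is the 0-1-bounded variant used for
#' repertoire comparison and is what this package computes.
#'
#' @param sampleA,sampleB \linkS4class{RepertoireSample} objects with
#'   productive templates.
#' @return a value in \[0, 1\].
#' @examples
#' a <- exampleSample(c(x = 5, y = 5))
#' b <- exampleSample(c(x = 10))
#' morisitaIndex(a, b)   # 2/3
#' @export
morisitaIndex <- function(sampleA, sampleB) {
  fa <- cloneFrequencies(sampleA)
  fb <- cloneFrequencies(sampleB)
  keys <- union(names(fa), names(fb))
  p <- fa[match(keys, names(fa))]; p[is.na(p)] <- 0
  q <- fb[match(keys, names(fb))]; q[is.na(q)] <- 0
  mh <- 2 * sum(p * q) / (sum(p^2) + sum(q^2))
  min(max(mh, 0), 1)
}

#' Jaccard overlap of two repertoires
#'
#' Shared productive clonotypes over the union, ignoring abundance.
#'
#' @inheritParams morisitaIndex
#' @return a value in \[0, 1\].
#' @examples
#' jaccardIndex(exampleSample(c(a = 1, b = 1)),
#'              exampleSample(c(b = 1, c = 1)))   # 1/3
#' @export
jaccardIndex <- function(sampleA, sampleB) {
  a <- .detectedKeys(sampleA)
  b <- .detectedKeys(sampleB)
  if (length(a) == 0L && length(b) == 0L)
    stop("both samples are empty: Jaccard index undefined")
  shared <- length(intersect(a, b))
  shared / (length(a) + length(b) - shared)
}

#' DRTC detection metrics within one sample
#'
#' A DRTC clone is "detected" when it carries at least one template in the
#' sample. Breadth is the fraction of the sample's unique productive
#' clonotypes that are DRTC; depth is the summed frequency of detected DRTC
#' (fraction of all T cells in the sample).
#'
#' @param drtc a \linkS4class{DRTCSet} or a character vector of clone keys.
#' @param sample a \linkS4class{RepertoireSample} with productive
#'   templates.
#' @return data.frame row: \code{sample_id, subset, n_detected, breadth,
#'   depth}. An empty DRTC set yields zeros, not an error.
#' @examples
#' s <- exampleSample(c(a = 10, b = 10, c = 80))
#' drtcMetrics(c("a", "b"), s)   # n 2, breadth 2/3, depth 0.2
#' @export
drtcMetrics <- function(drtc, sample) {
  keys <- if (is(drtc, "DRTCSet")) drtcClones(drtc) else as.character(drtc)
  subset <- if (is(drtc, "DRTCSet")) drtc@subset else NA_character_
  f <- cloneFrequencies(sample)
  detected <- intersect(keys, names(f)[f > 0])
  nUnique <- uniqueProductiveClonotypes(sample)
  data.frame(
    sample_id = sample@sampleId,
    subset = subset,
    n_detected = length(detected),
    breadth = if (nUnique) length(detected) / nUnique else 0,
    depth = sum(f[detected]),
    stringsAsFactors = FALSE)
}

#' T-cell fraction of a sample
#'
#' Productive templates divided by the input genome equivalents: the
#' fraction of nucleated cells in the specimen that are T cells. When the
#' genome-equivalent denominator was not recorded, the metric is reported as
#' \code{NA} rather than fabricated.
#'
#' @param sample a \linkS4class{RepertoireSample}.
#' @return fraction in \[0, 1\], or \code{NA} when genome equivalents are
#'   absent.
#' @export
tcellFraction <- function(sample) {
  stopifnot(is(sample, "RepertoireSample"))
  ge <- sample@genomeEquivalents
  if (is.na(ge)) return(NA_real_)
  min(max(totalTemplates(sample) / ge, 0), 1)
}

#' One-row bulk repertoire summary
#'
#' @param sample a \linkS4class{RepertoireSample}.
#' @return data.frame row with sample metadata, unique productive
#'   clonotypes, productive template total and T-cell fraction.
#' @export
repertoireSummary <- function(sample) {
  stopifnot(is(sample, "RepertoireSample"))
  data.frame(
    sample_id = sample@sampleId, subject_id = sample@subjectId,
    timepoint = sample@timepoint, compartment = sample@compartment,
    subset = sample@subset,
    unique_productive_clonotypes = uniqueProductiveClonotypes(sample),
    total_templates = totalTemplates(sample),
    tcell_fraction = tcellFraction(sample),
    stringsAsFactors = FALSE)
}

#' Pairwise sample-identity quality control
#'
#' Computes the full symmetric Morisita-Horn (and Jaccard) overlap across a
#' batch of samples. High abundance-weighted overlap between samples of
#' DIFFERENT subjects indicates possible material transfer or sample
#' swapping and is flagged; same-subject pairs are never flagged, however
#' similar.
#'
#' @param samples list of at least two \linkS4class{RepertoireSample}
#'   objects.
#' @param threshold flag a different-subject pair when its Morisita-Horn
#'   overlap exceeds this (default 0.2; unrelated repertoires share
#'   vanishing high-frequency mass).
#' @return list with \code{morisita} (symmetric matrix) and \code{pairs}
#'   (long data.frame: sample_a, sample_b, subject_a, subject_b, morisita,
#'   jaccard, flagged).
#' @export
qcPairwise <- function(samples, threshold = 0.2) {
  stopifnot(length(samples) >= 2L)
  ids <- vapply(samples, sampleId, character(1))
  subj <- vapply(samples, subjectId, character(1))
  n <- length(samples)
  M <- diag(1, n); dimnames(M) <- list(ids, ids)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    mi <- morisitaIndex(samples[[i]], samples[[j]])
    ji <- jaccardIndex(samples[[i]], samples[[j]])
    M[i, j] <- M[j, i] <- mi
    k <- k + 1L
    rows[[k]] <- data.frame(
      sample_a = ids[i], sample_b = ids[j],
      subject_a = subj[i], subject_b = subj[j],
      morisita = mi, jaccard = ji,
      flagged = (subj[i] != subj[j]) && mi > threshold,
      stringsAsFactors = FALSE)
  }
  list(morisita = M, pairs = do.call(rbind, rows))
}
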