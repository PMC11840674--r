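#' @import methods
NULL

## Controlled vocabularies for sample metadata. These mirror the specimen
## schedule of a transplant monitoring study: pre-transplant baseline, an
## early (2-week) urine, protocol visits at 3/6/12 months, and rejection
## episodes.
.TIMEPOINTS   <- c("pre_tx", "wk2", "m3", "m6", "m12", "rejection")
.COMPARTMENTS <- c("pbmc", "mlr_sort", "biopsy", "urine")
.SUBSETS      <- c("bulk", "cd4", "cd8")
.CALL_CLASSES <- c("drtc", "enriched_unstim", "not_significant",
                   "below_count_floor")

.CLONE_COLUMNS <- c("rearrangement", "cdr3_aa", "v_gene", "j_gene",
                    "productive", "templates")

#' RepertoireSample: one TCRbeta sequencing sample
#'
#' Container for a single immunosequencing sample: a clonotype table
#' (nucleotide rearrangement as the clone key, with CDR3 amino-acid sequence,
#' V/J gene labels, productive flag and template count) together with the
#' sample's metadata. Template counts are genomic-DNA molecule counts, so a
#' clone's count quantifies cell numbers. All frequencies, totals, tests and
#' overlap indices in this package are computed over productive clones only.
#'
#' @slot sampleId character(1), unique sample identifier.
#' @slot subjectId character(1).
#' @slot timepoint one of \code{pre_tx, wk2, m3, m6, m12, rejection}.
#' @slot compartment one of \code{pbmc, mlr_sort, biopsy, urine}.
#' @slot subset one of \code{bulk, cd4, cd8} (sorted population).
#' @slot clones data.frame with columns \code{rearrangement, cdr3_aa, v_gene,
#'   j_gene, productive, templates}; rearrangements are unique within the
#'   sample.
#' @slot genomeEquivalents integer(1); total input nucleated-cell genomes
#'   (for the T-cell fraction metric), or \code{NA} when unknown.
#'
#' @seealso [readClonotypeTable()], [cloneFrequencies()], [totalTemplates()]
#' @export
setClass("RepertoireSample",
  representation(
    sampleId = "character",
    subjectId = "character",
    timepoint = "character",
    compartment = "character",
    subset = "character",
    clones = "data.frame",
    genomeEquivalents = "integer"
  ),
  prototype(
    sampleId = "sample", subjectId = "subject",
    timepoint = "pre_tx", compartment = "pbmc", subset = "bulk",
    genomeEquivalents = NA_integer_
  )
)

.validRepertoireSample <- function(object) {
  msg <- character(0)
  for (sl in c("sampleId", "subjectId", "timepoint", "compartment", "subset"))
    if (length(slot(object, sl)) != 1L || is.na(slot(object, sl)))
      msg <- c(msg, sprintf("slot '%s' must be a single non-NA string", sl))
  if (length(object@timepoint) == 1L && !object@timepoint %in% .TIMEPOINTS)
    msg <- c(msg, sprintf("unknown timepoint '%s' (expected one of %s)",
                          object@timepoint, paste(.TIMEPOINTS, collapse = ", ")))
  if (length(object@compartment) == 1L &&
      !object@compartment %in% .COMPARTMENTS)
    msg <- c(msg, sprintf("unknown compartment '%s' (expected one of %s)",
                          object@compartment,
                          paste(.COMPARTMENTS, collapse = ", ")))
  if (length(object@subset) == 1L && !object@subset %in% .SUBSETS)
    msg <- c(msg, sprintf("unknown subset '%s' (expected one of %s)",
                          object@subset, paste(.SUBSETS, collapse = ", ")))
  cl <- object@clones
  missing_cols <- setdiff(.CLONE_COLUMNS, names(cl))
  if (length(missing_cols)) {
    msg <- c(msg, sprintf("clone table lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
    return(msg)
  }
  if (nrow(cl)) {
    if (any(is.na(cl$rearrangement)) || any(!nzchar(cl$rearrangement)))
      msg <- c(msg, "empty rearrangement key")
    if (anyDuplicated(cl$rearrangement))
      msg <- c(msg, "duplicate rearrangement keys within the sample")
    if (!is.numeric(cl$templates) || any(is.na(cl$templates)) ||
        any(cl$templates < 0) || any(cl$templates != floor(cl$templates)))
      msg <- c(msg, "template counts must be non-negative integers")
    if (!is.logical(cl$productive) || any(is.na(cl$productive)))
      msg <- c(msg, "productive flag must be TRUE/FALSE")
    ## CDR3 of a productive clone is plain amino acids; '*' (stop) and 'X'
    ## placeholders are only admissible for non-productive rearrangements.
    prod_aa <- cl$cdr3_aa[cl$productive & nzchar(cl$cdr3_aa)]
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", prod_aa)
    if (any(bad))
      msg <- c(msg, sprintf(
        "productive clone CDR3 contains non-amino-acid letters (e.g. '%s')",
        prod_aa[bad][1L]))
  }
  ge <- object@genomeEquivalents
  if (length(ge) != 1L || (!is.na(ge) && ge <= 0L))
    msg <- c(msg, "genomeEquivalents must be NA or a single positive integer")
  if (length(msg)) msg else TRUE
}
setValidity("RepertoireSample", .validRepertoireSample)

#' DRTCSet: donor-reactive clones called for one subject and subset
#'
#' Result of the differential-abundance comparison of an MLR-sorted sample
#' against the unstimulated pre-transplant sample. Holds the complete
#' per-clone result table (counts, frequencies, fold change, p and
#' BH-adjusted q, call class) together with the parameters used, so every
#' call is reproducible from the object alone.
#'
#' @slot subjectId character(1).
#' @slot subset sorted population the MLR sample came from (cd4 or cd8).
#' @slot results data.frame, one row per clone in the union of the two
#'   samples' productive clones: \code{rearrangement, count_mlr,
#'   count_unstim, total_mlr, total_unstim, freq_mlr, freq_unstim, fold,
#'   p_value, q_value, call}.
#' @slot parameters list with \code{alpha}, \code{foldMin}, \code{countFloor},
#'   \code{method} recorded for provenance.
#'
#' @seealso [callDRTC()], [drtcClones()], [classifyScatter()]
#' @export
setClass("DRTCSet",
  representation(
    subjectId = "character",
    subset = "character",
    results = "data.frame",
    parameters = "list"
  )
)

.RESULT_COLUMNS <- c("rearrangement", "count_mlr", "count_unstim",
                     "total_mlr", "total_unstim", "freq_mlr", "freq_unstim",
                     "fold", "p_value", "q_value", "call")

.validDRTCSet <- function(object) {
  msg <- character(0)
  missing_cols <- setdiff(.RESULT_COLUMNS, names(object@results))
  if (length(missing_cols))
    msg <- c(msg, sprintf("result table lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  else {
    res <- object@results
    if (nrow(res)) {
      if (!all(res$call %in% .CALL_CLASSES))
        msg <- c(msg, "unknown call class in result table")
      pv <- res$p_value[!is.na(res$p_value)]
      qv <- res$q_value[!is.na(res$q_value)]
      if (any(pv < 0 | pv > 1) || any(qv < 0 | qv > 1))
        msg <- c(msg, "p/q values outside [0,1]")
      ## BH can only raise a p-value or leave it unchanged
      both <- !is.na(res$p_value) & !is.na(res$q_value)
      if (any(res$q_value[both] < res$p_value[both] - 1e-12))
        msg <- c(msg, "q_value below p_value")
      below <- res$count_mlr + res$count_unstim <
        object@parameters$countFloor
      if (!identical(unname(below), unname(res$call == "below_count_floor")))
        msg <- c(msg, "below_count_floor call inconsistent with count floor")
    }
  }
  need <- c("alpha", "foldMin", "countFloor", "method")
  if (!all(need %in% names(object@parameters)))
    msg <- c(msg, "parameters must record alpha, foldMin, countFloor, method")
  if (length(msg)) msg else TRUE
}
setValidity("DRTCSet", .validDRTCSet)

#' TrackingTable: clone-by-sample presence/frequency grid for a DRTC set
#'
#' @slot subjectId character(1).
#' @slot subset cd4 or cd8.
#' @slot samples data.frame describing the tracked samples in chronological
#'   order (\code{sample_id, timepoint, compartment, subset,
#'   total_templates}).
#' @slot present logical matrix, clones x samples (count >= 1).
#' @slot counts integer matrix of template counts.
#' @slot freqs numeric matrix of within-sample frequencies.
#'
#' @seealso [buildTracking()]
#' @export
setClass("TrackingTable",
  representation(
    subjectId = "character",
    subset = "character",
    samples = "data.frame",
    present = "matrix",
    counts = "matrix",
    freqs = "matrix"
  )
)

.validTrackingTable <- function(object) {
  msg <- character(0)
  nS <- nrow(object@samples)
  for (sl in c("present", "counts", "freqs")) {
    m <- slot(object, sl)
    if (ncol(m) != nS)
      msg <- c(msg, sprintf("matrix '%s' has %d columns for %d samples",
                            sl, ncol(m), nS))
  }
  if (!identical(dim(object@present), dim(object@counts)) ||
      !identical(dim(object@counts), dim(object@freqs)))
    msg <- c(msg, "present/counts/freqs matrices differ in shape")
  if (nrow(object@counts) && any(object@present != (object@counts >= 1)))
    msg <- c(msg, "presence flag inconsistent with counts")
  if (length(msg)) msg else TRUE
}
setValidity("TrackingTable", .validTrackingTable)
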