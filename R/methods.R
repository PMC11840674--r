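#' Construct a RepertoireSample
#'
#' @param sampleId,subjectId,timepoint,compartment,subset sample metadata;
#'   see \linkS4class{RepertoireSample} for the admissible labels.
#' @param clones data.frame with columns \code{rearrangement, cdr3_aa,
#'   v_gene, j_gene, productive, templates}. Missing annotation columns are
#'   filled with empty strings.
#' @param genomeEquivalents optional positive integer (input cell genomes).
#' @return a validated \linkS4class{RepertoireSample}.
#' @export
RepertoireSample <- function(sampleId, subjectId, timepoint, compartment,
                             subset, clones,
                             genomeEquivalents = NA_integer_) {
  stopifnot(is.data.frame(clones))
  for (col in c("cdr3_aa", "v_gene", "j_gene"))
    if (is.null(clones[[col]])) clones[[col]] <- ""
  if (is.null(clones$productive)) clones$productive <- TRUE
  clones$templates <- as.integer(clones$templates)
  clones <- as.data.frame(clones)[, .CLONE_COLUMNS]
  rownames(clones) <- NULL
  new("RepertoireSample",
      sampleId = as.character(sampleId),
      subjectId = as.character(subjectId),
      timepoint = as.character(timepoint),
      compartment = as.character(compartment),
      subset = as.character(subset),
      clones = clones,
      genomeEquivalents = as.integer(genomeEquivalents))
}

#' Minimal sample constructor for examples and tests
#'
#' Builds a \linkS4class{RepertoireSample} from a named count vector, using
#' the names as rearrangement keys.
#'
#' @param counts named numeric vector of template counts.
#' @param productive logical vector (recycled) of productive flags.
#' @param ... metadata passed on to [RepertoireSample()].
#' @return a \linkS4class{RepertoireSample}.
#' @examples
#' exampleSample(c(a = 10, b = 5, c = 5))
#' @export
exampleSample <- function(counts, productive = TRUE,
                          ...) {
  args <- list(...)
  defaults <- list(sampleId = "example", subjectId = "subject",
                   timepoint = "pre_tx", compartment = "pbmc",
                   subset = "bulk")
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  args$clones <- data.frame(
    rearrangement = names(counts),
    cdr3_aa = "",
    v_gene = "",
    j_gene = "",
    productive = rep_len(productive, length(counts)),
    templates = as.integer(counts),
    stringsAsFactors = FALSE)
  do.call(RepertoireSample, args)
}

#' @rdname alloTCR-generics
setMethod("sampleId", "RepertoireSample", function(object) object@sampleId)

#' @rdname alloTCR-generics
setMethod("subjectId", "RepertoireSample", function(object) object@subjectId)

#' @rdname alloTCR-generics
setMethod("timepoint", "RepertoireSample", function(object) object@timepoint)

#' @rdname alloTCR-generics
setMethod("compartment", "RepertoireSample",
          function(object) object@compartment)

#' @rdname alloTCR-generics
setMethod("subsetLabel", "RepertoireSample", function(object) object@subset)

#' @rdname alloTCR-generics
setMethod("cloneTable", "RepertoireSample", function(object) object@clones)

#' @rdname alloTCR-generics
setMethod("genomeEquivalents", "RepertoireSample",
          function(object) object@genomeEquivalents)

#' @rdname alloTCR-generics
setMethod("totalTemplates", "RepertoireSample", function(object) {
  cl <- object@clones
  sum(cl$templates[cl$productive])
})

#' @rdname alloTCR-generics
setMethod("uniqueProductiveClonotypes", "RepertoireSample", function(object) {
  cl <- object@clones
  sum(cl$productive & cl$templates >= 1L)
})

setMethod("cloneFrequencies", "RepertoireSample", function(object) {
  cl <- object@clones[object@clones$productive, , drop = FALSE]
  tot <- sum(cl$templates)
  if (tot <= 0L)
    stop("degenerate sample '", object@sampleId,
         "': no productive templates, frequencies undefined")
  stats::setNames(cl$templates / tot, cl$rearrangement)
})

## productive clone keys with count >= 1 (the package-wide detection rule)
.detectedKeys <- function(sample) {
  cl <- sample@clones
  cl$rearrangement[cl$productive & cl$templates >= 1L]
}

setMethod("show", "RepertoireSample", function(object) {
  cl <- object@clones
  cat(sprintf(
    "RepertoireSample '%s' (subject %s, %s / %s / %s)\n",
    object@sampleId, object@subjectId, object@timepoint,
    object@compartment, object@subset))
  cat(sprintf("  %d clonotypes (%d productive), %d productive templates\n",
              nrow(cl), sum(cl$productive), totalTemplates(object)))
  if (!is.na(object@genomeEquivalents))
    cat(sprintf("  genome equivalents: %d\n", object@genomeEquivalents))
})

#' @rdname alloTCR-generics
setMethod("subjectId", "DRTCSet", function(object) object@subjectId)

#' @rdname alloTCR-generics
setMethod("subsetLabel", "DRTCSet", function(object) object@subset)

#' @rdname alloTCR-generics
setMethod("drtcResults", "DRTCSet", function(object) object@results)

#' @rdname alloTCR-generics
setMethod("drtcParameters", "DRTCSet", function(object) object@parameters)

setMethod("drtcClones", "DRTCSet", function(object) {
  object@results$rearrangement[object@results$call == "drtc"]
})

setMethod("show", "DRTCSet", function(object) {
  counts <- classifyScatter(object)
  p <- object@parameters
  cat(sprintf("DRTCSet: subject %s, %s subset\n",
              object@subjectId, object@subset))
  cat(sprintf(
    "  %d clones tested (of %d in the union), alpha=%g, fold>=%g, floor=%d\n",
    sum(!is.na(object@results$p_value)), nrow(object@results),
    p$alpha, p$foldMin, p$countFloor))
  cat(sprintf(
    "  calls: %d drtc, %d enriched_unstim, %d not_significant, %d below floor\n",
    counts[["drtc"]], counts[["enriched_unstim"]],
    counts[["not_significant"]], counts[["below_count_floor"]]))
})

#' @rdname alloTCR-generics
setMethod("subjectId", "TrackingTable", function(object) object@subjectId)

#' @rdname alloTCR-generics
setMethod("subsetLabel", "TrackingTable", function(object) object@subset)

setMethod("show", "TrackingTable", function(object) {
  cat(sprintf("TrackingTable: subject %s, %s DRTC set\n",
              object@subjectId, object@subset))
  cat(sprintf("  %d clones x %d samples (%s)\n",
              nrow(object@counts), nrow(object@samples),
              paste(object@samples$sample_id, collapse = ", ")))
})

#' Matrices of a TrackingTable
#'
#' @param object a \linkS4class{TrackingTable}.
#' @param what \code{"present"}, \code{"counts"} or \code{"freqs"}.
#' @return the requested clone-by-sample matrix.
#' @export
trackingMatrix <- function(object, what = c("present", "counts", "freqs")) {
  stopifnot(is(object, "TrackingTable"))
  slot(object, match.arg(what))
}

#' Sample metadata of a TrackingTable
#' @param object a \linkS4class{TrackingTable}.
#' @return data.frame of tracked samples in chronological order.
#' @export
trackingSamples <- function(object) {
  stopifnot(is(object, "TrackingTable"))
  object@samples
}
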