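#' @name alloTCR-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 containers. Slot access is
#'   considered internal; use these instead.
#' @param object a \linkS4class{RepertoireSample}, \linkS4class{DRTCSet} or
#'   \linkS4class{TrackingTable}.
#' @return the corresponding component; see the individual methods.
NULL

#' @rdname alloTCR-generics
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname alloTCR-generics
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname alloTCR-generics
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname alloTCR-generics
#' @export
setGeneric("compartment", function(object) standardGeneric("compartment"))

#' @rdname alloTCR-generics
#' @export
setGeneric("subsetLabel", function(object) standardGeneric("subsetLabel"))

#' @rdname alloTCR-generics
#' @export
setGeneric("cloneTable", function(object) standardGeneric("cloneTable"))

#' @rdname alloTCR-generics
#' @export
setGeneric("totalTemplates", function(object) standardGeneric("totalTemplates"))

#' @rdname alloTCR-generics
#' @export
setGeneric("genomeEquivalents",
           function(object) standardGeneric("genomeEquivalents"))

#' @rdname alloTCR-generics
#' @export
setGeneric("uniqueProductiveClonotypes",
           function(object) standardGeneric("uniqueProductiveClonotypes"))

#' Per-clone frequencies of a sample
#'
#' Frequencies are template counts divided by the productive template total,
#' over productive clones only; they sum to 1.
#'
#' @param object a \linkS4class{RepertoireSample} with
#'   \code{totalTemplates(object) > 0}.
#' @return named numeric vector (names are rearrangement keys).
#' @examples
#' s <- exampleSample(c(a = 10, b = 30))
#' cloneFrequencies(s)   # a 0.25, b 0.75
#' @export
setGeneric("cloneFrequencies",
           function(object) standardGeneric("cloneFrequencies"))

#' @rdname alloTCR-generics
#' @export
setGeneric("drtcClones", function(object) standardGeneric("drtcClones"))

#' @rdname alloTCR-generics
#' @export
setGeneric("drtcResults", function(object) standardGeneric("drtcResults"))

#' @rdname alloTCR-generics
#' @export
setGeneric("drtcParameters", function(object) standardGeneric("drtcParameters"))
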