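#' @title Generics for coamag classes
#' @description Accessor generics shared across the package's S4
#'   classes. Each has methods documented on the class pages.
#' @param x a coamag object
#' @param ... passed to methods
#' @name coamag-generics
NULL

#' @rdname coamag-generics
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname coamag-generics
#' @export
setGeneric("kmerSize", function(x, ...) standardGeneric("kmerSize"))

#' @rdname coamag-generics
#' @export
setGeneric("kmerCounts", function(x, ...) standardGeneric("kmerCounts"))

#' @rdname coamag-generics
#' @export
setGeneric("profileTotal", function(x, ...) standardGeneric("profileTotal"))

#' @rdname coamag-generics
#' @export
setGeneric("distMetric", function(x, ...) standardGeneric("distMetric"))

#' @rdname coamag-generics
#' @export
setGeneric("nLeaves", function(x, ...) standardGeneric("nLeaves"))

#' @rdname coamag-generics
#' @export
setGeneric("mergeSteps", function(x, ...) standardGeneric("mergeSteps"))

#' @rdname coamag-generics
#' @export
setGeneric("silhouetteCurve", function(x, ...) standardGeneric("silhouetteCurve"))

#' @rdname coamag-generics
#' @export
setGeneric("optimalK", function(x, ...) standardGeneric("optimalK"))

#' @rdname coamag-generics
#' @export
setGeneric("suboptimalK", function(x, ...) standardGeneric("suboptimalK"))

#' @rdname coamag-generics
#' @export
setGeneric("labelsAt", function(x, k, ...) standardGeneric("labelsAt"))

#' @rdname coamag-generics
#' @export
setGeneric("sampleGroups", function(x, ...) standardGeneric("sampleGroups"))

#' @rdname coamag-generics
#' @export
setGeneric("sourceK", function(x, ...) standardGeneric("sourceK"))

#' @rdname coamag-generics
#' @export
setGeneric("assemblyUnits", function(x, ...) standardGeneric("assemblyUnits"))

#' @rdname coamag-generics
#' @export
setGeneric("mappingJobs", function(x, ...) standardGeneric("mappingJobs"))

#' @rdname coamag-generics
#' @export
setGeneric("strategyName", function(x, ...) standardGeneric("strategyName"))

#' @rdname coamag-generics
#' @export
setGeneric("contigInfo", function(x, ...) standardGeneric("contigInfo"))

#' @rdname coamag-generics
#' @export
setGeneric("meanDepths", function(x, ...) standardGeneric("meanDepths"))

#' @rdname coamag-generics
#' @export
setGeneric("depthVariances", function(x, ...) standardGeneric("depthVariances"))

#' @rdname coamag-generics
#' @export
setGeneric("derepClusters", function(x, ...) standardGeneric("derepClusters"))

#' @rdname coamag-generics
#' @export
setGeneric("representatives", function(x, ...) standardGeneric("representatives"))

#' @rdname coamag-generics
#' @export
setGeneric("aniTable", function(x, ...) standardGeneric("aniTable"))

#' @rdname coamag-generics
#' @export
setGeneric("aniThreshold", function(x, ...) standardGeneric("aniThreshold"))

#' @rdname coamag-generics
#' @export
setGeneric("readOrigin", function(x, ...) standardGeneric("readOrigin"))

#' @rdname coamag-generics
#' @export
setGeneric("genomeAbundances", function(x, ...) standardGeneric("genomeAbundances"))
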