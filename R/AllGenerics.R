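#' @rdname CaptureDataset-class
#' @param x,object a `CaptureDataset` (or other package object as documented).
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("nOccasions", function(x) standardGeneric("nOccasions"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("nAgeClasses", function(x) standardGeneric("nAgeClasses"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("captureHistories", function(x) standardGeneric("captureHistories"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("firstCapture", function(x) standardGeneric("firstCapture"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("occasionLabels", function(x) standardGeneric("occasionLabels"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("indSex", function(x) standardGeneric("indSex"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("indSite", function(x) standardGeneric("indSite"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("ageAtFirst", function(x) standardGeneric("ageAtFirst"))

#' @rdname CaptureDataset-class
#' @export
setGeneric("effortMask", function(x) standardGeneric("effortMask"))

#' @rdname ClassCounts-class
#' @param x a `ClassCounts` object.
#' @export
setGeneric("totalCaptures", function(x) standardGeneric("totalCaptures"))

#' @rdname ClassCounts-class
#' @export
setGeneric("unmarkedCaptures", function(x) standardGeneric("unmarkedCaptures"))

#' @rdname PosteriorResult-class
#' @param x a fitted object.
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

#' @rdname PosteriorResult-class
#' @export
setGeneric("rhatValues", function(x) standardGeneric("rhatValues"))

#' @rdname PosteriorResult-class
#' @export
setGeneric("pointwiseLoglik", function(x) standardGeneric("pointwiseLoglik"))

#' @rdname PosteriorResult-class
#' @export
setGeneric("posteriorDraws", function(x, pars = NULL) standardGeneric("posteriorDraws"))

#' @rdname ModelComparison-class
#' @param x a `ModelComparison` object.
#' @export
setGeneric("comparisonTable", function(x) standardGeneric("comparisonTable"))

#' @rdname AdjustedSurvival-class
#' @param x an `AdjustedSurvival` object.
#' @export
setGeneric("adjustmentTable", function(x) standardGeneric("adjustmentTable"))

#' @rdname PPCResult-class
#' @param x a `PPCResult` object.
#' @export
setGeneric("bayesianP", function(x) standardGeneric("bayesianP"))
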