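#' @rdname ProbeSet-accessors
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))

#' @rdname ProbeSet-accessors
#' @export
setGeneric("probeRatios", function(x) standardGeneric("probeRatios"))

#' @rdname ProbeSet-accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))

#' @rdname ProbeSet-accessors
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' @rdname ProbeSet-accessors
#' @export
setGeneric("probeMidpoints", function(x) standardGeneric("probeMidpoints"))

#' @rdname KSProfile-accessors
#' @export
setGeneric("scoreRanges", function(x) standardGeneric("scoreRanges"))

#' @rdname KSProfile-accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname normalizeCenter
#' @export
setGeneric("normalizeCenter",
  function(x, method = c("median", "biweight")) standardGeneric("normalizeCenter"))
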