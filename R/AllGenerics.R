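#' @rdname frameRate
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname frameCount
#' @export
setGeneric("frameCount", function(x) standardGeneric("frameCount"))

#' @rdname gapRuns
#' @export
setGeneric("gapRuns", function(x) standardGeneric("gapRuns"))

#' @rdname scaleFactors
#' @export
setGeneric("scaleX", function(x) standardGeneric("scaleX"))

#' @rdname scaleFactors
#' @export
setGeneric("scaleY", function(x) standardGeneric("scaleY"))
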