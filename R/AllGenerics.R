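## Accessor generics for the core containers. Slot access from user code
## should go through these.

#' Accessors for sonocrack objects
#'
#' @param object a sonocrack S4 object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("recordLabel", function(object) standardGeneric("recordLabel"))

#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))

#' @rdname accessors
#' @export
setGeneric("centerFrequencies",
           function(object) standardGeneric("centerFrequencies"))

#' @rdname accessors
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("modeValues", function(object) standardGeneric("modeValues"))

#' @rdname accessors
#' @export
setGeneric("pixelValues", function(object) standardGeneric("pixelValues"))

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))

#' @rdname accessors
setMethod("sampleId", "UltrasoundRecord", function(object) object@sampleId)

#' @rdname accessors
setMethod("amplitudes", "UltrasoundRecord", function(object) object@amplitudes)

#' @rdname accessors
setMethod("recordLabel", "UltrasoundRecord", function(object) object@label)

#' @rdname accessors
setMethod("recordLabel", "EncodedImage", function(object) object@label)

#' @rdname accessors
setMethod("modes", "VMDResult", function(object) object@modes)

#' @rdname accessors
setMethod("centerFrequencies", "VMDResult", function(object) object@omegas)

#' @rdname accessors
setMethod("iterations", "VMDResult", function(object) object@iterations)

#' @rdname accessors
setMethod("isConverged", "VMDResult", function(object) object@converged)

#' @rdname accessors
setMethod("modeValues", "ModeMatrix", function(object) object@S)

#' @rdname accessors
setMethod("pixelValues", "EncodedImage", function(object) object@pixels)

#' @rdname accessors
setMethod("metricsTable", "Metrics", function(object) {
  data.frame(tp = object@tp, fp = object@fp, fn = object@fn, tn = object@tn,
             precision = object@precision, recall = object@recall,
             f1 = object@f1, accuracy = object@accuracy)
})
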