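#' Number of learnable parameters
#'
#' Exact count of learnable scalars. Works on a built model or on any nested
#' list of weight arrays (handy for closed-form checks on single layers).
#'
#' @param object a `DermViTModel` or a nested list of numeric arrays.
#' @return integer-valued numeric, total number of scalars.
#' @examples
#' countParameters(list(W = matrix(0, 4, 3), b = numeric(3))) # 15
#' @export
setGeneric("countParameters", function(object) standardGeneric("countParameters"))

#' @rdname countParameters
#' @export
setMethod("countParameters", "list", function(object) .nParams(object))

#' Multiply-accumulate count of one forward pass
#'
#' @param model a `DermViTModel`.
#' @param inputShape length-3 integer vector (channels, height, width);
#'   defaults to the model's configured input.
#' @return numeric MAC count (the usual 1 MAC = 1 FLOP convention).
#' @export
setGeneric("countMacs", function(model, inputShape = NULL) standardGeneric("countMacs"))

#' @rdname metricsAccessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname metricsAccessors
#' @export
setGeneric("mauc", function(object) standardGeneric("mauc"))

#' @rdname metricsAccessors
#' @export
setGeneric("macroF1", function(object) standardGeneric("macroF1"))

#' @rdname metricsAccessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' Accessors for MetricsReport
#'
#' @param object a `MetricsReport`.
#' @return the requested component: a scalar for `accuracy`, `mauc`,
#'   `macroF1`; the truth-by-prediction matrix for `confusion`.
#' @name metricsAccessors
NULL

#' @rdname metricsAccessors
#' @export
setMethod("accuracy", "MetricsReport", function(object) object@accuracy)

#' @rdname metricsAccessors
#' @export
setMethod("mauc", "MetricsReport", function(object) object@mauc)

#' @rdname metricsAccessors
#' @export
setMethod("macroF1", "MetricsReport", function(object) object@macroF1)

#' @rdname metricsAccessors
#' @export
setMethod("confusion", "MetricsReport", function(object) object@confusion)

#' @rdname classLabels
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' Class labels of a dataset
#'
#' @param object a `SyntheticDermData`.
#' @return for `classLabels`, the integer label vector (1-based); names give
#'   the class name of each image.
#' @name classLabels
#' @export
setMethod("classLabels", "SyntheticDermData", function(object) {
  stats::setNames(object@labels, object@classNames[object@labels])
})

#' Configuration of a model
#'
#' @param object a `DermViTModel`.
#' @return the embedded `DermViTConfig`.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "DermViTModel", function(object) object@config)
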