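#' Accessors for dkmseg result objects
#'
#' Slot access goes through these accessors, never through `@`.
#'
#' @param object a dkmseg S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname accessors
#' @export
setGeneric("labelData", function(object) standardGeneric("labelData"))

#' @rdname accessors
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignment",
           function(object) standardGeneric("clusterAssignment"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace",
           function(object) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))

#' @rdname accessors
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @rdname accessors
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))

#' @rdname accessors
#' @export
setGeneric("phantomSpec", function(object) standardGeneric("phantomSpec"))

#' @rdname accessors
#' @export
setGeneric("reportErrorRate",
           function(object) standardGeneric("reportErrorRate"))

#' @rdname accessors
#' @export
setGeneric("confusionMatrix",
           function(object) standardGeneric("confusionMatrix"))

#' @rdname accessors
#' @export
setMethod("pixelData", "GrayImage", function(object) object@.Data)

#' @rdname accessors
setMethod("pixelData", "Phantom", function(object) object@image@.Data)

#' @rdname accessors
setMethod("labelData", "LabelImage", function(object) object@.Data)

#' @rdname accessors
setMethod("centers", "ClusterModel", function(object) object@centers)

#' @rdname accessors
setMethod("clusterAssignment", "ClusterModel",
          function(object) object@assignment)

#' @rdname accessors
setMethod("clusterAssignment", "MeanShiftResult",
          function(object) object@assignment)

#' @rdname accessors
setMethod("objectiveTrace", "ClusterModel",
          function(object) object@objectiveTrace)

#' @rdname accessors
setMethod("modes", "MeanShiftResult", function(object) object@modes)

#' @rdname accessors
setMethod("truthLabels", "Phantom", function(object) object@truth)

#' @rdname accessors
setMethod("phantomImage", "Phantom", function(object) object@image)

#' @rdname accessors
setMethod("phantomSpec", "Phantom", function(object) object@spec)

#' @rdname accessors
setMethod("reportErrorRate", "EvalReport", function(object) object@errorRate)

#' @rdname accessors
setMethod("confusionMatrix", "EvalReport", function(object) object@confusion)
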