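#' @include utils.R
NULL

#' Accessors for scProto classes
#'
#' Small accessor generics used across the package: covariate and annotation
#' bookkeeping on [ExpressionDataset] objects, and component access on
#' [ProtoModel] and [PrototypeSet] objects.
#'
#' @param x An object.
#' @param ... Further arguments passed to methods.
#' @return See the individual methods.
#' @name scProto-accessors
#' @aliases covariateKeys annotationKeys unlabeledToken librarySize
#'   covariateValues annotationValues embeddingMatrix conditionLevels
#'   modelConfig trainingReport cellPrototypes latentDim prototypeLevel
#'   labeledPrototypes unlabeledPrototypes
NULL

#' @rdname scProto-accessors
#' @export
setGeneric("covariateKeys", function(x) standardGeneric("covariateKeys"))

#' @rdname scProto-accessors
#' @export
setGeneric("annotationKeys", function(x) standardGeneric("annotationKeys"))

#' @rdname scProto-accessors
#' @export
setGeneric("unlabeledToken", function(x) standardGeneric("unlabeledToken"))

#' @rdname scProto-accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname scProto-accessors
#' @export
setGeneric("covariateValues", function(x, key) standardGeneric("covariateValues"))

#' @rdname scProto-accessors
#' @export
setGeneric("annotationValues", function(x, key) standardGeneric("annotationValues"))

#' @rdname scProto-accessors
#' @export
setGeneric("embeddingMatrix", function(x, covariate) standardGeneric("embeddingMatrix"))

#' @rdname scProto-accessors
#' @export
setGeneric("conditionLevels", function(x, covariate) standardGeneric("conditionLevels"))

#' @rdname scProto-accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname scProto-accessors
#' @export
setGeneric("trainingReport", function(x) standardGeneric("trainingReport"))

#' @rdname scProto-accessors
#' @export
setGeneric("cellPrototypes", function(x, level) standardGeneric("cellPrototypes"))

#' @rdname scProto-accessors
#' @export
setGeneric("latentDim", function(x) standardGeneric("latentDim"))

#' @rdname scProto-accessors
#' @export
setGeneric("prototypeLevel", function(x) standardGeneric("prototypeLevel"))

#' @rdname scProto-accessors
#' @export
setGeneric("labeledPrototypes", function(x) standardGeneric("labeledPrototypes"))

#' @rdname scProto-accessors
#' @export
setGeneric("unlabeledPrototypes", function(x) standardGeneric("unlabeledPrototypes"))
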