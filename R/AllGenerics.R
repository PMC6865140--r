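#' @rdname variantKeys
#' @export
setGeneric("variantKeys", function(x, ...) standardGeneric("variantKeys"))

#' @rdname cohortPanel-accessors
#' @export
setGeneric("panelLabel", function(x) standardGeneric("panelLabel"))

#' @rdname cohortPanel-accessors
#' @export
setGeneric("panelLabel<-", function(x, value) standardGeneric("panelLabel<-"))

#' @rdname cohortPanel-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname cohortPanel-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname screenReport-accessors
#' @export
setGeneric("nSurvivors", function(x) standardGeneric("nSurvivors"))

#' @rdname screenReport-accessors
#' @export
setGeneric("removedByStage", function(x) standardGeneric("removedByStage"))

#' @rdname screenReport-accessors
#' @export
setGeneric("surviving", function(x) standardGeneric("surviving"))
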