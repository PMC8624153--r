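#' @rdname adhesionParams
#' @export
setGeneric("nTypes", function(x) standardGeneric("nTypes"))

#' @rdname adhesionParams
#' @export
setGeneric("betaMatrix", function(x) standardGeneric("betaMatrix"))

#' @rdname adhesionParams
#' @export
setGeneric("betaVector", function(x) standardGeneric("betaVector"))

#' @rdname systemParams
#' @export
setGeneric("scalingParam", function(params) standardGeneric("scalingParam"))

#' @rdname systemParams
#' @export
setGeneric("effectiveAdhesion",
           function(params) standardGeneric("effectiveAdhesion"))

#' @rdname systemParams
#' @export
setGeneric("convergenceSpeed",
           function(params, ...) standardGeneric("convergenceSpeed"))

#' @rdname systemParams
#' @export
setGeneric("symmetricProjection",
           function(params) standardGeneric("symmetricProjection"))

#' @rdname totalHomotypic
#' @export
setGeneric("totalHomotypic", function(config) standardGeneric("totalHomotypic"))

#' @rdname lattice-accessors
#' @export
setGeneric("latticeSide", function(x) standardGeneric("latticeSide"))

#' @rdname lattice-accessors
#' @export
setGeneric("latticeTypes", function(x) standardGeneric("latticeTypes"))

#' @rdname lattice-accessors
#' @export
setGeneric("typeCounts", function(x) standardGeneric("typeCounts"))
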