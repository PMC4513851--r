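## Accessor generics. Slot access from user code goes through these.

#' Accessors for pullQuant S4 objects
#'
#' @param object a \linkS4class{GroundTruth}, \linkS4class{RunQuant},
#'   \linkS4class{AbundanceTable}, \linkS4class{FilterReport} or
#'   \linkS4class{CompositionSummary}.
#'
#' @return \code{quantTable} and \code{abundance} return the underlying
#'   data.frame; \code{runId}, \code{runRole}, \code{baitId} return
#'   character scalars; \code{stoichiometry}, \code{contaminants},
#'   \code{filterCounts} and \code{meanPercent} return named numerics;
#'   \code{proteome} and \code{perRunPercent} return data.frames.
#'
#' @examples
#' gt <- eif3GroundTruth(seed = 1)
#' baitId(gt)
#' head(proteome(gt))
#' stoichiometry(gt)
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("quantTable", function(object) standardGeneric("quantTable"))
#' @rdname accessors
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))
#' @rdname accessors
#' @export
setGeneric("runRole", function(object) standardGeneric("runRole"))
#' @rdname accessors
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))
#' @rdname accessors
#' @export
setGeneric("baitId", function(object) standardGeneric("baitId"))
#' @rdname accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))
#' @rdname accessors
#' @export
setGeneric("contaminants", function(object) standardGeneric("contaminants"))
#' @rdname accessors
#' @export
setGeneric("proteome", function(object) standardGeneric("proteome"))
#' @rdname accessors
#' @export
setGeneric("filterCounts", function(object) standardGeneric("filterCounts"))
#' @rdname accessors
#' @export
setGeneric("meanPercent", function(object) standardGeneric("meanPercent"))
#' @rdname accessors
#' @export
setGeneric("perRunPercent", function(object) standardGeneric("perRunPercent"))

#' @rdname accessors
#' @export
setMethod("quantTable", "RunQuant", function(object) object@quant)
#' @rdname accessors
#' @export
setMethod("runId", "RunQuant", function(object) object@runId)
#' @rdname accessors
#' @export
setMethod("runRole", "RunQuant", function(object) object@role)
#' @rdname accessors
#' @export
setMethod("abundance", "AbundanceTable", function(object) object@table)
#' @rdname accessors
#' @export
setMethod("baitId", "AbundanceTable", function(object) object@baitId)
#' @rdname accessors
#' @export
setMethod("baitId", "GroundTruth", function(object) object@baitId)
#' @rdname accessors
#' @export
setMethod("stoichiometry", "GroundTruth", function(object)
  object@stoichiometry)
#' @rdname accessors
#' @export
setMethod("contaminants", "GroundTruth", function(object)
  object@contaminants)
#' @rdname accessors
#' @export
setMethod("proteome", "GroundTruth", function(object) object@proteome)
#' @rdname accessors
#' @export
setMethod("filterCounts", "FilterReport", function(object) object@counts)
#' @rdname accessors
#' @export
setMethod("meanPercent", "CompositionSummary", function(object)
  object@meanPercent)
#' @rdname accessors
#' @export
setMethod("perRunPercent", "CompositionSummary", function(object)
  object@perRun)
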