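#' Accessor generics
#'
#' Small accessor generics for the S4 result classes; use these rather than
#' reaching into slots.
#'
#' @param object An object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("categories", function(object) standardGeneric("categories"))
#' @rdname accessors
#' @export
setGeneric("occupancies", function(object) standardGeneric("occupancies"))
#' @rdname accessors
#' @export
setGeneric("totalSize", function(object) standardGeneric("totalSize"))
#' @rdname accessors
#' @export
setGeneric("canonicalParams",
           function(object) standardGeneric("canonicalParams"))
#' @rdname accessors
#' @export
setGeneric("support", function(object) standardGeneric("support"))
#' @rdname accessors
#' @export
setGeneric("probMass", function(object) standardGeneric("probMass"))
#' @rdname accessors
#' @export
setGeneric("ccdf", function(object) standardGeneric("ccdf"))
#' @rdname accessors
#' @export
setGeneric("multiplicities",
           function(object) standardGeneric("multiplicities"))
#' @rdname accessors
#' @export
setGeneric("groupCounts", function(object) standardGeneric("groupCounts"))
#' @rdname accessors
#' @export
setGeneric("slope", function(object) standardGeneric("slope"))
#' @rdname accessors
#' @export
setGeneric("adjustedR2", function(object) standardGeneric("adjustedR2"))
#' @rdname accessors
#' @export
setGeneric("fitRange", function(object) standardGeneric("fitRange"))
#' @rdname accessors
#' @export
setGeneric("exponent", function(object) standardGeneric("exponent"))
#' @rdname accessors
#' @export
setGeneric("xmin", function(object) standardGeneric("xmin"))
#' @rdname accessors
#' @export
setGeneric("ksStatistic", function(object) standardGeneric("ksStatistic"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(object) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setMethod("categories", "OccupancyPrediction",
          function(object) object@categories)
#' @rdname accessors
#' @export
setMethod("occupancies", "OccupancyPrediction",
          function(object) object@occupancies)
#' @rdname accessors
#' @export
setMethod("totalSize", "OccupancyPrediction", function(object) object@total)
#' @rdname accessors
#' @export
setMethod("canonicalParams", "OccupancyPrediction",
          function(object) object@params)
#' @rdname accessors
#' @export
setMethod("support", "EmpiricalDistribution", function(object) object@support)
#' @rdname accessors
#' @export
setMethod("probMass", "EmpiricalDistribution", function(object) object@pmf)
#' @rdname accessors
#' @export
setMethod("ccdf", "EmpiricalDistribution", function(object) object@ccdf)
#' @rdname accessors
#' @export
setMethod("multiplicities", "MultiplicityTable",
          function(object) object@multiplicity)
#' @rdname accessors
#' @export
setMethod("groupCounts", "MultiplicityTable", function(object) object@nGroups)
#' @rdname accessors
#' @export
setMethod("slope", "OLSFit", function(object) object@slope)
#' @rdname accessors
#' @export
setMethod("adjustedR2", "OLSFit", function(object) object@adjustedR2)
#' @rdname accessors
#' @export
setMethod("fitRange", "OLSFit", function(object) object@fitRange)
#' @rdname accessors
#' @export
setMethod("exponent", "PowerLawFit", function(object) object@exponent)
#' @rdname accessors
#' @export
setMethod("xmin", "PowerLawFit", function(object) object@xmin)
#' @rdname accessors
#' @export
setMethod("ksStatistic", "PowerLawFit", function(object) object@ksD)
#' @rdname accessors
#' @export
setMethod("pValue", "BootstrapResult", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("verdict", "PowerLawVerdict", function(object) object@verdict)
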