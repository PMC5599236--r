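#' Accessors for TEmimic classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("expectation", function(x) standardGeneric("expectation"))
#' @rdname accessors
#' @export
setGeneric("mimicryClass", function(x) standardGeneric("mimicryClass"))
#' @rdname accessors
#' @export
setGeneric("centralDefects", function(x) standardGeneric("centralDefects"))
#' @rdname accessors
#' @export
setGeneric("duplex", function(x) standardGeneric("duplex"))
#' @rdname accessors
#' @export
setGeneric("siteStart", function(x) standardGeneric("siteStart"))
#' @rdname accessors
#' @export
setGeneric("siteEnd", function(x) standardGeneric("siteEnd"))
#' @rdname accessors
#' @export
setGeneric("alignmentStates", function(x) standardGeneric("alignmentStates"))
#' @rdname accessors
#' @export
setGeneric("ageYears", function(x) standardGeneric("ageYears"))
#' @rdname accessors
#' @export
setGeneric("divergence", function(x) standardGeneric("divergence"))
#' @rdname accessors
#' @export
setGeneric("supportsCleavage", function(x) standardGeneric("supportsCleavage"))
#' @rdname accessors
#' @export
setGeneric("cleavageCategory", function(x) standardGeneric("cleavageCategory"))

#' @rdname accessors
#' @export
setMethod("expectation", "DuplexAlignment", function(x) x@expectation)
#' @rdname accessors
#' @export
setMethod("expectation", "TargetSite", function(x) x@duplex@expectation)
#' @rdname accessors
#' @export
setMethod("mimicryClass", "TargetSite", function(x) x@mimicryClass)
#' @rdname accessors
#' @export
setMethod("centralDefects", "TargetSite", function(x) x@centralDefects)
#' @rdname accessors
#' @export
setMethod("duplex", "TargetSite", function(x) x@duplex)
#' @rdname accessors
#' @export
setMethod("siteStart", "DuplexAlignment", function(x) x@siteStart)
#' @rdname accessors
#' @export
setMethod("siteStart", "TargetSite", function(x) x@duplex@siteStart)
#' @rdname accessors
#' @export
setMethod("siteEnd", "DuplexAlignment", function(x) x@siteEnd)
#' @rdname accessors
#' @export
setMethod("siteEnd", "TargetSite", function(x) x@duplex@siteEnd)
#' @rdname accessors
#' @export
setMethod("alignmentStates", "DuplexAlignment", function(x)
  setNames(x@states, x@positions))
#' @rdname accessors
#' @export
setMethod("alignmentStates", "TargetSite", function(x)
  alignmentStates(x@duplex))
#' @rdname accessors
#' @export
setMethod("ageYears", "LTRAgeEstimate", function(x) x@age)
#' @rdname accessors
#' @export
setMethod("divergence", "LTRAgeEstimate", function(x) x@D)
#' @rdname accessors
#' @export
setMethod("supportsCleavage", "CleavageCall", function(x) x@supportsCleavage)
#' @rdname accessors
#' @export
setMethod("cleavageCategory", "CleavageCall", function(x) x@category)
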