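#' Accessors for package classes
#'
#' `reads()` returns the `GRanges` of alignments of an [SncLibrary-class];
#' `totalMapped()` the pre-filter library depth; `tissue()` the sample
#' label; `overlapCounts()` the zero-filled `n_k` vector of an
#' [OverlapHistogram-class]; `zscores()` the `z_k` vector of a
#' [ZScoreProfile-class].
#'
#' @param x an object of the documented class.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname accessors
#' @export
setMethod("reads", "SncLibrary", function(x) x@reads)

#' @rdname accessors
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))

#' @rdname accessors
#' @export
setMethod("totalMapped", "SncLibrary", function(x) x@totalMapped)

#' @rdname accessors
#' @export
setGeneric("tissue", function(x) standardGeneric("tissue"))

#' @rdname accessors
#' @export
setMethod("tissue", "SncLibrary", function(x) x@tissue)

#' @rdname accessors
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))

#' @rdname accessors
#' @export
setMethod("overlapCounts", "OverlapHistogram", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname accessors
#' @export
setMethod("zscores", "ZScoreProfile", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setMethod("isDegenerate", "ZScoreProfile", function(x) x@degenerate)

#' @rdname zscoreProfile
#' @export
setGeneric("zscoreProfile", function(x) standardGeneric("zscoreProfile"))
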