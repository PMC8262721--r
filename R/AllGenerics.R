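#' Accessors for coregmap classes
#'
#' `pairTable()` returns the pair-level statistics of a [CorrelationSet];
#' `corMethod()` the correlation method; `featureUniverse()` every feature
#' that entered the analysis. `refName()`, `refPairs()` and `refComplexes()`
#' access a [ReferenceSet]. `nodeTable()` and `edgeTable()` access a
#' [MultiOmicGraph]; `chromOffsets()` the cumulative offsets of a
#' [GenomeLayout].
#'
#' @param x an object of the documented class.
#' @return The slot contents as plain base-R objects (data.frame, character
#'   or named numeric).
#' @name accessors
#' @examples
#' m <- matrix(rnorm(40), nrow = 4,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:10)))
#' cs <- correlateAllPairs(m, method = "pearson")
#' head(pairTable(cs))
#' corMethod(cs)
NULL

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("corMethod", function(x) standardGeneric("corMethod"))

#' @rdname accessors
#' @export
setGeneric("featureUniverse", function(x) standardGeneric("featureUniverse"))

#' @rdname accessors
#' @export
setGeneric("refName", function(x) standardGeneric("refName"))

#' @rdname accessors
#' @export
setGeneric("refPairs", function(x) standardGeneric("refPairs"))

#' @rdname accessors
#' @export
setGeneric("refComplexes", function(x) standardGeneric("refComplexes"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("chromOffsets", function(x) standardGeneric("chromOffsets"))

#' @rdname accessors
setMethod("pairTable", "CorrelationSet", function(x) x@pairs)

#' @rdname accessors
setMethod("corMethod", "CorrelationSet", function(x) x@method)

#' @rdname accessors
setMethod("featureUniverse", "CorrelationSet", function(x) x@features)

#' @rdname accessors
setMethod("refName", "ReferenceSet", function(x) x@name)

#' @rdname accessors
setMethod("refPairs", "ReferenceSet", function(x) x@pairs)

#' @rdname accessors
setMethod("refComplexes", "ReferenceSet", function(x) x@complexes)

#' @rdname accessors
setMethod("nodeTable", "MultiOmicGraph", function(x) x@nodes)

#' @rdname accessors
setMethod("edgeTable", "MultiOmicGraph", function(x) x@edges)

#' @rdname accessors
setMethod("chromOffsets", "GenomeLayout", function(x) x@offsets)

setMethod("show", "CorrelationSet", function(object) {
  cat("CorrelationSet (", object@method, ")\n", sep = "")
  cat("  features:", length(object@features), "\n")
  cat("  pairs:   ", nrow(object@pairs),
      " (skipped for low n_obs: ", object@nSkippedLowN, ")\n", sep = "")
  if (nrow(object@pairs)) {
    cat("  |r| range: [",
        sprintf("%.3f", min(abs(object@pairs$r), na.rm = TRUE)), ", ",
        sprintf("%.3f", max(abs(object@pairs$r), na.rm = TRUE)), "]\n", sep = "")
  }
  if ("db_flags" %in% names(object@pairs)) {
    cat("  annotated against references:",
        sum(nzchar(object@pairs$db_flags)), "pairs flagged\n")
  }
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet '", object@name, "'\n", sep = "")
  cat("  pairs:", nrow(object@pairs))
  if ("score" %in% names(object@pairs) && nrow(object@pairs) &&
      !all(is.na(object@pairs$score))) cat(" (scored)")
  cat("\n")
  if (length(object@complexes)) {
    cat("  complexes:", length(object@complexes),
        "(sizes", paste(range(lengths(object@complexes)), collapse = "-"), ")\n")
  }
})

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", length(object@chroms), "chromosomes, padding",
      object@padding, "\n")
  cat("  order:", paste(utils::head(object@chroms, 8), collapse = ", "),
      if (length(object@chroms) > 8) "..." else "", "\n")
})

setMethod("show", "MultiOmicGraph", function(object) {
  cat("MultiOmicGraph\n")
  nd <- table(object@nodes$type)
  cat("  nodes:", nrow(object@nodes),
      paste0("(", paste(names(nd), nd, sep = ":", collapse = ", "), ")"), "\n")
  if (nrow(object@edges)) {
    ed <- table(object@edges$type)
    cat("  edges:", nrow(object@edges),
        paste0("(", paste(names(ed), ed, sep = ":", collapse = ", "), ")"),
        "| total multiplicity:", sum(object@edges$multiplicity), "\n")
  } else cat("  edges: 0\n")
})
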