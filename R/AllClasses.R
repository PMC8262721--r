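#' @import methods
NULL

#' CorrelationSet: all-pairs co-regulation results
#'
#' Holds the full table of unordered feature pairs produced by
#' [correlateAllPairs()], together with the correlation method used, the
#' complete feature universe (so zero-connectivity features are not lost)
#' and bookkeeping counts (pairs skipped for too few pairwise-complete
#' observations).
#'
#' The pair table has columns `feature_a`, `feature_b` (gene symbols stored
#' with `feature_a < feature_b`), `r`, `p`, `q`, `n_obs`, and — after
#' [annotatePairs()] — `db_flags` and `complex_ids` (semicolon-joined).
#'
#' @slot pairs data.frame of pair statistics.
#' @slot method character(1), one of `"pearson"`, `"spearman"`, `"bicor"`.
#' @slot features character vector of all features entering the analysis.
#' @slot nSkippedLowN integer(1), pairs dropped for `n_obs < min_obs`.
#'
#' @aliases CorrelationSet
#' @exportClass CorrelationSet
setClass("CorrelationSet",
  representation(
    pairs = "data.frame",
    method = "character",
    features = "character",
    nSkippedLowN = "integer"
  ),
  prototype(
    pairs = data.frame(),
    method = "pearson",
    features = character(),
    nSkippedLowN = 0L
  )
)

setValidity("CorrelationSet", function(object) {
  p <- object@pairs
  need <- c("feature_a", "feature_b", "r", "p", "q", "n_obs")
  if (!all(need %in% names(p))) {
    return(paste("pair table must contain columns:", paste(need, collapse = ", ")))
  }
  if (nrow(p)) {
    if (any(p$feature_a >= p$feature_b)) {
      return("pairs must be stored with feature_a < feature_b")
    }
    ok_r <- is.na(p$r) | abs(p$r) <= 1 + 1e-12
    if (!all(ok_r)) return("|r| must not exceed 1")
    ok_p <- is.na(p$p) | (p$p >= 0 & p$p <= 1)
    if (!all(ok_p)) return("p-values must lie in [0, 1]")
    if (any(p$n_obs < 3L)) return("n_obs must be at least 3 for every pair")
    if (!all(c(p$feature_a, p$feature_b) %in% object@features)) {
      return("pair members must belong to the feature universe")
    }
  }
  if (!object@method %in% c("pearson", "spearman", "bicor")) {
    return("method must be pearson, spearman or bicor")
  }
  TRUE
})

#' ReferenceSet: a protein-interaction or protein-complex reference
#'
#' Canonical container for interaction references (scored or unscored pair
#' lists in the style of STRING/BioPlex extracts) and complex-style
#' references (CORUM-like member lists, expanded to all within-complex
#' pairs). Pairs are stored canonically with `member_a < member_b`; self
#' pairs are disallowed.
#'
#' @slot name character(1) reference name used as the db flag.
#' @slot pairs data.frame with `member_a`, `member_b` and optional `score`.
#' @slot complexes named list of character member vectors (may be empty for
#'   pairwise references).
#'
#' @aliases ReferenceSet
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    name = "character",
    pairs = "data.frame",
    complexes = "list"
  ),
  prototype(name = "reference", pairs = data.frame(), complexes = list())
)

setValidity("ReferenceSet", function(object) {
  p <- object@pairs
  if (!all(c("member_a", "member_b") %in% names(p))) {
    return("pairs must have member_a and member_b columns")
  }
  if (nrow(p)) {
    if (any(p$member_a == p$member_b)) return("self-pairs are not allowed")
    if (any(p$member_a >= p$member_b)) {
      return("pairs must be stored canonically with member_a < member_b")
    }
    if (anyDuplicated(paste(p$member_a, p$member_b, sep = "\r"))) {
      return("duplicate pairs are not allowed")
    }
  }
  if (length(object@complexes) && is.null(names(object@complexes))) {
    return("complexes must be a named list")
  }
  TRUE
})

#' GenomeLayout: cumulative coordinates for genome-wide plots
#'
#' Maps per-chromosome positions onto a single cumulative axis (the layout
#' used for Manhattan plots). Chromosomes are ordered numerically, then
#' X, Y, MT, then lexicographically; each chromosome's offset is the prefix
#' sum of the preceding extents plus inter-chromosome padding.
#'
#' @slot chroms ordered character vector of chromosome labels.
#' @slot extents named numeric, per-chromosome extent.
#' @slot offsets named numeric, cumulative offset per chromosome
#'   (offset of the first chromosome is 0).
#' @slot padding numeric(1) gap inserted between chromosomes.
#'
#' @aliases GenomeLayout
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(
    chroms = "character",
    extents = "numeric",
    offsets = "numeric",
    padding = "numeric"
  )
)

setValidity("GenomeLayout", function(object) {
  if (!length(object@chroms)) return("at least one chromosome required")
  if (!identical(names(object@offsets), object@chroms) ||
      !identical(names(object@extents), object@chroms)) {
    return("extents and offsets must be named by chroms, in order")
  }
  if (object@offsets[[1]] != 0) return("offset of the first chromosome must be 0")
  if (length(object@offsets) > 1 && any(diff(object@offsets) <= 0)) {
    return("offsets must be strictly increasing in chromosome order")
  }
  if (object@padding < 0) return("padding must be non-negative")
  TRUE
})

#' MultiOmicGraph: typed nodes and annotated, typed edges
#'
#' Graph of `snp`, `feature`, `trait`, `ld_block` and `chromosome` nodes
#' joined by `coregulation` (feature–feature), `qtl` (snp–feature) and
#' `trait_assoc` (snp–trait) edges. Edges carry type-specific annotations
#' and a multiplicity (>= 1) that accumulates when SNP nodes are collapsed
#' into LD-block or chromosome nodes.
#'
#' @slot nodes data.frame with `id`, `type`, `label` and (for SNP nodes)
#'   `chrom`, `pos`.
#' @slot edges data.frame with `from`, `to`, `type`, `multiplicity` and the
#'   per-type annotation columns (`r`, `q`, `db_flags`, `proxy`,
#'   `consequence`, `impact`, `significance`).
#'
#' @aliases MultiOmicGraph
#' @exportClass MultiOmicGraph
setClass("MultiOmicGraph",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("MultiOmicGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("id", "type", "label") %in% names(nd))) {
    return("nodes need id, type and label columns")
  }
  if (anyDuplicated(nd$id)) return("node ids must be unique")
  bad_type <- setdiff(nd$type, c("snp", "feature", "trait", "ld_block", "chromosome"))
  if (length(bad_type)) return(paste("unknown node type:", bad_type[1]))
  if (nrow(ed)) {
    if (!all(c("from", "to", "type", "multiplicity") %in% names(ed))) {
      return("edges need from, to, type and multiplicity columns")
    }
    if (!all(c(ed$from, ed$to) %in% nd$id)) return("edge endpoints must exist")
    if (any(ed$from == ed$to)) return("self-edges are not allowed")
    if (any(ed$multiplicity < 1)) return("edge multiplicity must be >= 1")
    bad_et <- setdiff(ed$type, c("coregulation", "qtl", "trait_assoc"))
    if (length(bad_et)) return(paste("unknown edge type:", bad_et[1]))
  }
  TRUE
})
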