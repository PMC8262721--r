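#' Keep the top score percentile of a scored pair reference
#'
#' Pairs are stably sorted by score, largest first, and the top
#' `ceil(N * percentile / 100)` pairs are retained — the rule used to
#' restrict large affinity-purification interaction catalogues to their
#' highest-confidence decile (e.g. 11,817 of 118,162 pairs at the 10th
#' percentile). Ties at the boundary keep earlier-listed pairs.
#'
#' @param ref a scored [ReferenceSet] (every pair must have a score).
#' @param percentile in (0, 100].
#' @return a [ReferenceSet] with the retained pairs.
#' @export
filterTopPercentile <- function(ref, percentile = 10) {
  stopifnot(percentile > 0, percentile <= 100)
  p <- refPairs(ref)
  if (!nrow(p)) stop("empty reference")
  if (!"score" %in% names(p) || anyNA(p$score)) {
    stop("reference is not fully scored; top-percentile filter undefined")
  }
  k <- ceiling(nrow(p) * percentile / 100)
  ord <- order(-p$score)        # stable: ties keep file order
  keep <- sort(ord[seq_len(k)])
  methods::new("ReferenceSet", name = refName(ref),
               pairs = p[keep, , drop = FALSE], complexes = refComplexes(ref))
}

#' Flag correlation pairs found in reference databases
#'
#' Each pair's `db_flags` column lists (semicolon-joined) every reference
#' that contains it; complex-style references additionally record the
#' complex id(s) in `complex_ids` (a pair belongs to a complex iff both
#' members do). No pairs are added or removed.
#'
#' @param cs a [CorrelationSet].
#' @param references list of [ReferenceSet] objects.
#' @return the annotated [CorrelationSet].
#' @export
annotatePairs <- function(cs, references) {
  if (is(references, "ReferenceSet")) references <- list(references)
  p <- cs@pairs
  key <- .pair_key(p$feature_a, p$feature_b)
  flags <- vector("list", nrow(p))
  cplx <- vector("list", nrow(p))
  for (ref in references) {
    rp <- refPairs(ref)
    hit <- key %in% .pair_key(rp$member_a, rp$member_b)
    flags[hit] <- lapply(flags[hit], c, refName(ref))
    comps <- refComplexes(ref)
    if (length(comps)) {
      for (cn in names(comps)) {
        members <- comps[[cn]]
        in_c <- p$feature_a %in% members & p$feature_b %in% members
        cplx[in_c] <- lapply(cplx[in_c], c, cn)
      }
    }
  }
  p$db_flags <- vapply(flags, function(f) paste(unique(f), collapse = ";"), "")
  p$complex_ids <- vapply(cplx, function(f) paste(unique(f), collapse = ";"), "")
  methods::new("CorrelationSet", pairs = p, method = cs@method,
               features = cs@features, nSkippedLowN = cs@nSkippedLowN)
}

# ancestor closure of one term under an acyclic parent map (memoised by
# the caller); errors on cycles
.ancestors <- function(term, parents, seen = character()) {
  if (term %in% seen) stop("cycle detected in ontology parents at term '", term, "'")
  direct <- parents[[term]]
  if (is.null(direct)) return(character())
  out <- direct
  for (d in direct) out <- c(out, .ancestors(d, parents, c(seen, term)))
  unique(out)
}

#' Propagate localisation terms to their ontology ancestors
#'
#' Replaces each feature's compartment set by its transitive-ancestor
#' closure union itself, so that a feature annotated to a specific
#' substructure (say a nuclear speck, with parents nucleoplasm and then
#' nucleus) is also counted in every enclosing compartment. Idempotent;
#' errors if the parent map contains a cycle.
#'
#' @param table a `LocalizationTable` from [readLocalizations()].
#' @return the propagated `LocalizationTable`.
#' @export
propagateLocalizations <- function(table) {
  stopifnot(inherits(table, "LocalizationTable"))
  parents <- table$parents
  cache <- new.env(parent = emptyenv())
  closure <- function(term) {
    if (!is.null(cache[[term]])) return(cache[[term]])
    res <- sort(unique(c(term, .ancestors(term, parents))))
    cache[[term]] <- res
    res
  }
  table$loc <- lapply(table$loc, function(terms) {
    sort(unique(unlist(lapply(terms, closure))))
  })
  table$propagated <- TRUE
  table
}

#' Do two features share a subcellular compartment?
#'
#' TRUE iff the features' propagated compartment sets intersect. Features
#' without any annotation count as "different compartment" (FALSE), not
#' unknown.
#'
#' @param a,b feature names.
#' @param table a propagated `LocalizationTable` (propagated on the fly if
#'   not already).
#' @return logical(1).
#' @export
sameCompartment <- function(a, b, table) {
  if (!isTRUE(table$propagated)) table <- propagateLocalizations(table)
  sa <- table$loc[[a]]; sb <- table$loc[[b]]
  if (is.null(sa) || is.null(sb)) return(FALSE)
  length(intersect(sa, sb)) > 0
}

#' Look up known drug interactions for features
#'
#' @param features character feature (gene) names.
#' @param dgiTable data.frame `gene, drug` from [readDrugTable()].
#' @return named list feature -> character vector of drugs (table order
#'   preserved; empty for features without interactions).
#' @export
annotateDrugTargets <- function(features, dgiTable) {
  out <- lapply(features, function(g) dgiTable$drug[dgiTable$gene == g])
  names(out) <- features
  out
}

#' Enrichment of reference membership among correlated pairs
#'
#' Builds the 2x2 table of correlated (`|r| >= rCut` and `q <= qCut`)
#' versus in-reference over all pairs and tests independence with the
#' Pearson chi-squared statistic (1 df, no continuity correction). A
#' warning is issued when any expected count falls below 5.
#' `overlap_fraction` is the in-reference share among correlated pairs.
#'
#' @param cs an annotated [CorrelationSet] (see [annotatePairs()]).
#' @param ref the [ReferenceSet] (or its name) tested against.
#' @param rCut,qCut correlation and q-value cutoffs.
#' @return one-row data.frame: `reference, r_cut, q_cut, n_corr_in,
#'   n_corr_out, n_uncorr_in, n_uncorr_out, chi2, p, overlap_fraction,
#'   degenerate`.
#' @export
overlapChisq <- function(cs, ref, rCut, qCut) {
  name <- if (is(ref, "ReferenceSet")) refName(ref) else as.character(ref)
  p <- cs@pairs
  if (!"db_flags" %in% names(p)) stop("pairs not annotated; run annotatePairs() first")
  correlated <- abs(p$r) >= rCut & p$q <= qCut
  in_ref <- vapply(strsplit(p$db_flags, ";", fixed = TRUE),
                   function(f) name %in% f, logical(1))
  tab <- matrix(c(sum(correlated & in_ref), sum(correlated & !in_ref),
                  sum(!correlated & in_ref), sum(!correlated & !in_ref)),
                nrow = 2, byrow = TRUE)
  res <- data.frame(reference = name, r_cut = rCut, q_cut = qCut,
                    n_corr_in = tab[1, 1], n_corr_out = tab[1, 2],
                    n_uncorr_in = tab[2, 1], n_uncorr_out = tab[2, 2],
                    chi2 = NA_real_, p = NA_real_,
                    overlap_fraction = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  n_corr <- sum(correlated)
  if (n_corr > 0) res$overlap_fraction <- tab[1, 1] / n_corr
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margin: a row or column of the 2x2 table is empty")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected count < 5 in the 2x2 table; chi-squared approximation may be poor")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res$chi2 <- unname(ct$statistic)
  res$p <- unname(ct$p.value)
  res
}

#' Cutoff sensitivity grid for reference enrichment
#'
#' Evaluates [overlapChisq()] over a grid of correlation and q-value
#' cutoffs for each reference — by default 9 correlation cutoffs (0.1 to
#' 0.9) by 8 q-value cutoffs, 72 combinations, so that the dependence of
#' reference overlap on the chosen thresholds can be inspected before
#' fixing them. Degenerate cells (e.g. no pair passes the cutoffs) are
#' flagged, not fatal.
#'
#' @param cs an annotated [CorrelationSet].
#' @param references list of [ReferenceSet] objects (or one).
#' @param rCuts,qCuts cutoff grids.
#' @return data.frame with one row per (reference, r_cut, q_cut).
#' @export
sensitivityGrid <- function(cs, references,
                            rCuts = seq(0.1, 0.9, by = 0.1),
                            qCuts = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.25, 1)) {
  if (is(references, "ReferenceSet")) references <- list(references)
  rows <- list()
  for (ref in references) {
    for (rc in rCuts) for (qc in qCuts) {
      row <- tryCatch(
        suppressWarnings(overlapChisq(cs, ref, rc, qc)),
        error = function(e) {
          data.frame(reference = refName(ref), r_cut = rc, q_cut = qc,
                     n_corr_in = NA_integer_, n_corr_out = NA_integer_,
                     n_uncorr_in = NA_integer_, n_uncorr_out = NA_integer_,
                     chi2 = NA_real_, p = NA_real_,
                     overlap_fraction = NA_real_, degenerate = TRUE,
                     stringsAsFactors = FALSE)
        })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
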