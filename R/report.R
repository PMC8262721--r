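#' Plot-ready Manhattan table
#'
#' One row per QTL record with its cumulative genomic position and plot
#' y-value: `-log10(significance)` for p-values (p = 0 clamped to `pFloor`
#' first so the axis stays finite) or the raw score for LOD. Row count
#' equals the input record count.
#'
#' @param qtl QTL data.frame (optionally annotated/classified).
#' @param layout a [GenomeLayout] covering the records' chromosomes.
#' @param pFloor clamp for zero p-values (default 1e-300).
#' @return data.frame `rsid, chrom, pos, cumulative_pos, y, proxy, impact`.
#' @export
manhattanTable <- function(qtl, layout, pFloor = 1e-300) {
  kind <- attr(qtl, "sigKind")
  if (is.null(kind)) kind <- .detect_sig_kind(qtl$significance)
  y <- if (kind == "pvalue") -log10(pmax(qtl$significance, pFloor))
       else qtl$significance
  data.frame(
    rsid = qtl$rsid, chrom = qtl$snp_chrom, pos = qtl$snp_pos,
    cumulative_pos = cumulativePosition(qtl$snp_chrom, qtl$snp_pos, layout),
    y = y,
    proxy = if ("computed_proxy" %in% names(qtl)) qtl$computed_proxy else qtl$proxy,
    impact = if ("impact" %in% names(qtl)) qtl$impact else "",
    stringsAsFactors = FALSE
  )
}

#' Ordering for complex arc diagrams
#'
#' Complexes are arranged by size, largest first (ties broken by complex
#' label ascending); within each complex, members are ordered by their
#' number of correlation partners passing the cutoffs, most first (ties
#' broken by member label ascending). Positions are consecutive integers,
#' unique across the whole arrangement.
#'
#' @param complexMap a complex-style [ReferenceSet].
#' @param cs a [CorrelationSet] supplying partner counts.
#' @param rCut,qCut cutoffs defining a correlated partner.
#' @return data.frame `complex_id, member, degree, position`, in diagram
#'   order.
#' @export
arcOrder <- function(complexMap, cs, rCut = 0, qCut = 1) {
  comps <- refComplexes(complexMap)
  if (!length(comps)) stop("complexMap has no complexes")
  deg <- connectivity(cs, rCut, qCut)
  degv <- stats::setNames(deg$n_partners, deg$feature)
  sizes <- lengths(comps)
  corder <- names(comps)[order(-sizes, names(comps))]
  rows <- lapply(corder, function(cn) {
    members <- comps[[cn]]
    d <- ifelse(is.na(degv[members]), 0L, degv[members])
    morder <- members[order(-d, members)]
    data.frame(complex_id = cn, member = morder,
               degree = as.integer(ifelse(is.na(degv[morder]), 0L, degv[morder])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Quality-control summary tables
#'
#' Count summaries backing the QC dashboards: features passing the
#' missing-value filter, features with a localisation annotation, features
#' with a known drug interaction; QTL counts by proxy, group, consequence
#' and impact; and histograms of correlation coefficients and q-values
#' (bin counts sum to the pair count).
#'
#' @param expression optional SummarizedExperiment/matrix before filtering.
#' @param filtered optional filtered object from [filterMissing()].
#' @param locTable optional `LocalizationTable`.
#' @param drugTable optional data.frame `gene, drug`.
#' @param qtl optional QTL data.frame.
#' @param cs optional [CorrelationSet].
#' @param breaks histogram breaks for correlation coefficients.
#' @return named list of data.frames: `features`, `qtl_counts`,
#'   `correlation_hist`, `qvalue_hist` (present where inputs were given).
#' @export
qcSummaries <- function(expression = NULL, filtered = NULL, locTable = NULL,
                        drugTable = NULL, qtl = NULL, cs = NULL,
                        breaks = seq(-1, 1, by = 0.1)) {
  out <- list()
  if (!is.null(expression) || !is.null(filtered)) {
    feats <- if (!is.null(filtered)) rownames(.as_exprs(filtered)) else
      rownames(.as_exprs(expression))
    n_in <- if (!is.null(expression)) nrow(.as_exprs(expression)) else NA_integer_
    n_loc <- if (!is.null(locTable)) sum(feats %in% names(locTable$loc)) else NA_integer_
    n_drug <- if (!is.null(drugTable)) sum(feats %in% unique(drugTable$gene)) else NA_integer_
    out$features <- data.frame(
      n_features_in = n_in, n_features_kept = length(feats),
      n_localized = n_loc, n_drug_annotated = n_drug)
  }
  if (!is.null(qtl)) {
    cnt <- function(col) {
      if (!col %in% names(qtl)) return(NULL)
      v <- qtl[[col]]
      v[!nzchar(v)] <- "(unannotated)"
      tb <- table(v)
      data.frame(dimension = col, level = names(tb), count = as.integer(tb),
                 stringsAsFactors = FALSE)
    }
    out$qtl_counts <- do.call(rbind, Filter(Negate(is.null), list(
      cnt("proxy"), cnt("computed_proxy"), cnt("group"),
      cnt("consequence"), cnt("impact"))))
    rownames(out$qtl_counts) <- NULL
  }
  if (!is.null(cs)) {
    p <- pairTable(cs)
    h <- graphics::hist(p$r, breaks = breaks, plot = FALSE)
    out$correlation_hist <- data.frame(bin_lo = utils::head(h$breaks, -1),
                                       bin_hi = h$breaks[-1], count = h$counts)
    hq <- graphics::hist(p$q, breaks = seq(0, 1, by = 0.05), plot = FALSE)
    out$qvalue_hist <- data.frame(bin_lo = utils::head(hq$breaks, -1),
                                  bin_hi = hq$breaks[-1], count = hq$counts)
  }
  out
}

#' Static figures
#'
#' ggplot2 figures for the standard views: Manhattan plot (cumulative
#' position vs significance, coloured by proxy), correlation-coefficient
#' histogram, per-feature connectivity distribution, and the sensitivity
#' grid (overlap fraction across cutoff combinations).
#'
#' @param mt Manhattan table from [manhattanTable()].
#' @return a ggplot object.
#' @export
plotManhattan <- function(mt) {
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$cumulative_pos, y = .data$y,
                                   colour = .data$proxy)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "cumulative genomic position", y = "-log10(p) / LOD") +
    ggplot2::theme_minimal()
}

#' @rdname plotManhattan
#' @param cs a [CorrelationSet].
#' @export
plotCorrelationHistogram <- function(cs) {
  ggplot2::ggplot(pairTable(cs), ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(breaks = seq(-1, 1, by = 0.05)) +
    ggplot2::labs(x = "correlation coefficient", y = "pairs") +
    ggplot2::theme_minimal()
}

#' @rdname plotManhattan
#' @param conn connectivity table from [connectivity()].
#' @export
plotConnectivity <- function(conn) {
  ggplot2::ggplot(conn, ggplot2::aes(x = .data$n_partners)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "correlated partners per feature", y = "features") +
    ggplot2::theme_minimal()
}

#' @rdname plotManhattan
#' @param grid sensitivity grid from [sensitivityGrid()].
#' @export
plotSensitivityGrid <- function(grid) {
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$r_cut, y = .data$overlap_fraction,
                               colour = factor(.data$q_cut))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~reference) +
    ggplot2::labs(x = "correlation cutoff", y = "fraction in reference",
                  colour = "q cutoff") +
    ggplot2::theme_minimal()
}

#' Export tables, figures and graphs with a manifest
#'
#' Tables (data.frames) are written as CSV, figures (ggplot objects) as
#' SVG and PDF, and [MultiOmicGraph] objects as GraphML plus node/edge
#' CSVs. The returned manifest lists every file with its row count (tables
#' and graph CSVs) for provenance checks; all outputs are deterministic
#' given identical inputs.
#'
#' @param outputs named list of data.frames, ggplot objects and/or
#'   [MultiOmicGraph] objects.
#' @param directory output directory (created if needed).
#' @param formats figure formats, subset of `c("svg", "pdf")`.
#' @return data.frame manifest: `name, file, kind, rows`.
#' @export
exportAll <- function(outputs, directory, formats = c("svg", "pdf")) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) stop("cannot create directory: ", directory)
  }
  if (file.access(directory, 2) != 0) stop("unwritable directory: ", directory)
  rows <- list()
  add <- function(name, file, kind, n = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, file = basename(file), kind = kind, rows = n,
      stringsAsFactors = FALSE)
  }
  for (name in names(outputs)) {
    obj <- outputs[[name]]
    if (is(obj, "MultiOmicGraph")) {
      files <- exportGraph(obj, file.path(directory, name))
      add(name, files[["graphml"]], "graphml")
      add(name, files[["nodes"]], "csv", nrow(nodeTable(obj)))
      add(name, files[["edges"]], "csv", nrow(edgeTable(obj)))
    } else if (inherits(obj, "ggplot")) {
      if ("svg" %in% formats) {
        f <- file.path(directory, paste0(name, ".svg"))
        grDevices::svg(f, width = 7, height = 5); print(obj); grDevices::dev.off()
        add(name, f, "svg")
      }
      if ("pdf" %in% formats) {
        f <- file.path(directory, paste0(name, ".pdf"))
        grDevices::pdf(f, width = 7, height = 5); print(obj); grDevices::dev.off()
        add(name, f, "pdf")
      }
    } else if (is.data.frame(obj)) {
      f <- file.path(directory, paste0(name, ".csv"))
      .write_csv(obj, f)
      add(name, f, "csv", nrow(obj))
    } else if (is(obj, "CorrelationSet")) {
      f <- file.path(directory, paste0(name, ".csv"))
      .write_csv(pairTable(obj), f)
      add(name, f, "csv", nrow(pairTable(obj)))
    } else {
      stop("cannot export object '", name, "' of class ", class(obj)[1])
    }
  }
  manifest <- do.call(rbind, rows)
  .write_csv(manifest, file.path(directory, "manifest.csv"))
  manifest
}
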