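#' Read a plain key=value pipeline config file
#'
#' One `key=value` per line; blank lines and `#` comments ignored. Later
#' duplicates override earlier ones. Values passed in `overrides` take
#' precedence over the file (the flags-override-config rule of the CLI).
#'
#' @param path config file path.
#' @param overrides named list/character of overriding values.
#' @return named list of character values.
#' @export
readConfig <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  cfg <- list()
  for (p in kv) if (length(p) == 2) cfg[[trimws(p[1])]] <- trimws(p[2])
  for (k in names(overrides)) cfg[[k]] <- as.character(overrides[[k]])
  cfg
}

.cfg_num <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) return(default)
  as.numeric(cfg[[key]])
}

.cfg_chr <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Run the full analysis pipeline from a config
#'
#' Orchestrates ingest -> missing-value handling -> all-pairs correlation
#' -> reference annotation and enrichment -> QTL filtering, cis/trans
#' classification and consequence annotation -> SNP co-mapping -> network
#' assembly -> table/figure/graph export, with per-stage count logging.
#' Any stage error aborts with a stage-tagged message. Outputs are a
#' deterministic function of (inputs, config, seed).
#'
#' Recognised config keys: `expression, qtl, traits, ld_blocks,
#' complex_reference, pair_reference, localizations,
#' localization_parents, drug_table, consequence_lookup, mapping_table,
#' output_dir, method, adjust, max_missing, impute, min_obs, r_cut,
#' q_cut, sig_cut, cis_window, top_percentile, collapse, seed`.
#'
#' @param config path to a key=value config file, or a named list.
#' @param overrides named values overriding the config file.
#' @return list with `status` (0 on success), `manifest` (export
#'   manifest), `counts` (per-stage record counts) and the main in-memory
#'   results (`cs`, `qtl`, `comappings`, `graph`).
#' @export
runPipeline <- function(config, overrides = list()) {
  cfg <- if (is.list(config)) utils::modifyList(config, as.list(overrides))
         else readConfig(config, overrides)
  counts <- list()
  seed <- .cfg_num(cfg, "seed", 1)

  # -- ingest ----------------------------------------------------------
  stage <- "ingest"
  res <- tryCatch({
    if (is.null(cfg$expression)) stop("config key 'expression' is required")
    se <- readExpressionMatrix(cfg$expression,
                               mappingTable = .cfg_chr(cfg, "mapping_table"))
    qtl <- if (!is.null(cfg$qtl)) readQTLTable(cfg$qtl) else NULL
    traits <- if (!is.null(cfg$traits)) readTraitTable(cfg$traits) else NULL
    ld <- if (!is.null(cfg$ld_blocks)) readLDBlocks(cfg$ld_blocks) else NULL
    refs <- list()
    if (!is.null(cfg$complex_reference)) {
      refs$complexdb <- readComplexReference(cfg$complex_reference, "complexdb")
    }
    if (!is.null(cfg$pair_reference)) {
      pr <- readPairReference(cfg$pair_reference, "interactiondb")
      top <- .cfg_num(cfg, "top_percentile")
      if (!is.null(top)) pr <- filterTopPercentile(pr, top)
      refs$interactiondb <- pr
    }
    loc <- if (!is.null(cfg$localizations)) {
      readLocalizations(cfg$localizations,
                        .cfg_chr(cfg, "localization_parents"))
    } else NULL
    drugs <- if (!is.null(cfg$drug_table)) readDrugTable(cfg$drug_table) else NULL
    lookup <- if (!is.null(cfg$consequence_lookup)) {
      readConsequenceLookup(cfg$consequence_lookup)
    } else NULL
    list(se = se, qtl = qtl, traits = traits, ld = ld, refs = refs,
         loc = loc, drugs = drugs, lookup = lookup)
  }, error = function(e) .stop_stage(stage, e))
  counts$features_in <- nrow(res$se)
  counts$qtl_rows <- if (is.null(res$qtl)) 0L else nrow(res$qtl)
  counts$trait_rows <- if (is.null(res$traits)) 0L else nrow(res$traits)
  .msg("[ingest] %d features, %d qtl rows, %d trait rows",
       counts$features_in, counts$qtl_rows, counts$trait_rows)

  # -- co-regulation ---------------------------------------------------
  stage <- "coreg"
  cs <- tryCatch({
    se <- filterMissing(res$se, .cfg_num(cfg, "max_missing", 0.5))
    se <- imputeMissing(se, .cfg_chr(cfg, "impute", "none"), seed = seed)
    correlateAllPairs(se, method = .cfg_chr(cfg, "method", "pearson"),
                      minObs = .cfg_num(cfg, "min_obs", 3),
                      adjust = .cfg_chr(cfg, "adjust", "bh"))
  }, error = function(e) .stop_stage(stage, e))
  counts$features_corr <- length(featureUniverse(cs))
  counts$pairs <- nrow(pairTable(cs))
  .msg("[coreg] %d features -> %d pairs (%s)", counts$features_corr,
       counts$pairs, corMethod(cs))

  # -- annotation ------------------------------------------------------
  stage <- "annotate"
  grid <- NULL
  tryCatch({
    if (length(res$refs)) {
      cs <- annotatePairs(cs, res$refs)
      grid <- sensitivityGrid(cs, res$refs)
    }
    if (!is.null(res$loc)) res$loc <- propagateLocalizations(res$loc)
  }, error = function(e) .stop_stage(stage, e))
  counts$flagged_pairs <- if ("db_flags" %in% names(pairTable(cs))) {
    sum(nzchar(pairTable(cs)$db_flags))
  } else 0L
  .msg("[annotate] %d pairs flagged in references", counts$flagged_pairs)

  # -- qtl -------------------------------------------------------------
  stage <- "qtl"
  qtl <- res$qtl; layout <- NULL
  tryCatch({
    if (!is.null(qtl)) {
      sig_cut <- .cfg_num(cfg, "sig_cut")
      if (!is.null(sig_cut)) qtl <- filterQTL(qtl, cut = sig_cut)
      qtl <- classifyCisTrans(qtl, window = .cfg_num(cfg, "cis_window", 1e6))
      if (!is.null(res$lookup)) {
        qtl <- suppressWarnings(annotateVariantConsequences(qtl, res$lookup))
      }
      layout <- buildGenomeLayout(qtl)
    }
  }, error = function(e) .stop_stage(stage, e))
  counts$qtl_kept <- if (is.null(qtl)) 0L else nrow(qtl)
  .msg("[qtl] %d records after filtering/annotation", counts$qtl_kept)

  # -- integration -----------------------------------------------------
  stage <- "integrate"
  cm <- NULL; graph <- NULL
  tryCatch({
    if (!is.null(qtl) && !is.null(res$traits)) cm <- comap(qtl, res$traits)
    kept <- filterPairs(cs, .cfg_num(cfg, "r_cut", 0.5),
                        .cfg_num(cfg, "q_cut", 0.05))
    graph <- buildGraph(pairs = kept, qtls = qtl, comappings = cm)
    collapse <- .cfg_chr(cfg, "collapse")
    if (!is.null(collapse)) {
      graph <- collapseNodes(graph, collapse, ldBlocks = res$ld)
    }
  }, error = function(e) .stop_stage(stage, e))
  counts$comappings <- if (is.null(cm)) 0L else nrow(cm)
  counts$graph_nodes <- nrow(nodeTable(graph))
  counts$graph_edges <- nrow(edgeTable(graph))
  .msg("[integrate] %d co-mappings; graph %d nodes / %d edges",
       counts$comappings, counts$graph_nodes, counts$graph_edges)

  # -- report ----------------------------------------------------------
  stage <- "report"
  manifest <- NULL
  outdir <- .cfg_chr(cfg, "output_dir")
  if (!is.null(outdir)) {
    manifest <- tryCatch({
      outputs <- list(pair_table = cs, connectivity = connectivity(
        cs, .cfg_num(cfg, "r_cut", 0.5), .cfg_num(cfg, "q_cut", 0.05)),
        network = graph)
      qc <- qcSummaries(expression = res$se, filtered = NULL,
                        locTable = res$loc, drugTable = res$drugs,
                        qtl = qtl, cs = cs)
      for (nm in names(qc)) outputs[[paste0("qc_", nm)]] <- qc[[nm]]
      if (!is.null(grid)) outputs$sensitivity_grid <- grid
      if (!is.null(qtl)) {
        mt <- manhattanTable(qtl, layout)
        outputs$manhattan <- mt
        outputs$fig_manhattan <- plotManhattan(mt)
      }
      if (!is.null(cm)) outputs$comappings <- cm
      outputs$fig_correlation_hist <- plotCorrelationHistogram(cs)
      exportAll(outputs, outdir)
    }, error = function(e) .stop_stage(stage, e))
    .msg("[report] %d files written to %s", nrow(manifest), outdir)
  }

  list(status = 0L, manifest = manifest, counts = counts, cs = cs,
       qtl = qtl, comappings = cm, graph = graph)
}
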