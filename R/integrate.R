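#' Co-map QTLs and trait associations via shared rsIDs
#'
#' Exact inner join on rsID: one output row per (QTL row, trait row) pair
#' sharing an rsID, so an rsID with `a` QTL rows and `b` trait rows
#' contributes `a * b` co-mappings. An empty join is allowed.
#'
#' @param qtl QTL data.frame (optionally consequence-annotated).
#' @param traits trait-association data.frame.
#' @return data.frame `rsid, gene, trait, qtl_significance,
#'   trait_significance, proxy, impact, snp_chrom, snp_pos`.
#' @export
comap <- function(qtl, traits) {
  q <- data.frame(rsid = qtl$rsid, gene = qtl$gene,
                  qtl_significance = qtl$significance,
                  proxy = qtl$proxy,
                  impact = if ("impact" %in% names(qtl)) qtl$impact else "",
                  consequence = if ("consequence" %in% names(qtl)) qtl$consequence else "",
                  snp_chrom = qtl$snp_chrom, snp_pos = qtl$snp_pos,
                  stringsAsFactors = FALSE)
  t <- data.frame(rsid = traits$rsid, trait = traits$trait,
                  trait_significance = traits$significance,
                  stringsAsFactors = FALSE)
  out <- merge(q, t, by = "rsid", sort = FALSE)
  out <- out[order(out$rsid, out$gene, out$trait), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("rsid", "gene", "trait", "qtl_significance", "trait_significance",
          "proxy", "impact", "consequence", "snp_chrom", "snp_pos")]
}

.empty_nodes <- function() {
  data.frame(id = character(), type = character(), label = character(),
             chrom = character(), pos = numeric(), stringsAsFactors = FALSE)
}

.empty_edges <- function() {
  data.frame(from = character(), to = character(), type = character(),
             multiplicity = integer(), r = numeric(), q = numeric(),
             db_flags = character(), proxy = character(),
             consequence = character(), impact = character(),
             significance = numeric(), stringsAsFactors = FALSE)
}

.node_row <- function(type, label, chrom = NA_character_, pos = NA_real_) {
  data.frame(id = paste(type, label, sep = ":"), type = type, label = label,
             chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

.edge_row <- function(from, to, type, multiplicity = 1L, r = NA_real_,
                      q = NA_real_, db_flags = NA_character_,
                      proxy = NA_character_, consequence = NA_character_,
                      impact = NA_character_, significance = NA_real_) {
  blank2na <- function(x) { x[!is.na(x) & !nzchar(x)] <- NA_character_; x }
  proxy <- blank2na(proxy); consequence <- blank2na(consequence)
  impact <- blank2na(impact)
  data.frame(from = from, to = to, type = type,
             multiplicity = as.integer(multiplicity), r = r, q = q,
             db_flags = db_flags, proxy = proxy, consequence = consequence,
             impact = impact, significance = significance,
             stringsAsFactors = FALSE)
}

#' Assemble the multi-omic network
#'
#' Builds a typed graph from any combination of the three layers: feature
#' nodes from correlation pairs and QTL genes, SNP nodes from QTL records
#' and co-mappings, trait nodes from co-mappings; edges are
#' `coregulation` (feature–feature, carrying r/q and db flags), `qtl`
#' (snp–feature, carrying proxy/consequence/impact/significance) and
#' `trait_assoc` (snp–trait, carrying significance). Inputs are assumed to
#' be pre-filtered to the caller's cutoffs.
#'
#' @param pairs optional [CorrelationSet] (use [filterPairs()] first).
#' @param qtls optional QTL data.frame.
#' @param comappings optional co-mapping data.frame from [comap()].
#' @return a [MultiOmicGraph].
#' @export
buildGraph <- function(pairs = NULL, qtls = NULL, comappings = NULL) {
  nodes <- list(); edges <- list()
  if (!is.null(pairs)) {
    pt <- if (is(pairs, "CorrelationSet")) pairTable(pairs) else pairs
    if (nrow(pt)) {
      nodes[[length(nodes) + 1L]] <-
        .node_row("feature", unique(c(pt$feature_a, pt$feature_b)))
      edges[[length(edges) + 1L]] <- .edge_row(
        from = paste0("feature:", pt$feature_a),
        to = paste0("feature:", pt$feature_b),
        type = "coregulation", r = pt$r, q = pt$q,
        db_flags = if ("db_flags" %in% names(pt)) pt$db_flags else NA_character_)
    }
  }
  if (!is.null(qtls) && nrow(qtls)) {
    nodes[[length(nodes) + 1L]] <- .node_row("feature", unique(qtls$gene))
    snp_first <- !duplicated(qtls$rsid)
    nodes[[length(nodes) + 1L]] <- .node_row(
      "snp", qtls$rsid[snp_first],
      chrom = qtls$snp_chrom[snp_first], pos = qtls$snp_pos[snp_first])
    edges[[length(edges) + 1L]] <- .edge_row(
      from = paste0("snp:", qtls$rsid), to = paste0("feature:", qtls$gene),
      type = "qtl",
      proxy = if ("computed_proxy" %in% names(qtls)) qtls$computed_proxy else qtls$proxy,
      consequence = if ("consequence" %in% names(qtls)) qtls$consequence else NA_character_,
      impact = if ("impact" %in% names(qtls)) qtls$impact else NA_character_,
      significance = qtls$significance)
  }
  if (!is.null(comappings) && nrow(comappings)) {
    cm <- comappings
    nodes[[length(nodes) + 1L]] <- .node_row("feature", unique(cm$gene))
    snp_first <- !duplicated(cm$rsid)
    nodes[[length(nodes) + 1L]] <- .node_row(
      "snp", cm$rsid[snp_first],
      chrom = cm$snp_chrom[snp_first], pos = cm$snp_pos[snp_first])
    nodes[[length(nodes) + 1L]] <- .node_row("trait", unique(cm$trait))
    edges[[length(edges) + 1L]] <- .edge_row(
      from = paste0("snp:", cm$rsid), to = paste0("feature:", cm$gene),
      type = "qtl", proxy = cm$proxy, consequence = cm$consequence,
      impact = cm$impact, significance = cm$qtl_significance)
    edges[[length(edges) + 1L]] <- .edge_row(
      from = paste0("snp:", cm$rsid), to = paste0("trait:", cm$trait),
      type = "trait_assoc", significance = cm$trait_significance)
  }
  nd <- do.call(rbind, c(list(.empty_nodes()), nodes))
  nd <- nd[!duplicated(nd$id), , drop = FALSE]
  ed <- do.call(rbind, c(list(.empty_edges()), edges))
  # identical records contributed twice (e.g. a qtl row repeated through a
  # comapping) are deduplicated, distinct parallel records are kept
  ed <- ed[!duplicated(ed), , drop = FALSE]
  rownames(nd) <- rownames(ed) <- NULL
  methods::new("MultiOmicGraph", nodes = nd, edges = ed)
}

# induced subgraph on a set of node ids
.induce <- function(g, ids) {
  nd <- g@nodes[g@nodes$id %in% ids, , drop = FALSE]
  ed <- g@edges[g@edges$from %in% ids & g@edges$to %in% ids, , drop = FALSE]
  rownames(nd) <- rownames(ed) <- NULL
  methods::new("MultiOmicGraph", nodes = nd, edges = ed)
}

.neighbors <- function(g, ids) {
  e <- g@edges
  unique(c(e$to[e$from %in% ids], e$from[e$to %in% ids]))
}

#' Bait-centred subgraph
#'
#' Extracts the induced subgraph around a bait of interest:
#' * `gene` — the feature node plus its direct neighbours (all edge
#'   types);
#' * `complex` — all member features of the complex present in the graph,
#'   plus their SNP/trait neighbours and the traits reached through those
#'   SNPs;
#' * `trait` — the trait node, its SNPs, and those SNPs' features.
#'
#' @param g a [MultiOmicGraph].
#' @param bait gene name, complex id, or trait name.
#' @param baitKind `"gene"`, `"complex"` or `"trait"`.
#' @param complexMap a complex-style [ReferenceSet], required for
#'   `baitKind = "complex"`.
#' @return the induced [MultiOmicGraph]; always a subgraph of the input.
#' @export
baitSubgraph <- function(g, bait, baitKind = c("gene", "complex", "trait"),
                         complexMap = NULL) {
  baitKind <- match.arg(baitKind)
  if (baitKind == "gene") {
    id <- paste0("feature:", bait)
    if (!id %in% g@nodes$id) stop("bait gene '", bait, "' absent from graph")
    keep <- c(id, .neighbors(g, id))
  } else if (baitKind == "trait") {
    id <- paste0("trait:", bait)
    if (!id %in% g@nodes$id) stop("bait trait '", bait, "' absent from graph")
    snps <- intersect(.neighbors(g, id),
                      g@nodes$id[g@nodes$type == "snp"])
    feats <- intersect(.neighbors(g, snps),
                       g@nodes$id[g@nodes$type == "feature"])
    keep <- c(id, snps, feats)
  } else {
    if (is.null(complexMap)) stop("complex bait requires a complexMap ReferenceSet")
    members <- refComplexes(complexMap)[[bait]]
    if (is.null(members)) stop("complex '", bait, "' not in complexMap")
    ids <- intersect(paste0("feature:", members), g@nodes$id)
    if (!length(ids)) stop("no member of complex '", bait, "' present in graph")
    nb <- .neighbors(g, ids)
    st <- g@nodes$id[g@nodes$type %in% c("snp", "trait")]
    nb <- intersect(nb, c(st, ids))
    snps <- intersect(nb, g@nodes$id[g@nodes$type == "snp"])
    traits2 <- intersect(.neighbors(g, snps), g@nodes$id[g@nodes$type == "trait"])
    keep <- unique(c(ids, nb, traits2))
  }
  .induce(g, unique(keep))
}

#' Collapse SNP nodes into LD-block or chromosome nodes
#'
#' In `ld_block` mode each SNP whose position falls inside a block's
#' closed interval `[start, end]` on the matching chromosome is merged
#' into that block's node; SNPs outside every block remain individual
#' nodes. In `chromosome` mode every SNP merges into its chromosome node.
#' Parallel edges of the same type between the same endpoints are merged
#' with their multiplicities summed (total multiplicity is conserved);
#' edges of different types are never merged with each other. Annotation
#' values are kept where unanimous across merged edges and dropped (NA)
#' otherwise.
#'
#' @param g a [MultiOmicGraph].
#' @param mode `"ld_block"` or `"chromosome"`.
#' @param ldBlocks LD-block data.frame from [readLDBlocks()] (required for
#'   `ld_block` mode).
#' @return the collapsed [MultiOmicGraph].
#' @export
collapseNodes <- function(g, mode = c("ld_block", "chromosome"), ldBlocks = NULL) {
  mode <- match.arg(mode)
  nd <- g@nodes; ed <- g@edges
  snp <- nd$type == "snp"
  remap <- stats::setNames(nd$id, nd$id)
  new_nodes <- list()
  if (mode == "chromosome") {
    for (i in which(snp)) {
      ch <- nd$chrom[i]
      if (is.na(ch)) next
      nid <- paste0("chromosome:", ch)
      remap[nd$id[i]] <- nid
      new_nodes[[nid]] <- .node_row("chromosome", ch)
    }
  } else {
    if (is.null(ldBlocks)) stop("ld_block mode requires an LD-block table")
    for (i in which(snp)) {
      ch <- nd$chrom[i]; pos <- nd$pos[i]
      if (is.na(ch) || is.na(pos)) next
      b <- ldBlocks[ldBlocks$chrom == ch & ldBlocks$start <= pos &
                      ldBlocks$end >= pos, , drop = FALSE]
      if (!nrow(b)) next       # outside every block: keep the SNP node
      lab <- sprintf("%s:%s-%s", b$chrom[1],
                     format(b$start[1], scientific = FALSE, trim = TRUE),
                     format(b$end[1], scientific = FALSE, trim = TRUE))
      nid <- paste0("ld_block:", lab)
      remap[nd$id[i]] <- nid
      new_nodes[[nid]] <- .node_row("ld_block", lab, chrom = b$chrom[1])
    }
  }
  keep_nd <- nd[remap[nd$id] == nd$id, , drop = FALSE]
  nd2 <- rbind(keep_nd, do.call(rbind, c(list(.empty_nodes()), unname(new_nodes))))
  nd2 <- nd2[!duplicated(nd2$id), , drop = FALSE]
  if (nrow(ed)) {
    ed$from <- unname(remap[ed$from])
    ed$to <- unname(remap[ed$to])
    key <- paste(ed$from, ed$to, ed$type, sep = "\r")
    agg <- rowsum(ed$multiplicity, key)
    first <- ed[!duplicated(key), , drop = FALSE]
    kfirst <- paste(first$from, first$to, first$type, sep = "\r")
    first$multiplicity <- as.integer(agg[kfirst, 1])
    # blank out annotations that are not unanimous within a merged edge
    for (col in c("r", "q", "db_flags", "proxy", "consequence", "impact",
                  "significance")) {
      n_distinct <- vapply(split(ed[[col]], key),
                           function(v) length(unique(v)), integer(1))
      mixed <- n_distinct[kfirst] > 1
      first[[col]][mixed] <- if (is.numeric(first[[col]])) NA_real_ else NA_character_
    }
    ed <- first
  }
  rownames(nd2) <- rownames(ed) <- NULL
  methods::new("MultiOmicGraph", nodes = nd2, edges = ed)
}

.IMPACT_LEVELS <- c(MODIFIER = 1L, LOW = 2L, MODERATE = 3L, HIGH = 4L)

#' Filter a multi-omic graph
#'
#' Supported criteria:
#' * `reference_flag` — keep coregulation edges whose db flags contain
#'   `value` (other edge types are untouched);
#' * `compartment` — keep feature nodes whose propagated localisation
#'   contains the term `value` (requires `locTable`); non-feature nodes
#'   are kept subject to pruning;
#' * `impact_at_least` — keep qtl edges whose impact rating is at least
#'   `value` (MODIFIER < LOW < MODERATE < HIGH);
#' * `proxy` — keep qtl edges whose proxy equals `value`.
#'
#' After edge/node removal, isolated nodes are pruned, except a `bait`
#' node which is kept even when isolated.
#'
#' @param g a [MultiOmicGraph].
#' @param criterion one of the four names above.
#' @param value the criterion value (reference name, compartment term,
#'   impact rating, or proxy label).
#' @param locTable propagated `LocalizationTable` for `compartment`.
#' @param bait optional node id (e.g. `"feature:FGB"`) never pruned.
#' @return the filtered [MultiOmicGraph].
#' @export
filterGraph <- function(g, criterion = c("reference_flag", "compartment",
                                         "impact_at_least", "proxy"),
                        value, locTable = NULL, bait = NULL) {
  criterion <- match.arg(criterion)
  nd <- g@nodes; ed <- g@edges
  if (criterion == "reference_flag") {
    drop <- ed$type == "coregulation" &
      !vapply(strsplit(ifelse(is.na(ed$db_flags), "", ed$db_flags), ";", fixed = TRUE),
              function(f) value %in% f, logical(1))
    ed <- ed[!drop, , drop = FALSE]
  } else if (criterion == "impact_at_least") {
    lev <- .IMPACT_LEVELS[[value]]
    ei <- .IMPACT_LEVELS[ifelse(is.na(ed$impact), "", ed$impact)]
    drop <- ed$type == "qtl" & (is.na(ei) | ei < lev)
    ed <- ed[!drop, , drop = FALSE]
  } else if (criterion == "proxy") {
    drop <- ed$type == "qtl" &
      (is.na(ed$proxy) | ed$proxy != value)
    ed <- ed[!drop, , drop = FALSE]
  } else {
    if (is.null(locTable)) stop("compartment filter requires locTable")
    if (!isTRUE(locTable$propagated)) locTable <- propagateLocalizations(locTable)
    ok_feat <- vapply(nd$label, function(f) {
      s <- locTable$loc[[f]]
      !is.null(s) && value %in% s
    }, logical(1))
    drop_node <- nd$type == "feature" & !ok_feat
    kept_ids <- nd$id[!drop_node]
    nd <- nd[!drop_node, , drop = FALSE]
    ed <- ed[ed$from %in% kept_ids & ed$to %in% kept_ids, , drop = FALSE]
  }
  touched <- unique(c(ed$from, ed$to))
  keep_node <- nd$id %in% touched | nd$id %in% bait
  nd <- nd[keep_node, , drop = FALSE]
  ed <- ed[ed$from %in% nd$id & ed$to %in% nd$id, , drop = FALSE]
  rownames(nd) <- rownames(ed) <- NULL
  methods::new("MultiOmicGraph", nodes = nd, edges = ed)
}

#' Convert a MultiOmicGraph to an igraph object
#'
#' @param g a [MultiOmicGraph].
#' @return an undirected [igraph::igraph] with node/edge attributes.
#' @export
asIgraph <- function(g) {
  nd <- g@nodes
  ed <- g@edges
  for (col in names(ed)) if (is.character(ed[[col]])) ed[[col]][is.na(ed[[col]])] <- ""
  for (col in names(nd)) if (is.character(nd[[col]])) nd[[col]][is.na(nd[[col]])] <- ""
  igraph::graph_from_data_frame(
    d = ed[, c("from", "to", setdiff(names(ed), c("from", "to")))],
    directed = FALSE, vertices = nd)
}

#' Export a graph as GraphML plus node/edge CSVs
#'
#' @param g a [MultiOmicGraph].
#' @param basePath path prefix; writes `<basePath>.graphml`,
#'   `<basePath>_nodes.csv`, `<basePath>_edges.csv`.
#' @return invisibly, the written file paths.
#' @export
exportGraph <- function(g, basePath) {
  files <- c(graphml = paste0(basePath, ".graphml"),
             nodes = paste0(basePath, "_nodes.csv"),
             edges = paste0(basePath, "_edges.csv"))
  igraph::write_graph(asIgraph(g), files[["graphml"]], format = "graphml")
  .write_csv(g@nodes, files[["nodes"]])
  .write_csv(g@edges, files[["edges"]])
  invisible(files)
}
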