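set.seed(707)

test_that("co-mapping is an exact inner join on rsID with multiplicative
           cardinality", {
  q <- tiny_qtl()
  tr <- tiny_traits()
  cm <- comap(q, tr)
  expect_equal(nrow(cm), 2L)   # rs1 and rs4 shared; rs9 has no qtl
  expect_identical(cm$gene[cm$rsid == "rs1"], "G1")
  expect_identical(cm$trait[cm$rsid == "rs1"], "TraitA")

  expect_equal(nrow(comap(q, tr[tr$rsid == "rs9", , drop = FALSE])), 0L)

  # rsid with 2 qtl rows and 3 trait rows -> 6 triples
  q2 <- rbind(q[1, ], q[1, ]); q2$gene <- c("G1", "G9")
  tr2 <- tr[c(1, 1, 1), ]; tr2$trait <- c("T1", "T2", "T3")
  expect_equal(nrow(comap(q2, tr2)), 6L)

  # combinatorial identity sum_rsid |A| * |B| on random fixtures
  for (i in 1:10) {
    qa <- q[sample(5, 12, replace = TRUE), ]
    qa$rsid <- sample(paste0("rs", 1:6), 12, replace = TRUE)
    tb <- tr[sample(3, 9, replace = TRUE), ]
    tb$rsid <- sample(paste0("rs", 1:6), 9, replace = TRUE)
    expect_equal(nrow(comap(qa, tb)),
                 oracle_comap_count(qa$rsid, tb$rsid))
  }
})

make_graph_fixture <- function() {
  q <- tiny_qtl()
  q <- classifyCisTrans(q)
  q <- suppressWarnings(annotateVariantConsequences(
    q, data.frame(rsid = c("rs1", "rs4"),
                  consequence = c("stop_gained", "intron_variant"))))
  tr <- tiny_traits()
  cm <- comap(q, tr)
  m <- matrix(rnorm(5 * 20), nrow = 5, dimnames = list(paste0("G", 1:5), NULL))
  m[2, ] <- m[1, ] + rnorm(20, sd = 0.05)
  cs <- filterPairs(correlateAllPairs(m, "pearson"), 0.8, 0.05)
  list(q = q, tr = tr, cm = cm, cs = cs)
}

test_that("graph assembly creates typed nodes/edges matching set arithmetic", {
  fx <- make_graph_fixture()

  g_pairs <- buildGraph(pairs = fx$cs)
  expect_true(all(edgeTable(g_pairs)$type == "coregulation"))

  g1 <- buildGraph(qtls = fx$q[1, ], comappings = fx$cm[fx$cm$rsid == "rs1", ])
  et <- edgeTable(g1)
  expect_setequal(et$type, c("qtl", "trait_assoc"))
  expect_setequal(et$to, c("feature:G1", "trait:TraitA"))

  g <- buildGraph(pairs = fx$cs, qtls = fx$q, comappings = fx$cm)
  nd <- nodeTable(g); ed <- edgeTable(g)
  # node sets by set arithmetic on the inputs
  expect_setequal(nd$label[nd$type == "feature"],
                  unique(c(pairTable(fx$cs)$feature_a,
                           pairTable(fx$cs)$feature_b, fx$q$gene)))
  expect_setequal(nd$label[nd$type == "snp"],
                  unique(c(fx$q$rsid, fx$cm$rsid)))
  expect_setequal(nd$label[nd$type == "trait"], unique(fx$cm$trait))
  expect_equal(sum(ed$type == "coregulation"), nrow(pairTable(fx$cs)))
  expect_equal(sum(ed$type == "trait_assoc"), nrow(fx$cm))
  expect_false(any(ed$from == ed$to))
})

test_that("bait subgraphs honour the documented reach and stay subgraphs", {
  fx <- make_graph_fixture()
  g <- buildGraph(pairs = fx$cs, qtls = fx$q, comappings = fx$cm)

  sub <- baitSubgraph(g, "G1", "gene")
  nb <- unique(c(edgeTable(g)$to[edgeTable(g)$from == "feature:G1"],
                 edgeTable(g)$from[edgeTable(g)$to == "feature:G1"]))
  expect_setequal(nodeTable(sub)$id, c("feature:G1", nb))
  expect_true(all(nodeTable(sub)$id %in% nodeTable(g)$id))
  expect_true(all(paste(edgeTable(sub)$from, edgeTable(sub)$to) %in%
                    paste(edgeTable(g)$from, edgeTable(g)$to)))

  # trait bait: the trait, its snps, those snps' features (reachability oracle)
  subt <- baitSubgraph(g, "TraitA", "trait")
  ed <- edgeTable(g)
  snps <- unique(ed$from[ed$type == "trait_assoc" & ed$to == "trait:TraitA"])
  feats <- unique(ed$to[ed$type == "qtl" & ed$from %in% snps])
  expect_setequal(nodeTable(subt)$id, c("trait:TraitA", snps, feats))

  # complex bait: members plus snp/trait neighbours plus snp-mediated traits
  cmap <- readComplexReference(
    data.frame(complex_id = "CPX", member = c("G1", "G2")), "cdb")
  subc <- baitSubgraph(g, "CPX", "complex", complexMap = cmap)
  expect_true(all(c("feature:G1", "feature:G2") %in% nodeTable(subc)$id))
  expect_true("snp:rs1" %in% nodeTable(subc)$id)
  expect_true("trait:TraitA" %in% nodeTable(subc)$id)  # via rs1

  expect_error(baitSubgraph(g, "NotAGene", "gene"), "absent")
  # isolated bait -> single-node graph
  giso <- buildGraph(qtls = fx$q)
  sub1 <- baitSubgraph(giso, "G3", "gene")
  expect_gte(nrow(nodeTable(sub1)), 1L)
})

test_that("collapsing into LD blocks and chromosomes conserves multiplicity", {
  # 3 snps in one block, each linked to protein P -> multiplicity 3
  q <- data.frame(rsid = paste0("rs", 1:3), snp_chrom = "1",
                  snp_pos = c(100, 150, 200), gene = "P", gene_chrom = "1",
                  gene_start = 1e6, gene_end = 2e6, significance = 1e-8,
                  proxy = "trans")
  g <- buildGraph(qtls = q)
  ld <- data.frame(chrom = "1", start = 100, end = 300)
  gc <- collapseNodes(g, "ld_block", ld)
  ed <- edgeTable(gc)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$multiplicity, 3L)
  expect_identical(nodeTable(gc)$type[nodeTable(gc)$id == ed$from], "ld_block")

  # snp on the closed boundary belongs to the block; outside stays a snp
  q2 <- q; q2$snp_pos <- c(100, 300, 301)
  g2 <- collapseNodes(buildGraph(qtls = q2), "ld_block", ld)
  expect_true("snp:rs3" %in% nodeTable(g2)$id)
  expect_false("snp:rs2" %in% nodeTable(g2)$id)

  # conservation on random fixtures, both modes
  for (seed in 1:5) {
    st <- generateStudy(studyDesign(n_samples = 20, n_features = 40,
                                    n_complexes = 2, complex_size = 4,
                                    missing_rate = 0, n_snps = 20, n_cis = 10,
                                    n_trans = 10, n_traits = 3, n_comapped = 3,
                                    seed = seed), decoy_count = 2)
    gg <- buildGraph(qtls = st$qtl, comappings = comap(st$qtl, st$traits))
    before <- sum(edgeTable(gg)$multiplicity)
    for (mode in c("ld_block", "chromosome")) {
      gcc <- collapseNodes(gg, mode, ldBlocks = st$ld_blocks)
      expect_equal(sum(edgeTable(gcc)$multiplicity), before)
    }
  }
})

test_that("graph filtering keeps exactly the edges passing the predicate", {
  fx <- make_graph_fixture()
  g <- buildGraph(pairs = annotatePairs(fx$cs, list(readPairReference(
    data.frame(a = "G1", b = "G2", s = 1), "refdb"))),
    qtls = fx$q, comappings = fx$cm)

  g_ref <- filterGraph(g, "reference_flag", "refdb")
  expect_true(all(grepl("refdb",
                        edgeTable(g_ref)$db_flags[edgeTable(g_ref)$type == "coregulation"])))

  g_imp <- filterGraph(g, "impact_at_least", "HIGH")
  eq <- edgeTable(g_imp)
  expect_true(all(eq$impact[eq$type == "qtl"] == "HIGH"))

  g_px <- filterGraph(g, "proxy", "cis")
  ep <- edgeTable(g_px)
  expect_true(all(ep$proxy[ep$type == "qtl"] == "cis"))

  # predicate-scan oracle for the proxy filter
  ed <- edgeTable(g)
  keep_oracle <- ed[!(ed$type == "qtl" & (is.na(ed$proxy) | ed$proxy != "cis")), ]
  expect_setequal(paste(ep$from, ep$to, ep$type),
                  paste(keep_oracle$from, keep_oracle$to, keep_oracle$type))
  # isolated nodes are pruned, bait survives
  g_b <- filterGraph(g, "proxy", "nonexistent_proxy", bait = "feature:G1")
  expect_true("feature:G1" %in% nodeTable(g_b)$id)
})

test_that("compartment filtering keeps only features in the organelle", {
  loc <- propagateLocalizations(readLocalizations(
    data.frame(feature = c("G1", "G2", "G3"),
               term = c("peroxisome", "peroxisome", "nucleus")),
    data.frame(term = character(), parent = character())))
  m <- matrix(rnorm(3 * 15), nrow = 3, dimnames = list(paste0("G", 1:3), NULL))
  m[2, ] <- m[1, ] + rnorm(15, sd = 0.05); m[3, ] <- m[1, ] + rnorm(15, sd = 0.05)
  cs <- filterPairs(correlateAllPairs(m, "pearson"), 0.5, 0.5)
  g <- buildGraph(pairs = cs)
  gf <- filterGraph(g, "compartment", "peroxisome", locTable = loc)
  labs <- nodeTable(gf)$label[nodeTable(gf)$type == "feature"]
  expect_setequal(labs, c("G1", "G2"))
})

test_that("node-local compartment filtering commutes with collapsing", {
  st <- generateStudy(studyDesign(n_samples = 20, n_features = 40,
                                  n_complexes = 2, complex_size = 4,
                                  missing_rate = 0, n_snps = 20, n_cis = 10,
                                  n_trans = 10, n_traits = 3, n_comapped = 3,
                                  seed = 9), decoy_count = 2)
  loc <- propagateLocalizations(st$localizations)
  term <- st$localizations$loc[[1]][1]
  g <- buildGraph(qtls = st$qtl)
  a <- filterGraph(collapseNodes(g, "chromosome"), "compartment", term,
                   locTable = loc)
  b <- collapseNodes(filterGraph(g, "compartment", term, locTable = loc),
                     "chromosome")
  expect_setequal(nodeTable(a)$id, nodeTable(b)$id)
  ek <- function(x) paste(edgeTable(x)$from, edgeTable(x)$to,
                          edgeTable(x)$type, edgeTable(x)$multiplicity)
  expect_setequal(ek(a), ek(b))
})

test_that("GraphML export round-trips through igraph", {
  fx <- make_graph_fixture()
  g <- buildGraph(pairs = fx$cs, qtls = fx$q, comappings = fx$cm)
  base <- file.path(tempdir(), "net")
  files <- exportGraph(g, base)
  expect_true(all(file.exists(files)))
  back <- igraph::read_graph(files[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(back), nrow(nodeTable(g)))
  expect_equal(igraph::ecount(back), nrow(edgeTable(g)))
  nodes_csv <- utils::read.csv(files[["nodes"]])
  expect_equal(nrow(nodes_csv), nrow(nodeTable(g)))
})
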