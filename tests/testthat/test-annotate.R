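set.seed(1123)

make_scored_ref <- function(n, name = "ref") {
  methods::new("ReferenceSet", name = name,
               pairs = data.frame(member_a = sprintf("A%06d", seq_len(n)),
                                  member_b = sprintf("B%06d", seq_len(n)),
                                  score = runif(n), stringsAsFactors = FALSE),
               complexes = list())
}

test_that("top-percentile filtering retains ceil(N p / 100) by stable rank", {
  expect_equal(nrow(refPairs(filterTopPercentile(make_scored_ref(100), 10))), 10L)
  expect_equal(nrow(refPairs(filterTopPercentile(make_scored_ref(10), 10))), 1L)
  # ties at the boundary keep earlier-listed pairs
  ref <- methods::new("ReferenceSet", name = "t",
                      pairs = data.frame(member_a = paste0("A", 1:4),
                                         member_b = paste0("B", 1:4),
                                         score = c(0.9, 0.5, 0.5, 0.5)),
                      complexes = list())
  kept <- refPairs(filterTopPercentile(ref, 50))
  expect_identical(kept$member_a, c("A1", "A2"))
  unscored <- methods::new("ReferenceSet", name = "u",
                           pairs = data.frame(member_a = "A", member_b = "B",
                                              score = NA_real_))
  expect_error(filterTopPercentile(unscored, 10), "not fully scored")
})

test_that("pair annotation flags membership exactly, without changing cardinality", {
  m <- matrix(rnorm(6 * 15), nrow = 6,
              dimnames = list(paste0("G", 1:6), NULL))
  cs <- correlateAllPairs(m, "pearson")
  cref <- readComplexReference(
    data.frame(complex_id = c("C1", "C1", "C1", "C2", "C2"),
               member = c("G1", "G2", "G3", "G5", "G6")), "corumlike")
  pref <- readPairReference(
    data.frame(a = c("G1", "G4"), b = c("G2", "G5"), score = c(1, 2)), "stringlike")
  ann <- annotatePairs(cs, list(cref, pref))
  pt_ <- pairTable(ann)
  expect_equal(nrow(pt_), nrow(pairTable(cs)))

  flag_of <- function(a, b) pt_$db_flags[pt_$feature_a == a & pt_$feature_b == b]
  expect_identical(flag_of("G1", "G2"), "corumlike;stringlike")
  expect_identical(flag_of("G2", "G3"), "corumlike")   # complex expansion
  expect_identical(flag_of("G3", "G4"), "")
  expect_identical(pt_$complex_ids[pt_$feature_a == "G1" & pt_$feature_b == "G2"], "C1")

  # brute-force membership recount over every pair and reference
  for (k in seq_len(nrow(pt_))) {
    a <- pt_$feature_a[k]; b <- pt_$feature_b[k]
    expected <- character()
    for (ref in list(cref, pref)) {
      rp <- refPairs(ref)
      hit <- any((rp$member_a == a & rp$member_b == b) |
                   (rp$member_a == b & rp$member_b == a))
      if (hit) expected <- c(expected, refName(ref))
    }
    expect_identical(pt_$db_flags[k], paste(expected, collapse = ";"))
  }
})

test_that("localisation propagation follows ancestor chains and is idempotent", {
  tab <- readLocalizations(
    data.frame(feature = c("F1", "F2", "F3"),
               term = c("nuclear speck", "nucleus", "cytosol")),
    data.frame(term = c("nuclear speck", "nucleoplasm", "cytosol"),
               parent = c("nucleoplasm", "nucleus", "cytoplasm")))
  prop <- propagateLocalizations(tab)
  expect_setequal(prop$loc$F1, c("nuclear speck", "nucleoplasm", "nucleus"))
  expect_identical(prop$loc$F2, "nucleus")   # root term unchanged
  expect_identical(propagateLocalizations(prop)$loc, prop$loc)

  # diamond DAG: both parent chains united, each ancestor once
  dia <- readLocalizations(
    data.frame(feature = "F", term = "leaf"),
    data.frame(term = c("leaf", "leaf", "p1", "p2"),
               parent = c("p1", "p2", "root", "root")))
  got <- propagateLocalizations(dia)$loc$F
  # path-enumeration oracle: every chain leaf -> ... -> root
  expect_identical(got, sort(unique(c("leaf", "p1", "p2", "root"))))

  cyc <- readLocalizations(data.frame(feature = "F", term = "a"),
                           data.frame(term = c("a", "b"), parent = c("b", "a")))
  expect_error(propagateLocalizations(cyc), "cycle")
})

test_that("same-compartment resolves via shared ancestors; unannotated is FALSE", {
  tab <- readLocalizations(
    data.frame(feature = c("F1", "F2", "F3"),
               term = c("nuclear speck", "nucleoplasm", "cytosol")),
    data.frame(term = c("nuclear speck", "nucleoplasm"),
               parent = c("nucleoplasm", "nucleus")))
  prop <- propagateLocalizations(tab)
  expect_true(sameCompartment("F1", "F2", prop))
  expect_false(sameCompartment("F1", "F3", prop))
  expect_false(sameCompartment("F1", "Funknown", prop))
})

test_that("drug-target lookup preserves table order and empties cleanly", {
  dgi <- data.frame(gene = c("IL5RA", "CCL11", "IL5RA"),
                    drug = c("Benralizumab", "Bertilimumab", "OtherMab"))
  got <- annotateDrugTargets(c("IL5RA", "ABC1"), dgi)
  expect_identical(got$IL5RA, c("Benralizumab", "OtherMab"))
  expect_identical(got$ABC1, character(0))
})

test_that("overlap chi-squared matches the closed form and its invariances", {
  # build an annotated pair set with prescribed 2x2 composition
  n <- c(corr_in = 30, corr_out = 70, unc_in = 10, unc_out = 190)
  total <- sum(n)
  pairs <- data.frame(
    feature_a = sprintf("A%03d", seq_len(total)),
    feature_b = sprintf("B%03d", seq_len(total)),
    r = c(rep(0.9, n[1] + n[2]), rep(0.1, n[3] + n[4])),
    p = 0.001, q = 0.001, n_obs = 30L,
    db_flags = c(rep("db", n[1]), rep("", n[2]), rep("db", n[3]), rep("", n[4])),
    stringsAsFactors = FALSE)
  cs <- methods::new("CorrelationSet", pairs = pairs, method = "pearson",
                     features = c(pairs$feature_a, pairs$feature_b),
                     nSkippedLowN = 0L)
  res <- overlapChisq(cs, "db", rCut = 0.5, qCut = 0.05)
  tab <- matrix(n, 2, byrow = TRUE)
  expect_equal(res$chi2, oracle_chisq(tab), tolerance = 1e-10)
  expect_equal(res$overlap_fraction, 30 / 100)
  # swapping rows and columns simultaneously leaves chi2 unchanged
  expect_equal(oracle_chisq(tab[2:1, 2:1]), res$chi2, tolerance = 1e-10)

  # proportionally identical rows give chi2 = 0
  pairs0 <- pairs
  pairs0$db_flags <- c(rep("db", 10), rep("", 90), rep("db", 20), rep("", 180))
  cs0 <- methods::new("CorrelationSet", pairs = pairs0, method = "pearson",
                      features = c(pairs0$feature_a, pairs0$feature_b),
                      nSkippedLowN = 0L)
  expect_equal(overlapChisq(cs0, "db", 0.5, 0.05)$chi2, 0, tolerance = 1e-12)
})

test_that("planted complexes are strongly enriched on a simulated study", {
  st <- generateStudy(studyDesign(n_samples = 60, n_features = 100,
                                  n_complexes = 2, complex_size = 8,
                                  within_complex_rho = 0.8, missing_rate = 0,
                                  n_snps = 4, n_cis = 2, n_trans = 2,
                                  n_traits = 2, n_comapped = 1, seed = 17),
                      decoy_count = 5)
  cs <- annotatePairs(correlateAllPairs(st$expression, "pearson"),
                      st$references["complexdb"])
  res <- suppressWarnings(overlapChisq(cs, "complexdb", 0.5, 0.05))
  expect_lt(res$p, 1e-6)
})

test_that("sensitivity grid enumerates the default 72 combinations with
           degenerate cells flagged, and overlap rises with the r cutoff", {
  st <- generateStudy(studyDesign(n_samples = 40, n_features = 40,
                                  n_complexes = 2, complex_size = 6,
                                  missing_rate = 0, n_snps = 2, n_cis = 1,
                                  n_trans = 1, n_traits = 1, n_comapped = 1,
                                  seed = 23), decoy_count = 3)
  cs <- annotatePairs(correlateAllPairs(st$expression, "pearson"),
                      st$references["complexdb"])
  grid <- sensitivityGrid(cs, st$references["complexdb"])
  expect_equal(nrow(grid), 72L)
  expect_gte(nrow(grid), 70L)
  expect_true(all(grid$r_cut %in% seq(0.1, 0.9, 0.1)))

  # an unreachable cutoff yields a degenerate, non-fatal cell
  grid2 <- sensitivityGrid(cs, st$references["complexdb"], rCuts = c(0.5),
                           qCuts = c(1e-30))
  expect_true(grid2$degenerate[1])

  # overlap_fraction non-decreasing in r_cut at fixed q (planted pairs
  # out-correlate background)
  g_fix <- grid[grid$q_cut == 1 & !grid$degenerate, ]
  g_fix <- g_fix[order(g_fix$r_cut), ]
  expect_true(all(diff(g_fix$overlap_fraction) >= -1e-12))
})
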