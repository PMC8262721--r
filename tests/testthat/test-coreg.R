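set.seed(20260924)

test_that("missing-value filter removes strictly above the cutoff", {
  m <- matrix(rnorm(30), nrow = 3, dimnames = list(c("A", "B", "C"), NULL))
  m[1, 1:6] <- NA   # 6/10 missing
  m[2, 1:5] <- NA   # 5/10 missing, exactly at a 0.5 cutoff
  out <- filterMissing(m, 0.5)
  expect_identical(rownames(out), c("B", "C"))
  counts <- attr(out, "filter")
  expect_equal(counts$features_in, counts$features_kept + counts$features_removed)
  # cutoff 0 keeps only complete features
  expect_identical(rownames(filterMissing(m, 0)), "C")
  expect_error(filterMissing(m[1, , drop = FALSE], 0), "all features")
})

test_that("imputation is deterministic, identity on complete data, and the
           downshift draws match the stated normal", {
  m <- matrix(rnorm(40, 20), nrow = 4)
  rownames(m) <- paste0("G", 1:4)
  for (meth in c("downshift_normal", "feature_min", "none")) {
    expect_identical(imputeMissing(m, meth, seed = 3), m)
  }
  m[1, 1:3] <- NA
  i1 <- imputeMissing(m, "downshift_normal", seed = 11)
  i2 <- imputeMissing(m, "downshift_normal", seed = 11)
  expect_identical(i1, i2)
  expect_false(anyNA(i1))
  i3 <- imputeMissing(m, "feature_min", seed = 1)
  expect_equal(i3[1, 1:3], rep(min(m[1, ], na.rm = TRUE), 3),
               ignore_attr = TRUE)

  # Monte-Carlo: 10,000 downshift draws follow Normal(mean - 1.8 sd, (0.3 sd)^2)
  obs <- rnorm(200, mean = 22, sd = 1.5)
  big <- matrix(c(obs, rep(NA_real_, 10000)), nrow = 1)
  rownames(big) <- "G1"
  imp <- imputeMissing(big, "downshift_normal", seed = 99)[1, -(1:200)]
  mu_target <- mean(obs) - 1.8 * sd(obs)
  sd_target <- 0.3 * sd(obs)
  expect_equal(mean(imp), mu_target, tolerance = 5 * sd_target / sqrt(10000) / abs(mu_target))
  expect_equal(sd(imp), sd_target, tolerance = 0.05)
  expect_true(all(imp < mean(obs)))   # essentially certain at 6 sigma
})

test_that("bicor is exact on self and affine transforms and matches a
           direct-formula oracle on random vectors", {
  x <- rnorm(30)
  expect_equal(bicor(x, x), 1.0)
  expect_equal(bicor(x, 3 + 2 * x), 1.0)
  expect_equal(bicor(x, 1 - 4 * x), -1.0)
  for (i in 1:50) {
    a <- rnorm(20); b <- rnorm(20) + 0.3 * a
    expect_equal(bicor(a, b), oracle_bicor(a, b), tolerance = 1e-10)
  }
  expect_error(bicor(1:2, 2:3 + 0), "at least 3")
  cx <- c(rep(5, 18), 6, 7)   # zero MAD: mean/SD fallback
  expect_warning(r <- bicor(cx, rnorm(20)), "zero MAD")
  expect_true(abs(r) <= 1)
  expect_error(suppressWarnings(bicor(rep(1, 10), rnorm(10))), "zero variance")
})

test_that("correlation p-values match the t-distribution and its bounds", {
  expect_equal(correlationPvalue(0, 20), 1)
  expect_equal(correlationPvalue(1, 20), 0)
  expect_equal(correlationPvalue(-1, 5), 0)
  r <- 0.5; n <- 20
  tval <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(correlationPvalue(r, n), 2 * (1 - pt(tval, n - 2)),
               tolerance = 1e-12)
  rs <- runif(20, -0.99, 0.99)
  expect_equal(correlationPvalue(rs, 15),
               vapply(rs, function(ri) {
                 ti <- abs(ri) * sqrt(13 / (1 - ri^2))
                 2 * pt(ti, 13, lower.tail = FALSE)
               }, numeric(1)), tolerance = 1e-12)
})

test_that("p-value adjustment matches hand computations and dominates p", {
  expect_equal(adjustPvalues(c(0.01, 0.3), "bonferroni"), c(0.02, 0.6))
  expect_equal(adjustPvalues(c(0.005, 0.01, 0.03, 0.04), "bh"),
               c(0.02, 0.02, 0.04, 0.04))
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjustPvalues(p, "bh"), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adjustPvalues(p, "bh") >= p - 1e-15))
    expect_true(all(adjustPvalues(p, "bonferroni") >= p - 1e-15))
  }
})

test_that("all-pairs correlation emits C(F,2) pairs, conserves counts and
           matches oracles", {
  m <- matrix(rnorm(4 * 12), nrow = 4,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:12)))
  cs <- correlateAllPairs(m, "pearson")
  expect_equal(nrow(pairTable(cs)), choose(4, 2))

  # pearson against the textbook-formula oracle
  big <- matrix(rnorm(10 * 25), nrow = 10,
                dimnames = list(paste0("G", sprintf("%02d", 1:10)), NULL))
  csb <- correlateAllPairs(big, "pearson")
  pt_ <- pairTable(csb)
  for (k in sample(nrow(pt_), 20)) {
    expect_equal(pt_$r[k],
                 oracle_pearson(big[pt_$feature_a[k], ], big[pt_$feature_b[k], ]),
                 tolerance = 1e-12)
  }

  # pairs below min_obs are skipped and counted: emitted + skipped = C(F,2)
  mm <- matrix(rnorm(3 * 10), nrow = 3,
               dimnames = list(c("A", "B", "C"), NULL))
  mm[1, 1:8] <- NA; mm[2, 9:10] <- NA  # A-B: 0 complete obs; A-C: 2
  cs2 <- correlateAllPairs(mm, "pearson", minObs = 3)
  expect_equal(nrow(pairTable(cs2)) + cs2@nSkippedLowN, choose(3, 2))
  expect_equal(cs2@nSkippedLowN, 2L)
  # n_obs is recorded per pair under pairwise-complete handling
  expect_true(all(pairTable(cs2)$n_obs >= 3))
})

test_that("correlation is symmetric and spearman equals pearson on ranks", {
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(bicor(x, y), bicor(y, x))
  m <- rbind(a = x, b = y)
  for (meth in c("pearson", "spearman", "bicor")) {
    r1 <- pairTable(correlateAllPairs(m, meth))$r
    r2 <- pairTable(correlateAllPairs(m[c(2, 1), ], meth))$r
    expect_equal(r1, r2)
  }
  # ties handled by average ranks
  xt <- round(rnorm(30), 1); yt <- round(rnorm(30), 1)
  sp <- pairTable(correlateAllPairs(rbind(a = xt, b = yt), "spearman"))$r
  expect_equal(sp, oracle_pearson(rank(xt), rank(yt)), tolerance = 1e-12)
})

test_that("connectivity counts match a nested-loop recount and sum to 2x pairs", {
  m <- matrix(rnorm(8 * 20), nrow = 8,
              dimnames = list(paste0("G", 1:8), NULL))
  m[2, ] <- m[1, ] + rnorm(20, sd = 0.1)
  m[3, ] <- m[1, ] + rnorm(20, sd = 0.1)
  cs <- correlateAllPairs(m, "pearson")
  conn <- connectivity(cs, rCut = 0.5, qCut = 0.05)
  expect_setequal(conn$feature, rownames(m))
  pt_ <- pairTable(cs)
  pass <- abs(pt_$r) >= 0.5 & pt_$q <= 0.05
  expect_equal(sum(conn$n_partners), 2 * sum(pass))
  # brute-force recount
  for (f in rownames(m)) {
    n_f <- sum((pt_$feature_a == f | pt_$feature_b == f) & pass)
    expect_equal(conn$n_partners[conn$feature == f], n_f)
  }
  # no passing pairs -> all zeros
  expect_true(all(connectivity(cs, rCut = 1.1)$n_partners == 0))
})

test_that("planted co-regulated blocks out-correlate background for all methods", {
  st <- generateStudy(studyDesign(n_samples = 40, n_features = 30,
                                  n_complexes = 2, complex_size = 5,
                                  missing_rate = 0, n_snps = 4, n_cis = 2,
                                  n_trans = 2, n_traits = 2, n_comapped = 1,
                                  seed = 5), decoy_count = 2)
  planted_key <- paste(st$truth$planted_pairs$member_a,
                       st$truth$planted_pairs$member_b)
  for (meth in c("pearson", "spearman", "bicor")) {
    pt_ <- pairTable(correlateAllPairs(st$expression, meth))
    in_block <- paste(pt_$feature_a, pt_$feature_b) %in% planted_key
    expect_gt(mean(abs(pt_$r[in_block])), mean(abs(pt_$r[!in_block])))
  }
})
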