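#' Design of a synthetic systems-genetics study
#'
#' Parameters of the seeded generator in [generateStudy()]. Defaults
#' describe a compact population-proteomics study: 60 samples, 200
#' features of which 5 planted complexes of 8 members co-regulate with
#' pairwise correlation 0.8 through a shared latent factor, 5% values
#' missing completely at random, 30 cis and 20 trans pQTLs, 10 traits and
#' 5 co-mapped SNPs shared verbatim between the QTL and trait tables.
#'
#' @param n_samples number of samples (columns).
#' @param n_features number of features (rows).
#' @param n_complexes number of planted complexes.
#' @param complex_size members per planted complex.
#' @param within_complex_rho target pairwise correlation inside a complex
#'   (0 <= rho < 1).
#' @param noise_sd scale of the expression values around each feature's
#'   baseline.
#' @param missing_rate fraction of values set missing at random
#'   (0 <= rate < 1).
#' @param n_snps total QTL records; must equal `n_cis + n_trans`.
#' @param n_cis,n_trans cis / trans QTL counts.
#' @param n_traits number of distinct traits.
#' @param n_comapped SNPs shared between the QTL and trait tables.
#' @param seed integer seed; the whole study is a deterministic function
#'   of the design including the seed.
#' @return a `StudyDesign` list.
#' @export
studyDesign <- function(n_samples = 60, n_features = 200, n_complexes = 5,
                        complex_size = 8, within_complex_rho = 0.8,
                        noise_sd = 1, missing_rate = 0.05,
                        n_snps = 50, n_cis = 30, n_trans = 20,
                        n_traits = 10, n_comapped = 5, seed = 1) {
  d <- list(n_samples = n_samples, n_features = n_features,
            n_complexes = n_complexes, complex_size = complex_size,
            within_complex_rho = within_complex_rho, noise_sd = noise_sd,
            missing_rate = missing_rate, n_snps = n_snps, n_cis = n_cis,
            n_trans = n_trans, n_traits = n_traits, n_comapped = n_comapped,
            seed = seed)
  stopifnot(all(unlist(d[c("n_samples", "n_features", "n_complexes",
                           "complex_size", "n_snps", "n_cis", "n_trans",
                           "n_traits", "n_comapped")]) >= 0),
            within_complex_rho >= 0, within_complex_rho < 1,
            missing_rate >= 0, missing_rate < 1, noise_sd > 0)
  if (n_cis + n_trans != n_snps) stop("n_snps must equal n_cis + n_trans")
  if (n_complexes * complex_size > n_features) {
    stop("infeasible design: complexes exceed available features")
  }
  if (n_comapped > n_snps) stop("infeasible design: n_comapped > n_snps")
  structure(d, class = "StudyDesign")
}

# synthetic genome: chromosomes 1-19 and X, 150 Mb each
.GENOME <- list(chroms = c(as.character(1:19), "X"), length = 1.5e8)

#' Generate a complete synthetic study with planted structure
#'
#' Produces every input the pipeline consumes, as in-memory objects plus a
#' truth record of the planted structure. Complex members are drawn from a
#' shared latent factor, `x = sqrt(rho) f + sqrt(1 - rho) e`, giving exact
#' expected pairwise correlation `rho` inside each complex; background
#' features are independent. Cis SNPs are placed inside their gene body,
#' trans SNPs on a different chromosome; `n_comapped` QTL SNPs reappear
#' verbatim in the trait table (decoy trait SNPs use a disjoint rsID
#' range, so the planted co-mappings are exactly recoverable). Reference
#' extracts, localisations, drug table and consequence lookup come from
#' [generateReferenceExtracts()].
#'
#' @param design a `StudyDesign` from [studyDesign()].
#' @param decoy_count decoy complexes/pairs added to the reference
#'   extracts.
#' @return list with `expression` (matrix with missing values), `qtl`,
#'   `traits`, `ld_blocks` (data.frames), `references` (list of
#'   [ReferenceSet]), `localizations`, `drug_table`,
#'   `consequence_lookup`, and `truth` (planted complexes, pairs, SNPs
#'   and co-mapped triples).
#' @export
generateStudy <- function(design = studyDesign(), decoy_count = 20) {
  stopifnot(inherits(design, "StudyDesign"))
  d <- design
  .with_seed(d$seed, {
    feat <- sprintf("Gene%04d", seq_len(d$n_features))
    samples <- sprintf("S%03d", seq_len(d$n_samples))
    complexes <- list()
    idx <- 0
    for (k in seq_len(d$n_complexes)) {
      complexes[[sprintf("CPX%02d", k)]] <- feat[idx + seq_len(d$complex_size)]
      idx <- idx + d$complex_size
    }

    # expression: latent factor per complex, independent background
    mu <- stats::rnorm(d$n_features, mean = 25, sd = 2)
    m <- matrix(NA_real_, d$n_features, d$n_samples,
                dimnames = list(feat, samples))
    rho <- d$within_complex_rho
    member_of <- rep(NA_integer_, d$n_features)
    for (k in seq_along(complexes)) {
      member_of[match(complexes[[k]], feat)] <- k
    }
    factors <- matrix(stats::rnorm(d$n_complexes * d$n_samples),
                      d$n_complexes, d$n_samples)
    for (i in seq_len(d$n_features)) {
      eps <- stats::rnorm(d$n_samples)
      z <- if (is.na(member_of[i])) eps
           else sqrt(rho) * factors[member_of[i], ] + sqrt(1 - rho) * eps
      m[i, ] <- mu[i] + d$noise_sd * z
    }
    if (d$missing_rate > 0) {
      miss <- matrix(stats::runif(length(m)) < d$missing_rate, nrow(m))
      # never blank out a full feature
      full <- rowSums(!miss) < 3
      miss[full, ] <- FALSE
      m[miss] <- NA_real_
    }

    # gene coordinates
    gene_chrom <- sample(.GENOME$chroms, d$n_features, replace = TRUE)
    gene_start <- floor(stats::runif(d$n_features, 1, .GENOME$length - 2e5))
    gene_end <- gene_start + floor(stats::runif(d$n_features, 5e3, 2e5))
    names(gene_chrom) <- names(gene_start) <- names(gene_end) <- feat

    # QTL records: cis inside the gene body, trans on another chromosome
    qtl_genes <- sample(feat, d$n_snps, replace = TRUE)
    rsid <- sprintf("rs%06d", seq_len(d$n_snps))
    is_cis <- seq_len(d$n_snps) <= d$n_cis
    snp_chrom <- character(d$n_snps); snp_pos <- numeric(d$n_snps)
    for (i in seq_len(d$n_snps)) {
      g <- qtl_genes[i]
      if (is_cis[i]) {
        snp_chrom[i] <- gene_chrom[[g]]
        snp_pos[i] <- floor(stats::runif(1, gene_start[[g]], gene_end[[g]] + 1))
      } else {
        snp_chrom[i] <- sample(setdiff(.GENOME$chroms, gene_chrom[[g]]), 1)
        snp_pos[i] <- floor(stats::runif(1, 1, .GENOME$length))
      }
    }
    qtl <- data.frame(
      rsid = rsid, snp_chrom = snp_chrom, snp_pos = snp_pos,
      gene = qtl_genes, gene_chrom = unname(gene_chrom[qtl_genes]),
      gene_start = unname(gene_start[qtl_genes]),
      gene_end = unname(gene_end[qtl_genes]),
      significance = 10^stats::runif(d$n_snps, -12, -4),
      proxy = ifelse(is_cis, "cis", "trans"),
      stringsAsFactors = FALSE
    )
    attr(qtl, "sigKind") <- "pvalue"

    # traits: planted co-mapped SNPs reuse QTL rsIDs verbatim; decoys use
    # a disjoint rsID range
    trait_names <- sprintf("Trait%02d", seq_len(max(d$n_traits, 1)))
    comapped_idx <- if (d$n_comapped > 0) sample(d$n_snps, d$n_comapped) else integer()
    planted <- if (length(comapped_idx)) data.frame(
      rsid = qtl$rsid[comapped_idx],
      trait = sample(trait_names, d$n_comapped, replace = TRUE),
      snp_chrom = qtl$snp_chrom[comapped_idx],
      snp_pos = qtl$snp_pos[comapped_idx],
      significance = 10^stats::runif(d$n_comapped, -12, -6),
      group = "planted", stringsAsFactors = FALSE
    ) else NULL
    n_decoy_tr <- 2 * max(d$n_traits, 1)
    decoys <- data.frame(
      rsid = sprintf("rs9%06d", seq_len(n_decoy_tr)),
      trait = sample(trait_names, n_decoy_tr, replace = TRUE),
      snp_chrom = sample(.GENOME$chroms, n_decoy_tr, replace = TRUE),
      snp_pos = floor(stats::runif(n_decoy_tr, 1, .GENOME$length)),
      significance = 10^stats::runif(n_decoy_tr, -10, -6),
      group = "background", stringsAsFactors = FALSE
    )
    traits <- rbind(planted, decoys)
    rownames(traits) <- NULL
    attr(traits, "sigKind") <- "pvalue"

    # LD blocks: non-overlapping intervals around a subset of SNPs
    ld <- .make_ld_blocks(qtl)

    truth <- list(
      complexes = complexes,
      planted_pairs = do.call(rbind, lapply(names(complexes), function(cn) {
        cmb <- utils::combn(sort(complexes[[cn]]), 2)
        data.frame(member_a = cmb[1, ], member_b = cmb[2, ],
                   complex_id = cn, stringsAsFactors = FALSE)
      })),
      cis_rsids = qtl$rsid[is_cis], trans_rsids = qtl$rsid[!is_cis],
      comapped = if (length(comapped_idx)) data.frame(
        rsid = qtl$rsid[comapped_idx], gene = qtl$gene[comapped_idx],
        trait = planted$trait, stringsAsFactors = FALSE
      ) else data.frame(rsid = character(), gene = character(),
                        trait = character())
    )
    refs <- generateReferenceExtracts(truth, decoy_count = decoy_count,
                                      seed = NULL, features = feat,
                                      rsids = qtl$rsid)
    c(list(expression = m, qtl = qtl, traits = traits, ld_blocks = ld,
           truth = truth, design = d), refs)
  })
}

.make_ld_blocks <- function(qtl) {
  rows <- list()
  for (ch in unique(qtl$snp_chrom)) {
    pos <- sort(unique(qtl$snp_pos[qtl$snp_chrom == ch]))
    taken <- utils::head(pos, max(1, length(pos) %/% 2))
    last_end <- -Inf
    for (p in taken) {
      start <- max(p - 5e5, last_end + 1, 1)
      end <- p + 5e5
      if (start > p) next
      rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = start,
                                              end = end,
                                              stringsAsFactors = FALSE)
      last_end <- end
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate reference extracts around a planted truth record
#'
#' Builds the local reference files: a complex-style reference containing
#' exactly the planted complexes plus decoy complexes of background
#' features; a scored pair reference in which planted pairs draw scores
#' from the top of the range (so they survive a top-10th-percentile
#' filter) and decoy pairs from the bulk; a localisation table with the
#' ontology chain nuclear speck -> nucleoplasm -> nucleus plus
#' cytoplasmic/mitochondrial terms; a drug table covering a few features;
#' and an rsID -> consequence lookup over the study's SNPs.
#'
#' @param truth truth record from [generateStudy()].
#' @param decoy_count number of decoy complexes and (x10) decoy pairs.
#' @param seed optional seed (NULL = inherit the caller's RNG stream).
#' @param features all feature names of the study.
#' @param rsids the study's SNP ids.
#' @return list `references` (list of [ReferenceSet]), `localizations`,
#'   `drug_table`, `consequence_lookup`.
#' @export
generateReferenceExtracts <- function(truth, decoy_count = 20, seed = NULL,
                                      features, rsids) {
  run <- function() {
    planted <- truth$planted_pairs
    background <- setdiff(features, unlist(truth$complexes))

    # complex-style reference: planted complexes + decoys
    cplx_rows <- do.call(rbind, lapply(names(truth$complexes), function(cn) {
      data.frame(complex_id = cn, member = truth$complexes[[cn]],
                 stringsAsFactors = FALSE)
    }))
    if (decoy_count > 0 && length(background) >= 3) {
      for (k in seq_len(decoy_count)) {
        sz <- sample(3:min(6, length(background)), 1)
        cplx_rows <- rbind(cplx_rows, data.frame(
          complex_id = sprintf("DECOY%02d", k),
          member = sample(background, sz), stringsAsFactors = FALSE))
      }
    }
    complex_ref <- readComplexReference(cplx_rows, name = "complexdb")

    # scored pair reference: planted pairs rank in the top decile by
    # construction — enough low-scoring decoys that the planted pairs make
    # up less than a tenth of the catalogue
    n_target <- max(decoy_count * 10, 9 * nrow(planted) + 10)
    decoy_a <- sample(features, 3 * n_target, replace = TRUE)
    decoy_b <- sample(features, 3 * n_target, replace = TRUE)
    ok <- decoy_a != decoy_b &
      !(.pair_key(decoy_a, decoy_b) %in% .pair_key(planted$member_a,
                                                   planted$member_b)) &
      !duplicated(.pair_key(decoy_a, decoy_b))
    keep <- utils::head(which(ok), n_target)
    pair_rows <- rbind(
      data.frame(member_a = planted$member_a, member_b = planted$member_b,
                 score = stats::runif(nrow(planted), 0.9, 1),
                 stringsAsFactors = FALSE),
      data.frame(member_a = decoy_a[keep], member_b = decoy_b[keep],
                 score = stats::runif(length(keep), 0, 0.8),
                 stringsAsFactors = FALSE))
    pair_ref <- readPairReference(pair_rows, name = "interactiondb")

    # localisations with an ancestor chain
    parents <- data.frame(
      term = c("nuclear speck", "nucleoplasm", "mitochondrial matrix",
               "cytosol"),
      parent = c("nucleoplasm", "nucleus", "mitochondrion", "cytoplasm"),
      stringsAsFactors = FALSE)
    terms <- c("nuclear speck", "mitochondrial matrix", "cytosol", "nucleus",
               "mitochondrion", "cytoplasm")
    n_loc <- min(length(features), max(10, length(features) %/% 2))
    loc_feats <- sample(features, n_loc)
    loc_rows <- data.frame(feature = loc_feats,
                           term = sample(terms, n_loc, replace = TRUE),
                           stringsAsFactors = FALSE)
    loc <- readLocalizations(loc_rows, parents)

    # drug interactions for a handful of features
    drug_feats <- sample(features, min(8, length(features)))
    drugs <- data.frame(gene = drug_feats,
                        drug = sprintf("Drug%02d", seq_along(drug_feats)),
                        stringsAsFactors = FALSE)

    # consequence lookup over most of the study's SNPs
    so_terms <- names(loadImpactMap())
    n_ann <- max(1, floor(0.9 * length(rsids)))
    ann_rs <- sample(rsids, n_ann)
    lookup <- data.frame(rsid = ann_rs,
                         consequence = sample(so_terms, n_ann, replace = TRUE),
                         stringsAsFactors = FALSE)

    list(references = list(complexdb = complex_ref, interactiondb = pair_ref),
         localizations = loc, drug_table = drugs,
         consequence_lookup = lookup)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Write a generated study to disk as plain-text inputs
#'
#' Writes every table of a [generateStudy()] result as CSV (expression
#' matrix, QTL and trait tables, LD blocks, reference extracts,
#' localisations + ontology parents, drug table, consequence lookup), the
#' truth record as JSON, and a ready-to-run pipeline config file.
#'
#' @param study result of [generateStudy()].
#' @param directory output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeStudy <- function(study, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(directory, x)
  paths <- c(expression = f("expression.csv"), qtl = f("qtl.csv"),
             traits = f("traits.csv"), ld_blocks = f("ld_blocks.csv"),
             complexdb = f("reference_complexes.csv"),
             interactiondb = f("reference_pairs.csv"),
             localizations = f("localizations.csv"),
             parents = f("localization_parents.csv"),
             drugs = f("drug_interactions.csv"),
             consequences = f("consequence_lookup.csv"),
             truth = f("truth.json"), config = f("config.txt"))

  em <- data.frame(feature_id = rownames(study$expression),
                   study$expression, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_csv(em, paths[["expression"]])
  .write_csv(study$qtl, paths[["qtl"]])
  .write_csv(study$traits, paths[["traits"]])
  .write_csv(study$ld_blocks, paths[["ld_blocks"]])

  comps <- refComplexes(study$references$complexdb)
  .write_csv(do.call(rbind, lapply(names(comps), function(cn) {
    data.frame(complex_id = cn, member = comps[[cn]], stringsAsFactors = FALSE)
  })), paths[["complexdb"]])
  .write_csv(refPairs(study$references$interactiondb), paths[["interactiondb"]])

  loc <- study$localizations
  .write_csv(do.call(rbind, lapply(names(loc$loc), function(ft) {
    data.frame(feature = ft, term = loc$loc[[ft]], stringsAsFactors = FALSE)
  })), paths[["localizations"]])
  .write_csv(do.call(rbind, lapply(names(loc$parents), function(tm) {
    data.frame(term = tm, parent = loc$parents[[tm]], stringsAsFactors = FALSE)
  })), paths[["parents"]])
  .write_csv(study$drug_table, paths[["drugs"]])
  .write_csv(study$consequence_lookup, paths[["consequences"]])

  jsonlite::write_json(study$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(
    paste0("expression=", paths[["expression"]]),
    paste0("qtl=", paths[["qtl"]]),
    paste0("traits=", paths[["traits"]]),
    paste0("ld_blocks=", paths[["ld_blocks"]]),
    paste0("complex_reference=", paths[["complexdb"]]),
    paste0("pair_reference=", paths[["interactiondb"]]),
    paste0("localizations=", paths[["localizations"]]),
    paste0("localization_parents=", paths[["parents"]]),
    paste0("drug_table=", paths[["drugs"]]),
    paste0("consequence_lookup=", paths[["consequences"]]),
    "method=pearson",
    "max_missing=0.5",
    "impute=none",
    "adjust=bh",
    "r_cut=0.5",
    "q_cut=0.05",
    paste0("seed=", study$design$seed)
  ), paths[["config"]])
  invisible(paths)
}
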