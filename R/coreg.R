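#' Remove features with too many missing values
#'
#' A feature is removed if and only if its missing fraction strictly
#' exceeds `maxMissingFraction` (so a feature exactly at the cutoff is
#' retained). With a cutoff of 0, only complete features survive.
#'
#' @param x SummarizedExperiment (assay `"exprs"`) or numeric matrix,
#'   features in rows.
#' @param maxMissingFraction allowed missing fraction per feature, in
#'   \[0, 1\].
#' @return filtered object of the same class, with attribute/metadata
#'   `filter` recording `features_in`, `features_kept`, `features_removed`.
#' @export
filterMissing <- function(x, maxMissingFraction) {
  stopifnot(maxMissingFraction >= 0, maxMissingFraction <= 1)
  m <- .as_exprs(x)
  frac <- rowMeans(is.na(m))
  keep <- frac <= maxMissingFraction
  if (!any(keep)) stop("missing-value filter removed all features")
  counts <- list(features_in = nrow(m), features_kept = sum(keep),
                 features_removed = sum(!keep))
  out <- if (is(x, "SummarizedExperiment")) x[keep, ] else m[keep, , drop = FALSE]
  if (is(out, "SummarizedExperiment")) {
    md <- S4Vectors::metadata(out); md$filter <- counts
    S4Vectors::metadata(out) <- md
  } else attr(out, "filter") <- counts
  out
}

#' Impute missing expression values
#'
#' `downshift_normal` draws replacements per feature from
#' Normal(mean - 1.8 sd, (0.3 sd)^2) computed on the feature's observed
#' values — the left-shifted distribution conventionally used for
#' intensities missing because they fall below the detection limit.
#' `feature_min` substitutes the feature's observed minimum. `none` leaves
#' missing values in place (pairwise-complete correlation then applies
#' downstream).
#'
#' @param x SummarizedExperiment or matrix, features in rows.
#' @param method `"downshift_normal"`, `"feature_min"` or `"none"`.
#' @param seed integer seed for the downshift draws; the same seed yields
#'   identical imputed values.
#' @return object of the same class with missing values replaced
#'   (unchanged for `method = "none"` or a complete matrix).
#' @export
imputeMissing <- function(x, method = c("downshift_normal", "feature_min", "none"),
                          seed = NULL) {
  method <- match.arg(method)
  m <- .as_exprs(x)
  if (method == "none" || !anyNA(m)) return(x)
  if (method == "feature_min") {
    for (i in seq_len(nrow(m))) {
      miss <- is.na(m[i, ])
      if (!any(miss)) next
      if (all(miss)) stop("feature '", rownames(m)[i],
                          "' entirely missing: cannot impute feature minimum")
      m[i, miss] <- min(m[i, ], na.rm = TRUE)
    }
  } else {
    m <- .with_seed(seed, {
      for (i in seq_len(nrow(m))) {
        miss <- is.na(m[i, ])
        if (!any(miss)) next
        obs <- m[i, !miss]
        if (length(obs) < 2) {
          stop("feature '", rownames(m)[i],
               "' has <2 observed values: downshift imputation undefined; ",
               "filter features first")
        }
        mu <- mean(obs); s <- stats::sd(obs)
        m[i, miss] <- stats::rnorm(sum(miss), mean = mu - 1.8 * s, sd = 0.3 * s)
      }
      m
    })
  }
  .replace_exprs(x, m)
}

#' Biweight midcorrelation
#'
#' Robust correlation after Langfelder & Horvath: each vector is centred
#' on its median, scaled by 9 times its (unscaled) median absolute
#' deviation, weighted by the Tukey biweight `(1 - u^2)^2` (zero outside
#' `|u| < 1`), normalised to unit length, and the correlation is the inner
#' product of the two weighted vectors. No outlier-proportion capping is
#' applied. If a vector's MAD is zero the biweight is undefined and that
#' vector falls back to mean/SD standardisation (Pearson-style) with a
#' warning.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value
#'   in either vector are dropped (pairwise-complete).
#' @return correlation coefficient in \[-1, 1\].
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(30)
#' bicor(x, 2 + 3 * x)   # affine: exactly 1
bicor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("bicor needs at least 3 pairwise-complete observations")
  xs <- .bicor_standardize(x)
  ys <- .bicor_standardize(y)
  r <- sum(xs * ys)
  max(-1, min(1, r))
}

# biweight-standardise one vector to unit length; mean/SD fallback on
# zero MAD
.bicor_standardize <- function(x) {
  med <- stats::median(x)
  madx <- stats::mad(x, constant = 1)
  if (madx > 0) {
    u <- (x - med) / (9 * madx)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    xt <- (x - med) * w
  } else {
    if (stats::sd(x) == 0) stop("zero variance: correlation undefined")
    warning("zero MAD: falling back to mean/SD standardisation")
    xt <- x - mean(x)
  }
  nrm <- sqrt(sum(xt^2))
  if (nrm == 0) stop("degenerate weights: all observations down-weighted to zero")
  xt / nrm
}

#' Two-sided p-value for a correlation coefficient
#'
#' Student-t test of zero correlation: `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom, two-sided. `|r| = 1` gives p = 0.
#'
#' @param r correlation coefficient(s), `|r| <= 1`.
#' @param n_obs number(s) of pairwise-complete observations, >= 3.
#' @return p-value(s) in \[0, 1\].
#' @export
#' @examples
#' correlationPvalue(0, 10)    # 1
#' correlationPvalue(1, 10)    # 0
correlationPvalue <- function(r, n_obs) {
  stopifnot(all(n_obs >= 3))
  r <- pmax(-1, pmin(1, r))
  p <- rep(NA_real_, length(r))
  degen <- !is.na(r) & abs(r) >= 1
  p[degen] <- 0
  reg <- !is.na(r) & !degen
  nn <- rep_len(n_obs, length(r))
  if (any(reg)) {
    tval <- r[reg] * sqrt((nn[reg] - 2) / (1 - r[reg]^2))
    p[reg] <- 2 * stats::pt(-abs(tval), df = nn[reg] - 2)
  }
  pmin(1, p)
}

#' Multiple-testing correction
#'
#' Benjamini–Hochberg step-up (with monotone enforcement) or Bonferroni
#' (`min(1, m p)`), delegated to [stats::p.adjust()].
#'
#' @param p p-values in \[0, 1\].
#' @param method `"bh"` or `"bonferroni"`.
#' @return adjusted p-values (q-values), `q >= p` elementwise.
#' @export
adjustPvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' All-pairs co-regulation analysis
#'
#' Computes the correlation of every unordered feature pair on
#' pairwise-complete observations, with two-sided p-values from
#' [correlationPvalue()] and q-values over the complete pair family (no
#' pre-thresholding, so the multiple-testing family is all emitted pairs).
#' Pairs with fewer than `minObs` complete observations are omitted and
#' counted, so that `pairs emitted + pairs skipped = choose(F, 2)`.
#'
#' @param x SummarizedExperiment or numeric matrix, features in rows.
#' @param method `"pearson"`, `"spearman"` (average ranks on ties) or
#'   `"bicor"`.
#' @param minObs minimum pairwise-complete observations per pair (>= 3).
#' @param adjust multiple-testing method passed to [adjustPvalues()].
#' @return a [CorrelationSet].
#' @export
correlateAllPairs <- function(x, method = c("pearson", "spearman", "bicor"),
                              minObs = 3L, adjust = c("bh", "bonferroni")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(minObs >= 3)
  m <- .as_exprs(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("F", seq_len(nrow(m)))
  if (nrow(m) < 2) stop("need at least 2 features to correlate")
  feats <- rownames(m)

  n_mat <- crossprod(!is.na(t(m)) * 1)
  if (method %in% c("pearson", "spearman")) {
    r_mat <- suppressWarnings(
      stats::cor(t(m), use = "pairwise.complete.obs", method = method))
  } else {
    r_mat <- .bicor_matrix(m)
  }

  idx <- which(upper.tri(r_mat), arr.ind = TRUE)
  a <- feats[idx[, 1]]; b <- feats[idx[, 2]]
  r <- r_mat[idx]; n <- n_mat[idx]
  ok <- n >= minObs & !is.na(r)
  n_skip <- sum(!ok)
  a <- a[ok]; b <- b[ok]; r <- r[ok]; n <- n[ok]

  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  ord <- order(a, b)
  pairs <- data.frame(feature_a = a[ord], feature_b = b[ord],
                      r = pmax(-1, pmin(1, r[ord])),
                      p = NA_real_, q = NA_real_, n_obs = as.integer(n[ord]),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) stop("no feature pair has enough pairwise-complete observations")
  pairs$p <- correlationPvalue(pairs$r, pairs$n_obs)
  pairs$q <- adjustPvalues(pairs$p, adjust)
  methods::new("CorrelationSet", pairs = pairs, method = method,
               features = feats, nSkippedLowN = as.integer(n_skip))
}

# all-pairs bicor: fast single-pass route on complete data, per-pair
# (median/MAD recomputed on the pairwise-complete subset) otherwise
.bicor_matrix <- function(m) {
  nf <- nrow(m)
  out <- diag(1, nf)
  if (!anyNA(m)) {
    sm <- t(apply(m, 1, function(v) {
      suppressWarnings(.bicor_standardize(v))
    }))
    out <- tcrossprod(sm)
    out[out > 1] <- 1
    out[out < -1] <- -1
    diag(out) <- 1
    return(out)
  }
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      rij <- if (sum(ok) >= 3) {
        tryCatch(suppressWarnings(bicor(m[i, ], m[j, ])),
                 error = function(e) NA_real_)
      } else NA_real_
      out[i, j] <- out[j, i] <- rij
    }
  }
  out
}

#' Subset a CorrelationSet by correlation and q-value cutoffs
#'
#' Keeps pairs with `|r| >= rCut` and `q <= qCut`; the feature universe is
#' retained so downstream connectivity still reports zero-partner
#' features.
#'
#' @param cs a [CorrelationSet].
#' @param rCut absolute-correlation cutoff.
#' @param qCut adjusted-p cutoff.
#' @return a [CorrelationSet] with the passing pairs only.
#' @export
filterPairs <- function(cs, rCut = 0, qCut = 1) {
  p <- cs@pairs
  keep <- abs(p$r) >= rCut & p$q <= qCut
  methods::new("CorrelationSet", pairs = p[keep, , drop = FALSE],
               method = cs@method, features = cs@features,
               nSkippedLowN = cs@nSkippedLowN)
}

#' Correlated-partner counts per feature
#'
#' Number of partners each feature has among pairs passing `|r| >= rCut`
#' and `q <= qCut`. Every feature of the analysis universe appears (count
#' 0 allowed); the counts sum to twice the number of passing pairs.
#'
#' @inheritParams filterPairs
#' @return data.frame `feature, n_partners`, sorted by feature.
#' @export
connectivity <- function(cs, rCut = 0, qCut = 1) {
  p <- pairTable(filterPairs(cs, rCut, qCut))
  feats <- sort(cs@features)
  tab <- table(factor(c(p$feature_a, p$feature_b), levels = feats))
  data.frame(feature = feats, n_partners = as.integer(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
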