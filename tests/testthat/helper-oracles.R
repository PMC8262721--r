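# Independent brute-force oracles, deliberately coded from the textbook
# definitions and kept separate from the package implementations.

# biweight midcorrelation, direct formula
oracle_bicor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  std <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    u <- (v - med) / (9 * madv)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    a <- (v - med) * w
    a / sqrt(sum(a^2))
  }
  sum(std(x) * std(y))
}

# Pearson correlation from the sum formulas
oracle_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Benjamini-Hochberg step-up by explicit sort / cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[ro]
}

# Pearson chi-squared from sum((O-E)^2/E)
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# nested-loop rsID join
oracle_comap_count <- function(qtl_rsids, trait_rsids) {
  n <- 0L
  for (r in qtl_rsids) for (t in trait_rsids) if (r == t) n <- n + 1L
  n
}

# write a data.frame to a temporary csv and return the path
tmp_csv <- function(df, ext = ".csv") {
  f <- tempfile(fileext = ext)
  utils::write.csv(df, f, row.names = FALSE, quote = TRUE, na = "")
  f
}

tiny_qtl <- function() {
  data.frame(
    rsid = paste0("rs", 1:5),
    snp_chrom = c("1", "1", "2", "3", "X"),
    snp_pos = c(500, 1500, 100, 9e6, 2e6),
    gene = paste0("G", 1:5),
    gene_chrom = c("1", "1", "1", "3", "X"),
    gene_start = c(1000, 1000, 5000, 1e6, 1e6),
    gene_end = c(2000, 2000, 6000, 2e6, 3e6),
    significance = c(1e-8, 1e-4, 0.2, 1e-6, 1e-3),
    proxy = c("cis", "cis", "trans", "trans", "cis"),
    stringsAsFactors = FALSE
  )
}

tiny_traits <- function() {
  data.frame(
    rsid = c("rs1", "rs4", "rs9"),
    trait = c("TraitA", "TraitB", "TraitA"),
    snp_chrom = c("1", "3", "5"),
    snp_pos = c(500, 9e6, 1e5),
    significance = c(1e-9, 1e-7, 1e-6),
    group = "gwas",
    stringsAsFactors = FALSE
  )
}
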