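#' Filter QTL records by significance
#'
#' Cut semantics follow the significance kind: p-values keep records with
#' `significance <= cut`, LOD scores keep `significance >= cut`. A single
#' global cut can be refined per proxy class (e.g. a stricter genome-wide
#' threshold for trans than for cis associations); records whose proxy has
#' no dedicated cut fall back to the global one. Idempotent, and
#' kept + dropped = input count (reported via the `filter` attribute).
#'
#' @param qtl QTL data.frame from [readQTLTable()].
#' @param cut global significance cutoff (optional if `perProxyCuts`
#'   covers every proxy present).
#' @param perProxyCuts named numeric, proxy -> cutoff.
#' @return filtered QTL data.frame (attributes preserved, plus `filter`
#'   counts).
#' @export
filterQTL <- function(qtl, cut = NULL, perProxyCuts = NULL) {
  if (is.null(cut) && is.null(perProxyCuts)) {
    stop("no significance cut supplied")
  }
  kind <- attr(qtl, "sigKind")
  if (is.null(kind)) kind <- .detect_sig_kind(qtl$significance)
  eff_cut <- rep(NA_real_, nrow(qtl))
  if (!is.null(cut)) eff_cut[] <- cut
  if (!is.null(perProxyCuts)) {
    hit <- match(qtl$proxy, names(perProxyCuts))
    eff_cut[!is.na(hit)] <- unlist(perProxyCuts)[hit[!is.na(hit)]]
  }
  if (anyNA(eff_cut)) {
    stop("proxy class(es) without a cut and no global cut: ",
         paste(unique(qtl$proxy[is.na(eff_cut)]), collapse = ", "))
  }
  keep <- if (kind == "pvalue") qtl$significance <= eff_cut
          else qtl$significance >= eff_cut
  out <- qtl[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sigKind") <- kind
  attr(out, "filter") <- list(rows_in = nrow(qtl), rows_kept = nrow(out),
                              rows_dropped = nrow(qtl) - nrow(out))
  out
}

#' Classify QTLs as cis or trans by genomic proximity
#'
#' A record is cis iff the SNP lies on the gene's chromosome within the
#' closed interval `[gene_start - window, gene_end + window]`; otherwise
#' trans. The result is stored in a new `computed_proxy` column; any
#' user-supplied `proxy` column is preserved untouched, since the two may
#' legitimately disagree.
#'
#' @param qtl QTL data.frame.
#' @param window flanking distance in location units (default 1e6; with
#'   `window = 0` only SNPs inside the gene body are cis).
#' @return the data.frame with a `computed_proxy` column added.
#' @export
classifyCisTrans <- function(qtl, window = 1e6) {
  stopifnot(window >= 0)
  same_chr <- qtl$snp_chrom == qtl$gene_chrom
  in_win <- qtl$snp_pos >= qtl$gene_start - window &
    qtl$snp_pos <= qtl$gene_end + window
  qtl$computed_proxy <- ifelse(same_chr & in_win, "cis", "trans")
  qtl
}

#' The shipped Sequence Ontology consequence-to-impact table
#'
#' Variant consequence terms from the Ensembl consequence list, each rated
#' HIGH / MODERATE / LOW / MODIFIER in line with the conventions of
#' variant-annotation tools (snpEff-style): HIGH for truncating or
#' function-destroying changes, MODERATE for non-disruptive protein
#' changes, LOW for changes unlikely to alter protein behaviour, MODIFIER
#' for non-coding and regulatory-region variants. The table ships as an
#' editable CSV under `inst/extdata/`.
#'
#' @return named character vector, consequence term -> impact.
#' @export
#' @examples
#' loadImpactMap()["stop_gained"]
loadImpactMap <- function() {
  path <- system.file("extdata", "so_impact_map.csv", package = "coregmap")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$impact, df$consequence)
}

#' Map a variant consequence term to its impact rating
#'
#' @param term Sequence Ontology consequence term(s).
#' @param impactMap named map as from [loadImpactMap()].
#' @return impact rating(s) in HIGH, MODERATE, LOW, MODIFIER; unknown
#'   terms map to MODIFIER with a warning.
#' @export
#' @examples
#' mapConsequenceToImpact("stop_gained")        # HIGH
#' mapConsequenceToImpact("synonymous_variant") # LOW
mapConsequenceToImpact <- function(term, impactMap = loadImpactMap()) {
  out <- unname(impactMap[term])
  unknown <- is.na(out) & !is.na(term) & nzchar(term)
  if (any(unknown)) {
    warning("unknown consequence term(s) mapped to MODIFIER: ",
            paste(unique(term[unknown]), collapse = ", "))
    out[unknown] <- "MODIFIER"
  }
  out
}

#' Annotate QTL records with variant consequences and impacts
#'
#' Joins a local rsID -> consequence lookup onto the records and fills the
#' impact rating via [mapConsequenceToImpact()]. rsIDs absent from the
#' lookup are left unannotated (empty consequence/impact) and counted in
#' the `"nUnannotated"` attribute.
#'
#' @param qtl QTL data.frame.
#' @param lookup data.frame `rsid, consequence` from
#'   [readConsequenceLookup()].
#' @param impactMap consequence -> impact map.
#' @return the data.frame with `consequence` and `impact` columns.
#' @export
annotateVariantConsequences <- function(qtl, lookup,
                                        impactMap = loadImpactMap()) {
  if (!all(c("rsid", "consequence") %in% names(lookup))) {
    stop("malformed lookup: need columns rsid, consequence")
  }
  hit <- match(qtl$rsid, lookup$rsid)
  qtl$consequence <- ifelse(is.na(hit), "", lookup$consequence[hit])
  qtl$impact <- ""
  has <- nzchar(qtl$consequence)
  if (any(has)) qtl$impact[has] <- mapConsequenceToImpact(qtl$consequence[has],
                                                          impactMap)
  attr(qtl, "nUnannotated") <- sum(!has)
  qtl
}

# numeric first, then X, Y, MT, then anything else lexicographically
.chrom_order <- function(chroms) {
  chroms <- unique(chroms)
  num <- suppressWarnings(as.numeric(chroms))
  is_num <- !is.na(num)
  special <- c("X", "Y", "MT")
  sp <- chroms[!is_num & chroms %in% special]
  rest <- chroms[!is_num & !chroms %in% special]
  c(chroms[is_num][order(num[is_num])],
    special[special %in% sp],
    sort(rest))
}

#' Build cumulative genome coordinates from QTL records
#'
#' Chromosome extents are the maximum observed SNP location per chromosome
#' (or supplied lengths); the cumulative offset of each chromosome is the
#' prefix sum of the preceding extents plus padding, giving the single
#' axis used in Manhattan plots.
#'
#' @param qtl QTL data.frame (>= 1 record), or any data.frame with
#'   `snp_chrom` and `snp_pos`.
#' @param padding gap between consecutive chromosomes (>= 0).
#' @param extents optional named numeric of chromosome lengths overriding
#'   the observed maxima.
#' @return a [GenomeLayout].
#' @export
buildGenomeLayout <- function(qtl, padding = 0, extents = NULL) {
  stopifnot(padding >= 0, nrow(qtl) >= 1)
  obs <- tapply(qtl$snp_pos, qtl$snp_chrom, max)
  ext <- stats::setNames(as.numeric(obs), names(obs))
  if (!is.null(extents)) ext[names(extents)] <- as.numeric(extents)
  chroms <- .chrom_order(names(ext))
  ext <- ext[chroms]
  offs <- stats::setNames(cumsum(c(0, utils::head(ext + padding, -1))), chroms)
  methods::new("GenomeLayout", chroms = chroms, extents = ext,
               offsets = offs, padding = padding)
}

#' Cumulative position of a locus under a genome layout
#'
#' @param chrom chromosome label(s).
#' @param pos within-chromosome location(s).
#' @param layout a [GenomeLayout].
#' @return cumulative location(s): `offset(chrom) + pos`.
#' @export
cumulativePosition <- function(chrom, pos, layout) {
  chrom <- .norm_chrom(chrom)
  hit <- match(chrom, layout@chroms)
  if (anyNA(hit)) {
    stop("unknown chromosome(s): ", paste(unique(chrom[is.na(hit)]), collapse = ", "))
  }
  unname(layout@offsets[hit] + pos)
}
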