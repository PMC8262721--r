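#' Detect the on-disk format of an input table
#'
#' Format is chosen by file extension (`.csv`, `.txt`, `.xls`, `.xlsx`);
#' for text files the first line is additionally sniffed so that, e.g., a
#' tab-delimited export saved as `.csv` is still read correctly.
#'
#' @param path path to an existing file.
#' @return One of `"csv"`, `"tsv"`, `"xlsx"`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("id,s1,s2\nG1,1,2", f)
#' detectFormat(f)
detectFormat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("csv", "txt", "xls", "xlsx")) {
    stop("unsupported file extension: .", ext,
         " (expected .csv, .txt, .xls or .xlsx)")
  }
  if (ext %in% c("xls", "xlsx")) return("xlsx")
  if (file.size(path) == 0) stop("empty file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) stop("empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (ext == "csv") {
    if (n_tab > 0 && n_com == 0) "tsv" else "csv"
  } else {
    if (n_com > 0 && n_tab == 0) "csv" else "tsv"
  }
}

# read any supported file into an all-character data.frame
.read_raw_table <- function(path) {
  fmt <- detectFormat(path)
  if (fmt == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    sep <- if (fmt == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", quote = "\"",
                            comment.char = "", na.strings = NULL)
  }
  if (!nrow(df) || ncol(df) < 2) stop("table has no data rows or <2 columns: ", path)
  df
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(unlist(cols), names(df))
  if (length(miss)) {
    stop(what, ": missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
}

#' Read a quantitative expression matrix
#'
#' The first column carries feature identifiers (gene symbols, UniProt
#' accessions or Ensembl gene ids — auto-detected); remaining columns are
#' samples. Blank cells and the tokens `NA`, `NaN`, `nan` (any case) become
#' missing values. Duplicated identifiers are resolved by keeping the row
#' with the fewest missing values (first occurrence on ties), with a
#' warning.
#'
#' @param path file path (CSV/TSV/XLSX).
#' @param mappingTable optional two-column (source_id, gene_symbol) table or
#'   file used to convert UniProt/Ensembl identifiers to gene symbols.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"exprs"`; `metadata()` carries `idType` and an `ingest` count summary
#'   (`rows_in`, `rows_kept`, `rows_dropped`).
#' @export
readExpressionMatrix <- function(path, mappingTable = NULL) {
  df <- .read_raw_table(path)
  ids <- trimws(as.character(df[[1]]))
  vals <- df[-1]
  if (ncol(vals) < 2) stop("expression matrix needs at least 2 samples")
  if (anyDuplicated(names(vals))) stop("duplicate sample names")

  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(NULL, names(vals)))
  for (j in seq_len(ncol(vals))) {
    cv <- .coerce_numeric(vals[[j]])
    if (attr(cv, "n_bad") > 0) {
      stop("non-numeric values in sample column '", names(vals)[j], "': ",
           paste(attr(cv, "bad_values"), collapse = ", "))
    }
    m[, j] <- cv
  }
  rows_in <- nrow(m)
  keep_id <- nzchar(ids) & !.is_missing_token(ids)
  m <- m[keep_id, , drop = FALSE]
  ids <- ids[keep_id]

  sel <- .resolve_duplicates(ids, m)
  m <- m[sel, , drop = FALSE]
  ids <- ids[sel]
  rownames(m) <- ids
  if (nrow(m) < 2) stop("expression matrix needs at least 2 features")

  id_type <- detectIdentifierType(ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m),
    metadata = list(
      idType = id_type,
      ingest = list(rows_in = rows_in, rows_kept = nrow(m),
                    rows_dropped = rows_in - nrow(m))
    )
  )
  if (!is.null(mappingTable)) se <- convertIdentifiers(se, mappingTable)
  se
}

# keep, for each duplicated id, the row with the fewest missing values
# (ties: first occurrence); returns row indices to keep, warns on drops
.resolve_duplicates <- function(ids, m) {
  if (!anyDuplicated(ids)) return(seq_along(ids))
  compl <- rowSums(!is.na(m))
  keep <- vapply(split(seq_along(ids), ids), function(ix) {
    ix[which.max(compl[ix])]
  }, integer(1))
  keep <- sort(unname(keep))
  warning(length(ids) - length(keep),
          " duplicated feature id row(s) dropped (kept highest completeness)")
  keep
}

# extract the numeric matrix from a SummarizedExperiment or pass a matrix
.as_exprs <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "exprs")
  } else if (is.matrix(x)) {
    x
  } else stop("expected a SummarizedExperiment or numeric matrix")
}

.replace_exprs <- function(x, m) {
  if (is(x, "SummarizedExperiment")) {
    out <- x[match(rownames(m), rownames(x)), ]
    SummarizedExperiment::assay(out, "exprs") <- m
    out
  } else m
}

#' Detect the identifier class of a feature id vector
#'
#' A majority vote over up to the first 100 ids: Ensembl gene ids match
#' `ENS...G` + 11 digits, UniProt ids the standard accession pattern, and
#' anything else is treated as a gene symbol. At least 80% of the sampled
#' ids must agree; otherwise the vector falls back to `gene_symbol` with a
#' warning. The vote is permutation-invariant over the sampled ids.
#'
#' @param ids character vector of identifiers (>= 1).
#' @return `"ensembl_gene"`, `"uniprot"` or `"gene_symbol"`.
#' @export
#' @examples
#' detectIdentifierType(c("ENSG00000139618", "ENSG00000141510"))
#' detectIdentifierType(c("P12345", "Q9Y6K9"))
#' detectIdentifierType(c("Actb", "Gapdh"))
detectIdentifierType <- function(ids) {
  if (!length(ids)) stop("at least one identifier required")
  smp <- utils::head(as.character(ids), 100L)
  ens <- grepl("^ENS[A-Z]*G[0-9]{11}$", smp)
  # UniProt accession (6- and 10-character forms)
  uni_re <- paste0(
    "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
  )
  uni <- grepl(uni_re, smp)
  frac <- c(ensembl_gene = mean(ens), uniprot = mean(uni & !ens),
            gene_symbol = mean(!ens & !uni))
  winner <- names(which.max(frac))
  if (frac[[winner]] < 0.8) {
    warning("identifier classes disagree (<80% majority); treating as gene symbols")
    return("gene_symbol")
  }
  winner
}

.read_mapping <- function(mappingTable) {
  if (is.character(mappingTable) && length(mappingTable) == 1 &&
      file.exists(mappingTable)) {
    mappingTable <- .read_raw_table(mappingTable)
  }
  if (!is.data.frame(mappingTable) || ncol(mappingTable) < 2) {
    stop("mapping table must have two columns: source_id, gene_symbol")
  }
  data.frame(source_id = trimws(as.character(mappingTable[[1]])),
             gene_symbol = trimws(as.character(mappingTable[[2]])),
             stringsAsFactors = FALSE)
}

#' Map identifiers to gene symbols
#'
#' Gene-symbol input is returned unchanged. Other identifier classes are
#' looked up in a two-column (source_id, gene_symbol) table; ids absent
#' from the table are retained verbatim and the unmapped count is reported
#' via the `"nUnmapped"` attribute and a message.
#'
#' @param ids character identifiers.
#' @param idType identifier class, as from [detectIdentifierType()].
#' @param mappingTable data.frame or file with columns (source_id,
#'   gene_symbol).
#' @return character vector of gene symbols with attribute `nUnmapped`.
#' @export
mapIdentifiers <- function(ids, idType, mappingTable = NULL) {
  ids <- as.character(ids)
  if (idType == "gene_symbol") {
    attr(ids, "nUnmapped") <- 0L
    return(ids)
  }
  map <- .read_mapping(mappingTable)
  hit <- match(ids, map$source_id)
  out <- ifelse(is.na(hit), ids, map$gene_symbol[hit])
  n_un <- sum(is.na(hit))
  if (n_un) .msg("mapIdentifiers: %d id(s) not in mapping table, kept verbatim", n_un)
  attr(out, "nUnmapped") <- n_un
  out
}

#' Convert the feature identifiers of an expression experiment to symbols
#'
#' Applies [mapIdentifiers()] to the rownames; if mapping introduces
#' duplicate symbols, duplicates are re-resolved by completeness as at
#' ingest.
#'
#' @param se SummarizedExperiment from [readExpressionMatrix()].
#' @param mappingTable two-column (source_id, gene_symbol) table or file.
#' @return SummarizedExperiment with gene-symbol rownames and
#'   `metadata()$idType == "gene_symbol"`.
#' @export
convertIdentifiers <- function(se, mappingTable) {
  id_type <- S4Vectors::metadata(se)$idType
  syms <- mapIdentifiers(rownames(se), id_type, mappingTable)
  m <- .as_exprs(se)
  rownames(m) <- as.character(syms)
  sel <- .resolve_duplicates2(rownames(m), m)
  se <- se[sel, ]
  rownames(se) <- rownames(m)[sel]
  md <- S4Vectors::metadata(se)
  md$idType <- "gene_symbol"
  md$nUnmapped <- attr(syms, "nUnmapped")
  S4Vectors::metadata(se) <- md
  se
}

# duplicate resolution that stays silent when there is nothing to do
.resolve_duplicates2 <- function(ids, m) {
  if (!anyDuplicated(ids)) return(seq_along(ids))
  .resolve_duplicates(ids, m)
}

# default column bindings; overridable so real exports with extra or
# renamed columns still load
.qtl_cols <- function(columns = list()) {
  utils::modifyList(list(
    rsid = "rsid", snp_chrom = "snp_chrom", snp_pos = "snp_pos",
    gene = "gene", gene_chrom = "gene_chrom", gene_start = "gene_start",
    gene_end = "gene_end", significance = "significance", proxy = "proxy"
  ), columns)
}

.trait_cols <- function(columns = list()) {
  utils::modifyList(list(
    rsid = "rsid", trait = "trait", snp_chrom = "snp_chrom",
    snp_pos = "snp_pos", significance = "significance", group = "group"
  ), columns)
}

.detect_sig_kind <- function(sig) {
  if (all(sig >= 0 & sig <= 1, na.rm = TRUE)) "pvalue" else "lod"
}

#' Read an e/pQTL association table
#'
#' Expects the nine documented columns (rsID, SNP chromosome + location,
#' gene name, gene chromosome + start/end, significance, proxy), bound by
#' configurable header names. Rows with missing mandatory fields or with
#' `gene_start > gene_end` are dropped and counted. The significance kind
#' is auto-detected (all values in \[0,1\] = p-values, otherwise LOD) and
#' can be overridden.
#'
#' @param path file path (CSV/TSV/XLSX).
#' @param sigKind `"auto"` (default), `"pvalue"` or `"lod"`.
#' @param columns named list overriding the default column headers.
#' @return data.frame with canonical columns `rsid, snp_chrom, snp_pos,
#'   gene, gene_chrom, gene_start, gene_end, significance, proxy`;
#'   attributes `sigKind` and `ingest` (row counts).
#' @export
readQTLTable <- function(path, sigKind = c("auto", "pvalue", "lod"),
                         columns = list()) {
  sigKind <- match.arg(sigKind)
  cols <- .qtl_cols(columns)
  df <- .read_raw_table(path)
  .require_columns(df, cols, "QTL table")

  out <- data.frame(
    rsid = trimws(df[[cols$rsid]]),
    snp_chrom = .norm_chrom(df[[cols$snp_chrom]]),
    snp_pos = .coerce_numeric(df[[cols$snp_pos]]),
    gene = trimws(df[[cols$gene]]),
    gene_chrom = .norm_chrom(df[[cols$gene_chrom]]),
    gene_start = .coerce_numeric(df[[cols$gene_start]]),
    gene_end = .coerce_numeric(df[[cols$gene_end]]),
    significance = .coerce_numeric(df[[cols$significance]]),
    proxy = trimws(df[[cols$proxy]]),
    stringsAsFactors = FALSE
  )
  rows_in <- nrow(out)
  mandatory_ok <- nzchar(out$rsid) & nzchar(out$gene) &
    nzchar(out$snp_chrom) & nzchar(out$gene_chrom) &
    !is.na(out$snp_pos) & !is.na(out$gene_start) & !is.na(out$gene_end) &
    !is.na(out$significance)
  inv_ok <- !is.na(out$gene_start) & !is.na(out$gene_end) &
    out$gene_start <= out$gene_end
  inv_ok[is.na(inv_ok)] <- FALSE
  n_inverted <- sum(mandatory_ok & !inv_ok)
  if (n_inverted) {
    warning(n_inverted, " row(s) with gene_start > gene_end dropped")
  }
  keep <- mandatory_ok & inv_ok
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL

  if (sigKind == "auto") sigKind <- .detect_sig_kind(out$significance)
  if (sigKind == "pvalue" && any(out$significance < 0 | out$significance > 1)) {
    stop("significance outside [0,1] for sigKind = 'pvalue'")
  }
  if (sigKind == "lod" && any(out$significance < 0)) {
    stop("negative significance: outside both the p-value and LOD ranges")
  }
  attr(out, "sigKind") <- sigKind
  attr(out, "ingest") <- list(rows_in = rows_in, rows_kept = nrow(out),
                              rows_dropped = rows_in - nrow(out))
  out
}

#' Read a trait-association (molQTL/GWAS) table
#'
#' Six-column schema (rsID, trait, SNP chromosome + location, significance,
#' grouping); files in the GWAS-Catalog-export layout with the same six
#' columns load unchanged. Rows with an empty rsID or trait are dropped
#' with a warning; duplicate (rsid, trait) rows are deduplicated keeping
#' the most significant record.
#'
#' @inheritParams readQTLTable
#' @return data.frame with canonical columns `rsid, trait, snp_chrom,
#'   snp_pos, significance, group`; attributes as [readQTLTable()].
#' @export
readTraitTable <- function(path, sigKind = c("auto", "pvalue", "lod"),
                           columns = list()) {
  sigKind <- match.arg(sigKind)
  cols <- .trait_cols(columns)
  df <- .read_raw_table(path)
  .require_columns(df, cols, "trait table")

  out <- data.frame(
    rsid = trimws(df[[cols$rsid]]),
    trait = trimws(df[[cols$trait]]),
    snp_chrom = .norm_chrom(df[[cols$snp_chrom]]),
    snp_pos = .coerce_numeric(df[[cols$snp_pos]]),
    significance = .coerce_numeric(df[[cols$significance]]),
    group = trimws(df[[cols$group]]),
    stringsAsFactors = FALSE
  )
  rows_in <- nrow(out)
  keep <- nzchar(out$rsid) & nzchar(out$trait) & !is.na(out$snp_pos) &
    !is.na(out$significance)
  if (any(!keep)) warning(sum(!keep), " row(s) with missing mandatory fields dropped")
  out <- out[keep, , drop = FALSE]

  if (sigKind == "auto") sigKind <- .detect_sig_kind(out$significance)
  if (sigKind == "lod" && any(out$significance < 0)) {
    stop("negative significance: outside both the p-value and LOD ranges")
  }
  # dedupe (rsid, trait): keep the most significant record
  key <- paste(out$rsid, out$trait, sep = "\r")
  if (anyDuplicated(key)) {
    strength <- if (sigKind == "pvalue") -out$significance else out$significance
    ord <- order(key, -strength)
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(paste(out$rsid, out$trait, sep = "\r")), , drop = FALSE]
    out <- out[order(match(paste(out$rsid, out$trait, sep = "\r"),
                           unique(key))), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "sigKind") <- sigKind
  attr(out, "ingest") <- list(rows_in = rows_in, rows_kept = nrow(out),
                              rows_dropped = rows_in - nrow(out))
  out
}

#' Read a three-column LD-block file
#'
#' Columns: chromosome, start, end. Blocks are validated (start <= end; no
#' overlap between blocks on the same chromosome — an error, since block
#' membership must be unambiguous) and returned sorted by (chrom, start).
#' Chromosome labels should use the same dialect as the QTL tables; a
#' leading `chr` prefix is stripped for matching.
#'
#' @param path file path.
#' @return data.frame `chrom, start, end`, sorted.
#' @export
readLDBlocks <- function(path) {
  df <- .read_raw_table(path)
  if (ncol(df) < 3) stop("LD-block file needs 3 columns: chrom, start, end")
  out <- data.frame(
    chrom = .norm_chrom(df[[1]]),
    start = .coerce_numeric(df[[2]]),
    end = .coerce_numeric(df[[3]]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start) | is.na(out$end))) stop("non-numeric LD-block bounds")
  if (any(out$start > out$end)) stop("LD block with start > end")
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  for (ch in unique(out$chrom)) {
    b <- out[out$chrom == ch, , drop = FALSE]
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("overlapping LD blocks on chromosome ", ch)
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a pairwise interaction reference (STRING/BioPlex-style extract)
#'
#' Two or three columns: member_a, member_b and an optional numeric score.
#' Pairs are canonicalised (member_a < member_b), self-pairs and duplicate
#' pairs are dropped with a message.
#'
#' @param path file path, or a data.frame in the same layout.
#' @param name reference name used as the annotation flag.
#' @return a [ReferenceSet].
#' @export
readPairReference <- function(path, name) {
  df <- if (is.data.frame(path)) path else .read_raw_table(path)
  a <- trimws(as.character(df[[1]]))
  b <- trimws(as.character(df[[2]]))
  score <- if (ncol(df) >= 3) .coerce_numeric(df[[3]]) else rep(NA_real_, length(a))
  keep <- nzchar(a) & nzchar(b) & a != b
  n_self <- sum(nzchar(a) & nzchar(b) & a == b)
  if (n_self) .msg("readPairReference: %d self-pair(s) dropped", n_self)
  pr <- data.frame(member_a = pmin(a[keep], b[keep]),
                   member_b = pmax(a[keep], b[keep]),
                   score = as.numeric(score)[keep],
                   stringsAsFactors = FALSE)
  dup <- duplicated(paste(pr$member_a, pr$member_b, sep = "\r"))
  if (any(dup)) .msg("readPairReference: %d duplicate pair(s) dropped", sum(dup))
  pr <- pr[!dup, , drop = FALSE]
  rownames(pr) <- NULL
  methods::new("ReferenceSet", name = name, pairs = pr, complexes = list())
}

#' Read a complex-style reference (CORUM-like member list)
#'
#' Two columns: complex_id, member. Each complex of size k contributes all
#' C(k,2) within-complex pairs to the pairwise view used for flagging.
#'
#' @inheritParams readPairReference
#' @return a [ReferenceSet] with the `complexes` slot filled.
#' @export
readComplexReference <- function(path, name) {
  df <- if (is.data.frame(path)) path else .read_raw_table(path)
  cid <- trimws(as.character(df[[1]]))
  mem <- trimws(as.character(df[[2]]))
  keep <- nzchar(cid) & nzchar(mem)
  cplx <- lapply(split(mem[keep], cid[keep]), function(x) sort(unique(x)))
  pair_rows <- lapply(cplx, function(members) {
    if (length(members) < 2) return(NULL)
    cmb <- utils::combn(members, 2)
    data.frame(member_a = cmb[1, ], member_b = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  pr <- do.call(rbind, c(pair_rows, list(
    data.frame(member_a = character(), member_b = character()))))
  pr <- pr[!duplicated(paste(pr$member_a, pr$member_b, sep = "\r")), , drop = FALSE]
  pr$score <- NA_real_
  rownames(pr) <- NULL
  methods::new("ReferenceSet", name = name, pairs = pr, complexes = cplx)
}

#' Read subcellular-localisation and ontology-parent tables
#'
#' `locPath`: two columns (feature, compartment term). `parentPath`: two
#' columns (term, parent term) describing an acyclic is-part-of/is-a
#' hierarchy used by [propagateLocalizations()] to add ancestor
#' compartments.
#'
#' @param locPath feature-to-term file or data.frame.
#' @param parentPath term-to-parent file or data.frame (optional).
#' @return a `LocalizationTable`: list with `loc` (named list of term sets
#'   per feature) and `parents` (named list of parent sets per term).
#' @export
readLocalizations <- function(locPath, parentPath = NULL) {
  df <- if (is.data.frame(locPath)) locPath else .read_raw_table(locPath)
  feat <- trimws(as.character(df[[1]]))
  term <- trimws(as.character(df[[2]]))
  keep <- nzchar(feat) & nzchar(term)
  loc <- lapply(split(term[keep], feat[keep]), function(x) sort(unique(x)))
  parents <- list()
  if (!is.null(parentPath)) {
    pf <- if (is.data.frame(parentPath)) parentPath else .read_raw_table(parentPath)
    tt <- trimws(as.character(pf[[1]]))
    pp <- trimws(as.character(pf[[2]]))
    k2 <- nzchar(tt) & nzchar(pp)
    parents <- lapply(split(pp[k2], tt[k2]), function(x) sort(unique(x)))
  }
  structure(list(loc = loc, parents = parents, propagated = FALSE),
            class = "LocalizationTable")
}

#' @export
print.LocalizationTable <- function(x, ...) {
  cat("LocalizationTable:", length(x$loc), "features,",
      length(unique(unlist(x$loc))), "terms,",
      length(x$parents), "parent links",
      if (isTRUE(x$propagated)) "(ancestors propagated)" else "", "\n")
  invisible(x)
}

#' Read a drug–gene interaction table
#'
#' Two columns (gene, drug), in the layout of DGIdb-style extracts. Drug
#' order within a gene is preserved from the file.
#'
#' @param path file path or data.frame.
#' @return data.frame `gene, drug`.
#' @export
readDrugTable <- function(path) {
  df <- if (is.data.frame(path)) path else .read_raw_table(path)
  out <- data.frame(gene = trimws(as.character(df[[1]])),
                    drug = trimws(as.character(df[[2]])),
                    stringsAsFactors = FALSE)
  out <- out[nzchar(out$gene) & nzchar(out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a local rsID-to-consequence lookup table
#'
#' Two columns (rsid, Sequence Ontology consequence term), standing in for
#' a variant-annotation database.
#'
#' @param path file path or data.frame.
#' @return data.frame `rsid, consequence`.
#' @export
readConsequenceLookup <- function(path) {
  df <- if (is.data.frame(path)) path else .read_raw_table(path)
  if (ncol(df) < 2) stop("malformed consequence lookup: need rsid, consequence")
  out <- data.frame(rsid = trimws(as.character(df[[1]])),
                    consequence = trimws(as.character(df[[2]])),
                    stringsAsFactors = FALSE)
  out <- out[nzchar(out$rsid) & nzchar(out$consequence), , drop = FALSE]
  out <- out[!duplicated(out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validation summary of an ingested object
#'
#' Row-count bookkeeping recorded at ingest: rows read, kept and dropped
#' (rows_in = rows_kept + rows_dropped).
#'
#' @param x an object from [readExpressionMatrix()], [readQTLTable()] or
#'   [readTraitTable()].
#' @return one-row data.frame `rows_in, rows_kept, rows_dropped`.
#' @export
ingestSummary <- function(x) {
  s <- if (is(x, "SummarizedExperiment")) S4Vectors::metadata(x)$ingest
       else attr(x, "ingest")
  if (is.null(s)) stop("object carries no ingest summary")
  data.frame(rows_in = s$rows_in, rows_kept = s$rows_kept,
             rows_dropped = s$rows_dropped)
}
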