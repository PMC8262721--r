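# internal helpers shared across modules

MISSING_TOKENS <- c("", "na", "nan")

.is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% MISSING_TOKENS
}

# numeric coercion that treats the documented missing tokens as NA and
# errors (via attr) on anything else non-numeric
.coerce_numeric <- function(x) {
  x_chr <- trimws(as.character(x))
  miss <- .is_missing_token(x_chr)
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- !miss & is.na(out)
  attr(out, "n_bad") <- sum(bad)
  attr(out, "bad_values") <- utils::head(unique(x_chr[bad]), 3)
  out[miss] <- NA_real_
  out
}

# strip a leading "chr" prefix; chromosome labels are otherwise opaque
.norm_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", trimws(as.character(x)))
}

# canonical unordered pair key
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# run an expression under a temporary RNG state set from `seed`
# (NULL seed = use the current stream)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# deterministic CSV writer used for all exports
.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

.read_csv_plain <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
}

.stop_stage <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

.msg <- function(...) message(sprintf(...))
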