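#' Derive a deterministic substream seed for a named stage
#'
#' Each pipeline stage draws from its own stream so that adding probes to the
#' methylation stage, say, does not shift the glycan peak draws. The substream
#' seed is a deterministic function of the master seed and the stage name and
#' stays below 2^31.
#'
#' @param seed master integer seed
#' @param stage character stage label
#' @return an integer seed
#' @export
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 1000003 * h) %% 2147483647L)
}

#' Read a tab-separated table
#'
#' @param path file path
#' @return data.frame, strings kept as character, names untouched
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = "")
}

#' Write a tab-separated table
#'
#' Missing values are written as empty fields.
#'
#' @param x data.frame
#' @param path file path
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Format an estimate with its interval as `0.70[0.64,0.75]`
#' @param est,lo,hi estimate and interval bounds
#' @param digits decimal places
#' @return character vector
#' @export
format_ci <- function(est, lo, hi, digits = 2) {
  ifelse(is.na(est), "",
         sprintf("%.*f[%.*f,%.*f]", digits, est, digits, lo, digits, hi))
}

#' Format p-values, using `1.19x10^-9` style scientific notation when small
#' @param p numeric vector of p-values
#' @param sci_below switch to scientific notation below this value
#' @param digits significant digits
#' @return character vector
#' @export
format_pval <- function(p, sci_below = 1e-4, digits = 2) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi >= sci_below) return(sprintf("%.*g", max(digits, 2), pi))
    e <- floor(log10(pi))
    m <- pi / 10^e
    sprintf("%.*gx10^%d", digits + 1, m, as.integer(e))
  }, character(1))
}

# matrix (rownames = sample ids) -> data.frame with a sample_id key column
matrix_to_table <- function(m, key = "sample_id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- key
  df
}

# shallow merge of defaults and overrides (no recursion into data.frames)
merge_defaults <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

# inverse of matrix_to_table
table_to_matrix <- function(df, key = "sample_id") {
  m <- as.matrix(df[, setdiff(names(df), key), drop = FALSE])
  rownames(m) <- as.character(df[[key]])
  m
}
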