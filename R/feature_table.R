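#' Write / read a window feature table
#'
#' CSV with key columns `subject`, `label`, `L`, `start`, `weak_side`
#' followed by one column per feature. Numeric values are written with
#' full double precision (`%.17g`), so a write/read round trip is
#' value-exact.
#'
#' @param tab feature table data.frame (all rows must share one feature-name
#'   set, which they do by construction).
#' @param path output CSV path.
#' @return `write_feature_table()`: `path` invisibly;
#'   `read_feature_table()`: the table.
#' @export
write_feature_table <- function(tab, path) {
  key <- c("subject", "label", "L", "start", "weak_side")
  if (nrow(tab) == 0L) {
    writeLines(paste(c(key, setdiff(colnames(tab), key)), collapse = ","), path)
    return(invisible(path))
  }
  missing_key <- setdiff(key, colnames(tab))
  if (length(missing_key))
    stop("schema error: feature table lacks key column(s): ",
         paste(missing_key, collapse = ", "))
  feats <- setdiff(colnames(tab), key)
  tab <- tab[, c(key, feats), drop = FALSE]
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) sprintf("%.17g", col)
    else as.character(col)
  }
  body <- do.call(paste, c(lapply(tab, fmt), sep = ","))
  writeLines(c(paste(colnames(tab), collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject = "character"))
  key <- c("subject", "label", "L", "start", "weak_side")
  missing_key <- setdiff(key, colnames(df))
  if (length(missing_key))
    stop("schema error: feature table lacks key column(s): ",
         paste(missing_key, collapse = ", "))
  df
}
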