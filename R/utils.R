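# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

bep_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "bep_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

bep_validation_error <- function(msg, ...) bep_stop(msg, "bep_validation_error", ...)
bep_capacity_error   <- function(msg, ...) bep_stop(msg, "bep_capacity_error", ...)
bep_config_error     <- function(msg, ...) bep_stop(msg, "bep_config_error", ...)
bep_data_error       <- function(msg, ...) bep_stop(msg, "bep_data_error", ...)

#' Hamming distance between equal-length strings
#'
#' Position-wise mismatch count. `b` may be a vector; `a` is recycled against
#' it element-wise only when lengths match, otherwise `a` must be scalar.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @keywords internal
hamming <- function(a, b) {
  if (length(a) == 1L) a <- rep(a, length(b))
  stopifnot(length(a) == length(b))
  mapply(function(x, y) {
    if (nchar(x) != nchar(y)) {
      bep_validation_error("hamming distance requires equal lengths (%d vs %d)",
                           nchar(x), nchar(y))
    }
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

# Distance from each query string to each of the reference strings; queries
# and refs must share one length. Returns a length(queries) x length(refs)
# integer matrix. Vectorised over characters for speed.
hamming_to_refs <- function(queries, refs) {
  k <- unique(nchar(refs))
  if (length(k) != 1L) bep_validation_error("reference barcodes must share one length")
  qmat <- matrix(unlist(strsplit(queries, "", fixed = TRUE), use.names = FALSE),
                 nrow = length(queries), byrow = TRUE)
  out <- matrix(0L, nrow = length(queries), ncol = length(refs))
  for (j in seq_along(refs)) {
    rchars <- strsplit(refs[j], "", fixed = TRUE)[[1]]
    out[, j] <- as.integer(rowSums(qmat != matrix(rchars, nrow = length(queries),
                                                  ncol = k, byrow = TRUE)))
  }
  out
}

str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_dna <- function(x) all(str_chars(x) %in% DNA_BASES)

# Write a data.frame as headered TSV, deterministically (no row names, fixed
# quoting). Shared output convention for all table artifacts.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    ...)
}
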