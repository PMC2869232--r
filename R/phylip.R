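#' Write a square PHYLIP distance matrix
#'
#' Classic format: a count line, then one row per taxon with the label
#' truncated or padded to 10 characters followed by the distances to 6
#' decimal places. With `relaxed = TRUE` labels are kept whole and
#' separated from the values by whitespace (the widely accepted relaxed
#' PHYLIP convention, needed when genome ids exceed 10 characters).
#'
#' @param dm A `dl_distmat` or labelled symmetric numeric matrix.
#' @param path Output path.
#' @param relaxed Keep full labels instead of the 10-character field.
#' @export
write_phylip <- function(dm, path, relaxed = FALSE) {
  m <- as.matrix(unclass(dm))
  labs <- rownames(m)
  if (is.null(labs)) stop("distance matrix must be labelled")
  if (!relaxed) {
    labs <- formatC(substr(labs, 1, 10), width = -10)
    if (anyDuplicated(labs)) stop("labels collide after 10-char truncation; ",
                                  "use relaxed = TRUE")
  }
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(labs[i], if (relaxed) "  " else "",
           paste(sprintf("%.6f", m[i, ]), collapse = "  "))
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix
#'
#' Accepts the classic and relaxed square formats (label followed by n
#' numeric values per row; rows may wrap onto continuation lines).
#'
#' @param path Path to a PHYLIP distance file.
#' @return Labelled symmetric numeric matrix.
#' @export
read_phylip <- function(path) {
  if (!file.exists(path)) stop("PHYLIP file not found: ", path)
  toks <- scan(path, what = character(), quiet = TRUE)
  n <- suppressWarnings(as.integer(toks[1]))
  if (is.na(n) || n < 2) stop("invalid PHYLIP header")
  toks <- toks[-1]
  if (length(toks) != n * (n + 1)) stop("malformed PHYLIP matrix body")
  labs <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    off <- (i - 1L) * (n + 1L)
    labs[i] <- toks[off + 1L]
    m[i, ] <- as.numeric(toks[off + 1L + seq_len(n)])
  }
  if (anyNA(m)) stop("non-numeric entries in PHYLIP matrix")
  dimnames(m) <- list(labs, labs)
  m
}
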