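# K-string counting by sliding window. Windows are taken within each
# sequence independently (no window ever spans two genes or replicons) and
# any window containing a non-alphabet character is skipped and excluded
# from the denominator, so frequencies still sum to 1.

count_core <- function(seqs, K, alphabet) {
  size <- alphabet$size
  parts <- vector("list", length(seqs))
  for (j in seq_along(seqs)) {
    codes <- letter_codes(seqs[j], alphabet)
    L <- length(codes)
    if (L < K) next
    nw <- L - K + 1L
    idx <- numeric(nw)
    for (i in seq_len(K)) idx <- idx * size + codes[i:(i + nw - 1L)]
    parts[[j]] <- idx[!is.na(idx)]  # NA propagates from invalid characters
  }
  idx <- sort(as.numeric(unlist(parts)))
  r <- rle(idx)
  list(idx = as.numeric(r$values), counts = as.numeric(r$lengths),
       valid_windows = length(idx))
}

#' Count K-strings in a genome
#'
#' Slides a window of length `K` one position at a time through every
#' sequence of the genome and counts occurrences of each K-string. Counts
#' from multiple sequences (genes, replicons) are pooled; a sequence shorter
#' than `K` contributes zero windows.
#'
#' @param genome A `genome_record`, or a character vector of sequences (then
#'   `alphabet` must be given).
#' @param K String length, `K >= 1`.
#' @param alphabet Alphabet override for raw character input.
#' @return A `kmer_counts` object: `genome_id`, `K`, `alphabet`, sorted
#'   0-based string indices `idx` with occurrence `counts`, and
#'   `valid_windows` (the number of counted windows; equals
#'   `sum(L_j - K + 1)` when no invalid characters are present).
#' @examples
#' count_kmers("ACGT", K = 2, alphabet = dna_alphabet())  # AC, CG, GT
#' @export
count_kmers <- function(genome, K, alphabet = NULL) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("K must be a positive integer")
  if (inherits(genome, "genome_record")) {
    seqs <- genome$sequences
    alphabet <- genome$alphabet
    id <- genome$genome_id
  } else {
    if (is.null(alphabet)) stop("alphabet required for raw sequence input")
    seqs <- toupper(as.character(genome))
    id <- "genome"
  }
  cc <- count_core(seqs, as.integer(K), alphabet)
  if (cc$valid_windows == 0L)
    warning("no countable windows at K = ", K, " for genome ", id)
  structure(list(genome_id = id, K = as.integer(K), alphabet = alphabet,
                 idx = cc$idx, counts = cc$counts,
                 valid_windows = cc$valid_windows),
            class = "kmer_counts")
}

#' Pooled K-string counts over a genome's gene set
#'
#' The multi-gene form of the observed frequency: occurrence counts and
#' window counts are summed over the genome's `m` sequences, giving
#' frequency `(sum_j n_j) / (sum_j (L_j - K + 1))` downstream. Identical to
#' [count_kmers()] on the full record; exposed under the pooled name to
#' mirror the pooled-frequency formula.
#'
#' @inheritParams count_kmers
#' @return A `kmer_counts`.
#' @export
pooled_counts <- function(genome, K) {
  stopifnot(inherits(genome, "genome_record"))
  count_kmers(genome, K)
}

#' Convert counts to observed frequencies
#'
#' `p(w) = n(w) / valid_windows`; the frequencies over all K-strings sum
#' to 1. Zero-frequency strings are implicit (absent keys).
#'
#' @param counts A `kmer_counts` with `valid_windows > 0`.
#' @return A `freq_table`: fields `genome_id`, `K`, `alphabet`, sorted
#'   indices `idx`, strictly positive `freqs`, and `valid_windows`.
#' @export
to_frequencies <- function(counts) {
  stopifnot(inherits(counts, "kmer_counts"))
  if (counts$valid_windows == 0L)
    stop("no countable windows for genome ", counts$genome_id,
         " at K = ", counts$K)
  structure(list(genome_id = counts$genome_id, K = counts$K,
                 alphabet = counts$alphabet, idx = counts$idx,
                 freqs = counts$counts / counts$valid_windows,
                 valid_windows = counts$valid_windows),
            class = "freq_table")
}

# Frequency lookup by 0-based index; absent keys are zero.
freq_at <- function(ft, idx) {
  m <- match(idx, ft$idx)
  out <- ft$freqs[m]
  out[is.na(m)] <- 0
  out
}

#' K-mer labels of a counts or frequency object
#' @param x A `kmer_counts` or `freq_table`.
#' @return Character vector of K-strings in canonical (alphabetical) order.
#' @export
kmer_labels <- function(x) index_to_kmer(x$idx, x$K, x$alphabet)

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<k-mer counts %s: K=%d, %d distinct strings, %d windows>\n",
              x$genome_id, x$K, length(x$idx), x$valid_windows))
  invisible(x)
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<k-mer frequencies %s: K=%d, %d nonzero of %g strings>\n",
              x$genome_id, x$K, length(x$idx), x$alphabet$size^x$K))
  invisible(x)
}

#' @export
as.data.frame.freq_table <- function(x, ...) {
  data.frame(kmer = kmer_labels(x),
             count = x$freqs * x$valid_windows,
             freq = x$freqs, stringsAsFactors = FALSE)
}

#' Write a frequency table as TSV
#'
#' Columns `kmer`, `count`, `freq`; rows in alphabetical k-mer order.
#'
#' @param ft A `freq_table`.
#' @param path Output path.
#' @export
write_freq_tsv <- function(ft, path) {
  utils::write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
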