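# Independent brute-force oracles, written from the definitions only; they
# share no code with the package internals (string-keyed named vectors,
# naive substring extraction).

# Naive sliding-window counts: extract every window as a substring, skip
# windows containing characters outside `letters`.
naive_counts <- function(seqs, K, letters) {
  counts <- integer(0)
  valid <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < K) next
    for (i in seq_len(L - K + 1L)) {
      w <- substr(s, i, i + K - 1L)
      if (grepl(sprintf("[^%s]", paste(letters, collapse = "")), w)) next
      valid <- valid + 1L
      counts[w] <- if (is.na(counts[w])) 1L else counts[w] + 1L
    }
  }
  list(counts = counts, valid_windows = valid)
}

naive_freqs <- function(seqs, K, letters) {
  nc <- naive_counts(seqs, K, letters)
  nc$counts / nc$valid_windows
}

all_kmers <- function(K, letters) {
  g <- do.call(expand.grid,
               c(replicate(K, letters, simplify = FALSE),
                 list(stringsAsFactors = FALSE)))
  sort(do.call(paste0, g))
}

lookup0 <- function(tbl, keys) {
  v <- tbl[keys]
  v[is.na(v)] <- 0
  unname(v)
}

# Dense denoised vector over all N k-mers, straight from the definitions:
# p from naive counts, q = [p(prefix) p(last) + p(first) p(suffix)]/2,
# X = p/q - 1 where q > 0 else 0.
naive_dense_x <- function(seqs, K, letters) {
  pK <- naive_freqs(seqs, K, letters)
  pKm1 <- naive_freqs(seqs, K - 1L, letters)
  p1 <- naive_freqs(seqs, 1L, letters)
  km <- all_kmers(K, letters)
  q <- (lookup0(pKm1, substr(km, 1, K - 1)) * lookup0(p1, substr(km, K, K)) +
          lookup0(p1, substr(km, 1, 1)) * lookup0(pKm1, substr(km, 2, K))) / 2
  p <- lookup0(pK, km)
  x <- numeric(length(km))
  nz <- q > 0
  x[nz] <- p[nz] / q[nz] - 1
  x
}

naive_cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

random_seq <- function(L, letters, seed) {
  set.seed(seed)
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

random_unit <- function(dim) {
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

# A random additive distance matrix: path lengths on a random tree.
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 2))
  list(tree = tr, D = stats::cophenetic(tr)[tr$tip.label, tr$tip.label])
}
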