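# Background subtraction. A K-string s1..sK can arise by appending sK to
# the (K-1)-string s1..s(K-1) or prepending s1 to s2..sK, so its expected
# frequency under the dynamical-language background model is
#   q(s1..sK) = [ p(s1..s(K-1)) p(sK) + p(s1) p(s2..sK) ] / 2,
# with the (K-1)-string and single-letter frequencies each measured by
# their own sliding-window pass over the same sequences. The denoised
# component is X = p/q - 1 where q > 0, and 0 where q = 0.

#' Expected background frequency of one K-string
#'
#' @param w A K-string (`K >= 2`).
#' @param p_km1 `freq_table` at length `K - 1` for the same genome.
#' @param p_1 `freq_table` at length 1 for the same genome.
#' @return The model frequency `q(w)` in `[0, 1]`; exactly 0 when both
#'   additive terms vanish.
#' @export
expected_frequency <- function(w, p_km1, p_1) {
  K <- nchar(w)
  if (K < 2) stop("the background model needs K >= 2")
  stopifnot(inherits(p_km1, "freq_table"), inherits(p_1, "freq_table"),
            p_km1$K == K - 1L, p_1$K == 1L,
            identical(p_km1$genome_id, p_1$genome_id))
  a <- p_km1$alphabet
  prefix <- freq_at(p_km1, kmer_to_index(substr(w, 1L, K - 1L), a))
  suffix <- freq_at(p_km1, kmer_to_index(substr(w, 2L, K), a))
  first <- freq_at(p_1, kmer_to_index(substr(w, 1L, 1L), a))
  last <- freq_at(p_1, kmer_to_index(substr(w, K, K), a))
  (prefix * last + first * suffix) / 2
}

#' Denoised composition vector of a genome
#'
#' Computes observed frequencies at lengths `K`, `K - 1` and 1 by
#' independent sliding-window passes, predicts the background `q` for every
#' string it can be nonzero on, and forms `X = p/q - 1` (or 0 where
#' `q = 0`). The vector is stored sparsely with an explicit partition of the
#' `N = size^K` index set:
#' * `S` — strings with `p > 0` (hence `q > 0`): `X = p/q - 1 > -1`;
#' * `Z` — strings with `q > 0` but `p = 0`: `X = -1`;
#' * everything else — `q = 0`: `X = 0` (implicit).
#'
#' @param genome A `genome_record`.
#' @param K String length, `K >= 2`.
#' @return A `composition_vector` with fields `genome_id`, `K`, `alphabet`,
#'   `N`, and the `S` block (`idx`, `p`, `q`, `x`) plus `z_idx`.
#' @export
composition_vector <- function(genome, K) {
  stopifnot(inherits(genome, "genome_record"))
  if (K < 2) stop("composition vectors need K >= 2 (background model)")
  pK <- to_frequencies(count_kmers(genome, K))
  pKm1 <- to_frequencies(count_kmers(genome, K - 1L))
  p1 <- to_frequencies(count_kmers(genome, 1L))
  a <- genome$alphabet
  size <- a$size
  hi <- size^(K - 1)

  # q is nonzero exactly on (observed (K-1)-prefix x observed letter) union
  # (observed letter x observed (K-1)-suffix)
  q_idx <- sort(unique(c(
    as.vector(outer(pKm1$idx * size, p1$idx, "+")),
    as.vector(outer(p1$idx * hi, pKm1$idx, "+")))))
  q <- (freq_at(pKm1, q_idx %/% size) * freq_at(p1, q_idx %% size) +
          freq_at(p1, q_idx %/% hi) * freq_at(pKm1, q_idx %% hi)) / 2

  s_pos <- match(pK$idx, q_idx)
  # every observed K-window has an observed (K-1)-prefix and first letter
  stopifnot(!anyNA(s_pos))
  q_s <- q[s_pos]
  x_s <- pK$freqs / q_s - 1
  z_keep <- is.na(match(q_idx, pK$idx))
  structure(list(genome_id = genome$genome_id, K = as.integer(K),
                 alphabet = a, N = size^K,
                 idx = pK$idx, p = pK$freqs, q = q_s, x = x_s,
                 z_idx = q_idx[z_keep], z_q = q[z_keep]),
            class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf(
    "<composition vector %s: K=%d, N=%g, |S|=%d, |Z|=%d>\n",
    x$genome_id, x$K, x$N, length(x$idx), length(x$z_idx)))
  invisible(x)
}

#' Expand a composition vector to its dense form
#'
#' Returns the full length-`N` vector in canonical alphabetical string
#' order. Intended for small `N` (tests, DNA alphabets); refuses absurd
#' expansions.
#'
#' @param cv A `composition_vector`.
#' @param max_n Guard on `N`.
#' @return Numeric vector of length `N`.
#' @export
as_dense <- function(cv, max_n = 2^24) {
  stopifnot(inherits(cv, "composition_vector"))
  if (cv$N > max_n) stop("dense expansion of N = ", cv$N, " refused")
  out <- numeric(cv$N)
  out[cv$idx + 1] <- cv$x
  out[cv$z_idx + 1] <- -1
  out
}

#' @export
as.data.frame.composition_vector <- function(x, ...) {
  ord <- order(c(x$idx, x$z_idx))
  data.frame(kmer = index_to_kmer(c(x$idx, x$z_idx), x$K, x$alphabet)[ord],
             p = c(x$p, numeric(length(x$z_idx)))[ord],
             q = c(x$q, x$z_q)[ord],
             x = c(x$x, rep(-1, length(x$z_idx)))[ord],
             stringsAsFactors = FALSE)
}

#' Mean of X over all strings: the K-selection diagnostic
#'
#' The mean of the denoised component over all `N` possible K-strings
#' (structural zeros included). As K grows the observed frequencies are
#' increasingly well predicted by the background model and the mean
#' approaches zero; the smallest K where it levels off near zero is the
#' recommended string length (in practice 6--7 for protein sequences,
#' 11--12 for whole DNA).
#'
#' @param genome A `genome_record`.
#' @param K_values Integer vector of string lengths, each `>= 2`.
#' @return Data.frame with columns `K` and `mean_x`, ascending in `K`.
#' @export
mean_x_profile <- function(genome, K_values) {
  K_values <- sort(unique(as.integer(K_values)))
  if (any(K_values < 2)) stop("the background model needs K >= 2")
  mx <- vapply(K_values, function(K) {
    cv <- composition_vector(genome, K)
    (sum(cv$x) - length(cv$z_idx)) / cv$N
  }, numeric(1))
  data.frame(K = K_values, mean_x = mx)
}

#' Write nonzero composition-vector entries as TSV
#'
#' Columns `kmer`, `p`, `q`, `x` for the S and Z strings, in alphabetical
#' k-mer order.
#'
#' @param cv A `composition_vector`.
#' @param path Output path.
#' @export
write_vector_tsv <- function(cv, path) {
  utils::write.table(as.data.frame(cv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
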