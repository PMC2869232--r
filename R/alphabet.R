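#' Sequence alphabets
#'
#' The method works over a fixed, alphabetically ordered alphabet: the 4 DNA
#' nucleotides or the 20 standard amino acids. The ordering defines the
#' canonical index of every K-string, so the length-`N = size^K` composition
#' vector has a well-defined component order.
#'
#' @return An object of class `dl_alphabet` with fields `name`, `letters`
#'   (ordered, uppercase, unique) and `size`.
#' @examples
#' dna_alphabet()$size     # 4
#' protein_alphabet()$size # 20
#' @export
dna_alphabet <- function() {
  new_alphabet("DNA", c("A", "C", "G", "T"))
}

#' @rdname dna_alphabet
#' @export
protein_alphabet <- function() {
  new_alphabet("PROTEIN", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
}

new_alphabet <- function(name, letters) {
  stopifnot(!anyDuplicated(letters), identical(letters, toupper(letters)))
  structure(list(name = name, letters = letters, size = length(letters)),
            class = "dl_alphabet")
}

#' @export
print.dl_alphabet <- function(x, ...) {
  cat(sprintf("<%s alphabet: %s (size %d)>\n",
              x$name, paste(x$letters, collapse = ""), x$size))
  invisible(x)
}

#' Resolve an alphabet from a mode flag
#'
#' Analysis modes: `WHOLE_DNA` (whole genome sequences, one or more
#' replicons), `CDS_DNA` (protein-coding DNA sequences, one per gene) and
#' `PROTEIN` (amino-acid sequences, one per gene). The first two use the DNA
#' alphabet.
#'
#' @param mode One of `"WHOLE_DNA"`, `"CDS_DNA"`, `"PROTEIN"`.
#' @return A `dl_alphabet`.
#' @export
alphabet_for_mode <- function(mode) {
  mode <- match.arg(mode, c("WHOLE_DNA", "CDS_DNA", "PROTEIN"))
  if (mode == "PROTEIN") protein_alphabet() else dna_alphabet()
}

# Map a character string to 0-based letter codes; non-alphabet characters
# (N, IUPAC ambiguity codes, X, *, gaps) become NA and are treated as
# invalid-window markers downstream -- they are never deleted, which would
# create artificial junction K-strings.
letter_codes <- function(seq, alphabet) {
  match(strsplit(seq, "", fixed = TRUE)[[1]], alphabet$letters) - 1L
}

# Encode K-strings as 0-based integers in base `size` (stored as doubles;
# exact for all N = size^K used here since N < 2^53).
kmer_to_index <- function(kmers, alphabet) {
  K <- unique(nchar(kmers))
  stopifnot(length(K) == 1L)
  idx <- numeric(length(kmers))
  for (pos in seq_len(K)) {
    d <- match(substr(kmers, pos, pos), alphabet$letters) - 1
    if (anyNA(d)) stop("k-mer contains non-alphabet characters")
    idx <- idx * alphabet$size + d
  }
  idx
}

index_to_kmer <- function(idx, K, alphabet) {
  if (length(idx) == 0L) return(character(0))
  out <- matrix("", nrow = length(idx), ncol = K)
  rem <- idx
  for (pos in K:1) {
    d <- rem %% alphabet$size
    out[, pos] <- alphabet$letters[d + 1]
    rem <- (rem - d) / alphabet$size
  }
  do.call(paste0, split(out, col(out)))
}
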