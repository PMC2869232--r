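#' Composition vectors for a set of genomes
#'
#' @param genomes List of `genome_record`s.
#' @param K String length, `>= 2`.
#' @return Named list of `composition_vector`s.
#' @export
composition_vectors <- function(genomes, K) {
  out <- lapply(genomes, composition_vector, K = K)
  names(out) <- vapply(out, function(v) v$genome_id, character(1))
  out
}

#' Full pipeline: genomes to NJ tree
#'
#' Counts K-strings, denoises, computes the pairwise distance matrix under
#' the chosen metric and builds the neighbor-joining tree.
#'
#' @inheritParams composition_vectors
#' @inheritParams distance_matrix
#' @inheritParams neighbor_joining
#' @return An `ape::phylo` with the `dl_distmat` attached as attribute
#'   `"distances"`.
#' @examples
#' tr <- balanced_tree(seed = 7)
#' gs <- evolve_genomes(tr, root_length = 2000, seed = 7)
#' tree <- build_tree(gs, K = 4)
#' robinson_foulds(tree, tr)
#' @export
build_tree <- function(genomes, K, metric = c("chord", "piecewise", "pseudo"),
                       rho = 3, normalized = FALSE, clamp_negative = FALSE) {
  metric <- match.arg(metric)
  cvs <- composition_vectors(genomes, K)
  dm <- distance_matrix(cvs, metric = metric, rho = rho,
                        normalized = normalized)
  tree <- neighbor_joining(dm, clamp_negative = clamp_negative)
  attr(tree, "distances") <- dm
  tree
}
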