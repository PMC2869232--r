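# Tree stage. Neighbor joining (Saitou & Nei) is exact on additive
# matrices; the implementation is ape's, wrapped with input validation, a
# two-taxon case, and an optional clamp for the negative branch lengths that
# non-additive inputs can produce.

#' Build an unrooted tree by neighbor joining
#'
#' @param D A `dl_distmat`, labelled symmetric numeric matrix, or `dist`.
#' @param clamp_negative Set negative branch lengths to zero, transferring
#'   the deficit to a sibling branch (common NJ post-processing; off by
#'   default, matching the raw algorithm).
#' @return An `ape::phylo`. For `n >= 3` the tree is unrooted with a
#'   trifurcation at the last-joined node; for `n = 2` it is the single
#'   edge, serialized as `(A:d,B:0.0);`.
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  m <- as.matrix(unclass(D))
  n <- nrow(m)
  if (n < 2L) stop("need at least two taxa")
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(m < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(m)) > 1e-12)) stop("distance matrix diagonal must be zero")
  if (n == 2L) {
    tree <- structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                           edge.length = c(m[1, 2], 0),
                           tip.label = rownames(m), Nnode = 1L),
                      class = "phylo", order = "cladewise")
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(m))
  if (clamp_negative) tree <- clamp_negative_branches(tree)
  tree
}

#' Clamp negative branch lengths
#'
#' Sets each negative branch length to zero and adds the deficit to a
#' sibling branch (the first other edge sharing the parent node, in edge
#' order), preserving the total length around the node.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return The adjusted tree.
#' @export
clamp_negative_branches <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  repeat {
    i <- which(tree$edge.length < 0)
    if (length(i) == 0L) break
    i <- i[1]
    deficit <- -tree$edge.length[i]
    tree$edge.length[i] <- 0
    sib <- which(tree$edge[, 1] == tree$edge[i, 1])
    sib <- setdiff(sib, i)
    if (length(sib) > 0L) {
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
      if (tree$edge.length[sib[1]] < 0) break  # avoid ping-pong on pathological input
    }
  }
  tree
}

#' Serialize a tree to Newick with deterministic ordering
#'
#' Children at every node are ordered lexicographically by the smallest
#' leaf label in their subtree, so topologically identical trees always
#' produce byte-identical strings. Branch lengths are written with up to
#' `digits` decimals, trailing zeros trimmed but at least one decimal kept
#' (`1.0`, `0.05`).
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param digits Maximum decimals for branch lengths.
#' @return A Newick string with trailing semicolon.
#' @export
to_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(x) {
    s <- sprintf("%.*f", digits, x)
    s <- sub("0+$", "", s)
    if (endsWith(s, ".")) paste0(s, "0") else s
  }
  min_leaf <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    min(vapply(kids[[as.character(node)]],
               function(e) min_leaf(tree$edge[e, 2]), character(1)))
  }
  render <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    edges <- kids[[as.character(node)]]
    ord <- order(vapply(edges, function(e) min_leaf(tree$edge[e, 2]),
                        character(1)))
    parts <- vapply(edges[ord], function(e) {
      paste0(render(tree$edge[e, 2]), ":",
             fmt_len(if (is.null(tree$edge.length)) NA_real_
                     else tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  paste0(render(root), ";")
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' (unrooted) trees; 0 means identical topology.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  u1 <- if (ape::is.rooted(t1)) ape::unroot(t1) else t1
  u2 <- if (ape::is.rooted(t2)) ape::unroot(t2) else t2
  as.integer(phangorn::RF.dist(u1, u2, check.labels = TRUE))
}
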