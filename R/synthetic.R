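# Synthetic data: i.i.d. random genomes and genomes evolved along a known
# tree under a Jukes-Cantor-type substitution process. A site at the end of
# a branch of length b (expected substitutions/site) differs from the site
# at its start with probability (1 - 1/size) * (1 - exp(-b * size/(size-1))),
# and a substituted site draws uniformly among the other letters. This is
# the exact JC transition kernel, so divergence composes correctly along
# paths: for DNA the expected differing fraction at path length t is
# (3/4) * (1 - exp(-4 t / 3)).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit stream seed for a branch, keyed on the global seed
# and the smallest leaf label below the branch, so regenerating a subtree
# after tree edits reuses the same stream.
branch_seed <- function(seed, key) {
  # iterated 31-bit hash; all intermediates stay well below 2^53 so the
  # arithmetic is exact in doubles
  h <- seed %% 2147483647
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

#' Generate a random i.i.d. genome
#'
#' @param alphabet A `dl_alphabet`.
#' @param length Sequence length, `>= 1`.
#' @param letter_weights Optional sampling weights, one per letter
#'   (normalized internally; default uniform). All-zero weights are an
#'   error.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @param genome_id Label for the record.
#' @return A `genome_record` with one sequence.
#' @export
random_genome <- function(alphabet = dna_alphabet(), length, letter_weights = NULL,
                          seed = 1L, genome_id = "random") {
  stopifnot(length >= 1)
  if (is.null(letter_weights)) letter_weights <- rep(1, alphabet$size)
  if (length(letter_weights) != alphabet$size || any(letter_weights < 0) ||
      sum(letter_weights) <= 0)
    stop("letter_weights must be non-negative, one per letter, not all zero")
  seq <- with_seed(seed, paste(
    sample(alphabet$letters, length, replace = TRUE,
           prob = letter_weights / sum(letter_weights)),
    collapse = ""))
  mode <- if (alphabet$name == "PROTEIN") "PROTEIN" else "WHOLE_DNA"
  assemble_genome(genome_id, seq, mode)
}

#' Balanced benchmark tree with random branch lengths
#'
#' A fully balanced topology over `n_leaves` (a power of two) with every
#' branch length drawn uniformly from `[bl_min, bl_max]` expected
#' substitutions/site. The defaults (8 leaves, 0.05--0.15) give moderately
#' diverged genomes on which composition signal is strong but far from
#' saturated.
#'
#' @param n_leaves Number of leaves (power of 2).
#' @param bl_min,bl_max Branch-length range.
#' @param seed Integer seed for the branch lengths.
#' @return An `ape::phylo` with tip labels `t1..tn`.
#' @export
balanced_tree <- function(n_leaves = 8L, bl_min = 0.05, bl_max = 0.15, seed = 1L) {
  stopifnot(n_leaves >= 4, bitwAnd(n_leaves, n_leaves - 1L) == 0L,
            bl_min >= 0, bl_max >= bl_min)
  tree <- ape::stree(n_leaves, type = "balanced")
  tree$edge.length <- with_seed(seed, stats::runif(nrow(tree$edge), bl_min, bl_max))
  tree
}

#' Evolve genomes along a known tree
#'
#' Draws an i.i.d. uniform root sequence of `root_length` letters and
#' applies the Jukes-Cantor site process down every branch. Each branch has
#' its own deterministic random stream derived from `seed`, so the same
#' seed always yields the same leaf genomes.
#'
#' @param tree An `ape::phylo` with non-negative branch lengths in expected
#'   substitutions/site.
#' @param root_length Root sequence length, `>= 1`.
#' @param alphabet A `dl_alphabet`.
#' @param seed Integer seed.
#' @return Named list of `genome_record`s, one per leaf, sorted by label.
#' @export
evolve_genomes <- function(tree, root_length, alphabet = dna_alphabet(),
                           seed = 1L) {
  stopifnot(inherits(tree, "phylo"), root_length >= 1,
            !is.null(tree$edge.length), all(tree$edge.length >= 0))
  size <- alphabet$size
  ntip <- length(tree$tip.label)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  leaf_set <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    paste(sort(unlist(lapply(kids[[as.character(node)]],
                             function(e) leaf_set(tree$edge[e, 2])))),
          collapse = "|")
  }
  root_codes <- with_seed(branch_seed(seed, "::root"),
                          sample.int(size, root_length, replace = TRUE) - 1L)
  mode <- if (alphabet$name == "PROTEIN") "PROTEIN" else "WHOLE_DNA"
  leaves <- list()
  descend <- function(node, codes) {
    if (node <= ntip) {
      seq <- paste(alphabet$letters[codes + 1L], collapse = "")
      leaves[[tree$tip.label[node]]] <<-
        assemble_genome(tree$tip.label[node], seq, mode)
      return(invisible())
    }
    for (e in kids[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      b <- tree$edge.length[e]
      ccodes <- codes
      if (b > 0) {
        p_diff <- (1 - 1 / size) * (1 - exp(-b * size / (size - 1)))
        ccodes <- with_seed(branch_seed(seed, leaf_set(child)), {
          cc <- codes
          hit <- stats::runif(root_length) < p_diff
          nh <- sum(hit)
          if (nh > 0) {
            shift <- sample.int(size - 1L, nh, replace = TRUE)
            cc[hit] <- (cc[hit] + shift) %% size
          }
          cc
        })
      }
      descend(child, ccodes)
    }
  }
  descend(root, root_codes)
  leaves[order(names(leaves))]
}

#' Analytic fixtures with hand-computed expectations
#'
#' Tiny genomes whose frequency tables and composition vectors are known in
#' closed form, used as exact oracles:
#' * `"acac_k2"` — genome `ACAC`, K = 2: `X(AC) = 5/3`, `X(CA) = 1/3`,
#'   `X(AA) = X(CC) = -1`, every string containing G or T has `q = 0` so
#'   `X = 0`.
#' * `"aaaa_k2"` — genome `AAAA`, K = 2: the all-zero vector.
#' * `"pooled_two_genes"` — genes `AAA`, `AA`, K = 2: pooled `p(AA) = 1`
#'   from 3 windows.
#'
#' @param name Fixture id.
#' @return List with the `genome` and an `expected` list (`K`, dense `x`
#'   where applicable, named `p`/`q` values).
#' @export
analytic_fixture <- function(name) {
  a <- dna_alphabet()
  switch(name,
    acac_k2 = {
      x <- numeric(16)
      names(x) <- index_to_kmer(0:15, 2L, a)
      x["AC"] <- 5 / 3; x["CA"] <- 1 / 3; x["AA"] <- -1; x["CC"] <- -1
      list(genome = assemble_genome("acac", "ACAC", "WHOLE_DNA"),
           expected = list(K = 2L, x = x,
                           p = c(AC = 2 / 3, CA = 1 / 3),
                           q = c(AA = 1 / 4, AC = 1 / 4, CA = 1 / 4, CC = 1 / 4)))
    },
    aaaa_k2 = {
      x <- numeric(16)
      names(x) <- index_to_kmer(0:15, 2L, a)
      list(genome = assemble_genome("aaaa", "AAAA", "WHOLE_DNA"),
           expected = list(K = 2L, x = x, p = c(AA = 1), q = c(AA = 1)))
    },
    pooled_two_genes = {
      list(genome = assemble_genome("pooled", c("AAA", "AA"), "CDS_DNA"),
           expected = list(K = 2L, p = c(AA = 1), valid_windows = 3))
    },
    stop("unknown fixture: ", name)
  )
}

#' Write a synthetic dataset to disk
#'
#' One FASTA per leaf genome, a manifest, and the generating tree as
#' Newick (for topology comparisons).
#'
#' @param genomes Named list of `genome_record`s (e.g. from
#'   [evolve_genomes()]).
#' @param tree The generating `ape::phylo` (optional).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_synthetic_dataset <- function(genomes, tree = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  paths <- file.path(dir, paste0(ids, ".fasta"))
  for (i in seq_along(genomes)) write_fasta(genomes[[i]], paths[i])
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(
    data.frame(genome_id = ids, path = basename(paths)),
    manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tree)) writeLines(to_newick(tree), file.path(dir, "true_tree.nwk"))
  invisible(manifest)
}
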