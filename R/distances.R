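# Correlation and the distances built on it. Two genomes are compared by
# the uncentered (cosine) sample correlation of their denoised composition
# vectors,
#   C(X, Y) = sum(X_i Y_i) / sqrt(sum(X_i^2) sum(Y_i^2)),
# taken over all N components (no mean subtraction). C is scale-invariant,
# so the unit-vector normalization X/|X| never has to be materialized: every
# distance below is a function of C alone.

clip_correlation <- function(C) pmin(pmax(C, -1), 1)

check_correlation <- function(C) {
  if (any(!is.finite(C)) || any(C < -1 - 1e-9) || any(C > 1 + 1e-9))
    stop("correlation must lie in [-1, 1]")
  clip_correlation(C)
}

#' Cosine correlation of two numeric vectors
#'
#' The uncentered correlation `sum(xy) / sqrt(sum(x^2) sum(y^2))`, clipped
#' to `[-1, 1]` to absorb floating-point overshoot.
#'
#' @param x,y Numeric vectors of equal length, neither identically zero.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sum(x * x); ny <- sum(y * y)
  if (nx == 0 || ny == 0) stop("correlation undefined for zero vector")
  clip_correlation(sum(x * y) / sqrt(nx * ny))
}

#' Correlation between two composition vectors
#'
#' Computed over all `N` components. The default sparse path uses the S/Z
#' partition directly (X is `p/q - 1` on S, `-1` on Z, `0` elsewhere), so
#' the full dot product is
#' `sum(x y over S∩S) - sum(x over S∩Z) - sum(y over Z∩S) + |Z∩Z|`
#' without ever expanding to length N; `method = "dense"` expands both
#' vectors (small N only) and evaluates the formula directly.
#'
#' @param X,Y `composition_vector`s with identical `K` and alphabet.
#' @param method `"sparse"` (default) or `"dense"`.
#' @return `C(X, Y)` in `[-1, 1]`.
#' @export
cv_correlation <- function(X, Y, method = c("sparse", "dense")) {
  stopifnot(inherits(X, "composition_vector"),
            inherits(Y, "composition_vector"))
  if (X$K != Y$K || !identical(X$alphabet$letters, Y$alphabet$letters))
    stop("composition vectors have mismatched K or alphabet")
  method <- match.arg(method)
  if (method == "dense") return(cosine_correlation(as_dense(X), as_dense(Y)))
  nx2 <- sum(X$x^2) + length(X$z_idx)  # X = -1 on Z
  ny2 <- sum(Y$x^2) + length(Y$z_idx)
  if (nx2 == 0 || ny2 == 0)
    stop("correlation undefined for zero vector (genome ",
         if (nx2 == 0) X$genome_id else Y$genome_id, ")")
  ss <- match(X$idx, Y$idx)
  sz <- match(X$idx, Y$z_idx)
  zs <- match(X$z_idx, Y$idx)
  zz <- match(X$z_idx, Y$z_idx)
  dot <- sum(X$x[!is.na(ss)] * Y$x[ss[!is.na(ss)]]) -
    sum(X$x[!is.na(sz)]) -
    sum(Y$x[zs[!is.na(zs)]]) +
    sum(!is.na(zz))
  clip_correlation(dot / sqrt(nx2 * ny2))
}

#' Legacy pseudo-distance
#'
#' `D_r = (1 - C) / 2`. Simple and historically used, but not a proper
#' metric: it is zero for any two proportional vectors and can violate the
#' triangle inequality.
#'
#' @param C Correlation value(s) in `[-1, 1]`.
#' @return Value(s) in `[0, 1]`.
#' @export
pseudo_distance <- function(C) {
  C <- check_correlation(C)
  (1 - C) / 2
}

#' Chord distance
#'
#' The Euclidean length of the chord between the two unit vectors,
#' `D = sqrt(2 (1 - C))` (the Cavalli-Sforza chord distance). A proper
#' metric on unit vectors; ranges over `[0, 2]`, or `[0, 1]` after
#' normalization (division by 2).
#'
#' @inheritParams pseudo_distance
#' @param normalized Divide by 2 so values lie in `[0, 1]`.
#' @return Non-negative value(s).
#' @export
chord_distance <- function(C, normalized = FALSE) {
  C <- check_correlation(C)
  d <- sqrt(2 * (1 - C))
  if (normalized) d / 2 else d
}

#' Piecewise distance
#'
#' `D = 0` when `C = 1`, else `1 - C / rho` with `rho >= 3`. The lower
#' bound on `rho` is what makes the triangle inequality hold; the function
#' jumps from `1 - 1/rho` down to 0 at `C = 1`. Equality with 1 is tested
#' on the clipped correlation with a `1e-12` tolerance so that genuinely
#' identical vectors land on the zero branch despite floating point.
#'
#' @inheritParams chord_distance
#' @param rho Real `>= 3` (default 3; results are typically insensitive to
#'   the choice).
#' @return Non-negative value(s); the nonzero branch lies in
#'   `(1 - 1/rho, 1 + 1/rho]`.
#' @export
piecewise_distance <- function(C, rho = 3, normalized = FALSE) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 3)
    stop("rho must be >= 3 (triangle inequality requires it)")
  C <- check_correlation(C)
  d <- ifelse(C >= 1 - 1e-12, 0, 1 - C / rho)
  if (normalized) d / 2 else d
}

apply_metric <- function(C, metric, rho, normalized) {
  switch(metric,
         pseudo = pseudo_distance(C),
         chord = chord_distance(C, normalized),
         piecewise = piecewise_distance(C, rho, normalized))
}

#' Pairwise distance matrix over a set of genomes
#'
#' Computes the correlation once per pair (sparse path) and applies the
#' chosen metric. The correlations are kept as an attribute so other
#' metrics can be derived without recounting.
#'
#' @param vectors List of `composition_vector`s (same `K` and alphabet,
#'   unique genome ids).
#' @param metric `"chord"`, `"piecewise"` or `"pseudo"`.
#' @param rho Piecewise parameter, `>= 3`.
#' @param normalized Use the `[0, 1]`-normalized form (chord/piecewise).
#' @return A `dl_distmat`: labelled symmetric matrix with zero diagonal and
#'   attributes `metric`, `rho`, `normalized`, `K` and `correlations`.
#' @export
distance_matrix <- function(vectors, metric = c("chord", "piecewise", "pseudo"),
                            rho = 3, normalized = FALSE) {
  metric <- match.arg(metric)
  n <- length(vectors)
  if (n < 2L) stop("need at least two composition vectors")
  labels <- vapply(vectors, function(v) v$genome_id, character(1))
  if (anyDuplicated(labels)) stop("duplicate genome labels")
  C <- diag(1, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      C[i, j] <- C[j, i] <- cv_correlation(vectors[[i]], vectors[[j]])
    }
  }
  dimnames(C) <- list(labels, labels)
  D <- apply_metric(C, metric, rho, normalized)
  diag(D) <- 0
  dimnames(D) <- dimnames(C)
  structure(D, class = c("dl_distmat", "matrix"),
            metric = metric, rho = rho, normalized = normalized,
            K = vectors[[1]]$K, correlations = C)
}

#' Re-derive a distance matrix under another metric
#'
#' Uses the correlations cached on an existing `dl_distmat`.
#'
#' @param dm A `dl_distmat` from [distance_matrix()].
#' @inheritParams distance_matrix
#' @return A `dl_distmat`.
#' @export
rederive_distances <- function(dm, metric = c("chord", "piecewise", "pseudo"),
                               rho = 3, normalized = FALSE) {
  metric <- match.arg(metric)
  C <- attr(dm, "correlations")
  if (is.null(C)) stop("no cached correlations on this matrix")
  D <- apply_metric(C, metric, rho, normalized)
  diag(D) <- 0
  dimnames(D) <- dimnames(C)
  structure(D, class = c("dl_distmat", "matrix"),
            metric = metric, rho = rho, normalized = normalized,
            K = attr(dm, "K"), correlations = C)
}

#' @export
print.dl_distmat <- function(x, ...) {
  cat(sprintf("<%s distance matrix: %d genomes, K=%s%s%s>\n",
              attr(x, "metric"), nrow(x),
              as.character(attr(x, "K")),
              if (identical(attr(x, "metric"), "piecewise"))
                sprintf(", rho=%g", attr(x, "rho")) else "",
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(round(m, 6))
  invisible(x)
}

#' Export a distance matrix in long TSV format
#'
#' One row per unordered pair: columns `genome_a`, `genome_b`, `distance`.
#'
#' @param dm A `dl_distmat` or labelled symmetric matrix.
#' @param path Output path.
#' @export
write_distance_tsv <- function(dm, path) {
  m <- as.matrix(unclass(dm))
  labs <- rownames(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  df <- data.frame(genome_a = labs[pairs[, 1]], genome_b = labs[pairs[, 2]],
                   distance = sprintf("%.6f", m[pairs]),
                   stringsAsFactors = FALSE)
  df <- df[order(df$genome_a, df$genome_b), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
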