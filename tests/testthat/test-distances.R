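dna <- dna_alphabet()

test_that("analytic values of the three distances are exact", {
  expect_equal(pseudo_distance(1), 0)
  expect_equal(pseudo_distance(0), 0.5)
  expect_equal(pseudo_distance(-1), 1)

  expect_equal(chord_distance(1), 0)
  expect_equal(chord_distance(0), sqrt(2), tolerance = 1e-15)
  expect_equal(chord_distance(-1), 2)
  expect_equal(chord_distance(-1, normalized = TRUE), 1)

  expect_equal(piecewise_distance(1, 3), 0)
  expect_equal(piecewise_distance(0, 3), 1)
  expect_equal(piecewise_distance(-1, 3), 4 / 3)
  expect_equal(piecewise_distance(-1, 3, normalized = TRUE), 2 / 3)

  expect_error(piecewise_distance(0, rho = 2.9), "rho")
  expect_error(chord_distance(1.2), "\\[-1, 1\\]")
})

test_that("cosine correlation follows the uncentered formula, no mean subtraction", {
  expect_equal(cosine_correlation(c(1, 2), c(2, 1)), 4 / 5)
  expect_equal(cosine_correlation(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_correlation(c(3, -1, 2), c(3, -1, 2)), 1)
  # centered (Pearson) correlation of (1,2),(2,1) would be -1, not 4/5
  expect_error(cosine_correlation(c(0, 0), c(1, 1)), "zero vector")
})

test_that("sparse composition-vector correlation equals the dense oracle", {
  for (seed in 1:4) {
    g1 <- random_genome(dna, 1500, seed = seed)
    g2 <- random_genome(dna, 900, seed = seed + 50)
    for (K in 2:4) {
      X <- composition_vector(g1, K)
      Y <- composition_vector(g2, K)
      want <- naive_cosine(naive_dense_x(g1$sequences, K, dna$letters),
                           naive_dense_x(g2$sequences, K, dna$letters))
      expect_equal(cv_correlation(X, Y), want, tolerance = 1e-12)
      expect_equal(cv_correlation(X, Y, method = "dense"), want,
                   tolerance = 1e-12)
    }
  }
  pa <- protein_alphabet()
  gp1 <- random_genome(pa, 700, seed = 3)
  gp2 <- random_genome(pa, 700, seed = 4)
  Xp <- composition_vector(gp1, 2)
  Yp <- composition_vector(gp2, 2)
  expect_equal(cv_correlation(Xp, Yp),
               naive_cosine(naive_dense_x(gp1$sequences, 2, pa$letters),
                            naive_dense_x(gp2$sequences, 2, pa$letters)),
               tolerance = 1e-12)
})

test_that("self-correlation is one; mismatched vectors are rejected", {
  g <- random_genome(dna, 500, seed = 1)
  X <- composition_vector(g, 3)
  expect_equal(cv_correlation(X, X), 1, tolerance = 1e-14)
  Y4 <- composition_vector(g, 4)
  expect_error(cv_correlation(X, Y4), "mismatched")
  gz <- analytic_fixture("aaaa_k2")$genome
  Z <- composition_vector(gz, 3)  # all-zero vector at K = 3 too
  expect_error(cv_correlation(X, Z), "zero vector")
})

test_that("distance matrix is symmetric, zero-diagonal, and equals per-pair calls", {
  gs <- lapply(1:4, function(i) random_genome(dna, 600, seed = i,
                                              genome_id = paste0("g", i)))
  cvs <- composition_vectors(gs, 3)
  for (metric in c("chord", "piecewise", "pseudo")) {
    dm <- distance_matrix(cvs, metric = metric)
    m <- as.matrix(unclass(dm))
    expect_equal(diag(m), setNames(rep(0, 4), paste0("g", 1:4)))
    expect_equal(m, t(m))
    C12 <- cv_correlation(cvs[[1]], cvs[[2]])
    want <- switch(metric, chord = chord_distance(C12),
                   piecewise = piecewise_distance(C12, 3),
                   pseudo = pseudo_distance(C12))
    expect_equal(m["g1", "g2"], want, tolerance = 1e-14)
  }
  # identical genomes sit at zero distance under every metric
  cvs2 <- list(cvs[[1]], composition_vector(
    assemble_genome("copy", gs[[1]]$sequences, "WHOLE_DNA"), 3))
  for (metric in c("chord", "piecewise", "pseudo")) {
    dm <- distance_matrix(cvs2, metric = metric)
    expect_equal(unclass(dm)[1, 2], 0, tolerance = 1e-7)
  }
  expect_error(distance_matrix(list(cvs[[1]], cvs[[1]])), "duplicate")
})

test_that("chord and piecewise satisfy the metric axioms on random triples", {
  set.seed(99)
  n_triples <- 800
  rhos <- c(3, 4, 6, 8, 10)
  for (i in seq_len(n_triples)) {
    dim <- sample(10:1000, 1)
    x <- random_unit(dim); y <- random_unit(dim); z <- random_unit(dim)
    Cxy <- cosine_correlation(x, y)
    Cyz <- cosine_correlation(y, z)
    Cxz <- cosine_correlation(x, z)
    dc <- chord_distance(c(Cxy, Cyz, Cxz))
    expect_true(all(dc >= 0))
    expect_gte(dc[1] + dc[2] - dc[3], -1e-12)
    for (rho in rhos) {
      dp <- piecewise_distance(c(Cxy, Cyz, Cxz), rho)
      expect_true(all(dp >= 0))
      expect_gte(dp[1] + dp[2] - dp[3], -1e-12)
    }
  }
})

test_that("symmetry and identity of indiscernibles hold", {
  set.seed(7)
  for (i in 1:50) {
    x <- random_unit(64); y <- random_unit(64)
    expect_identical(chord_distance(cosine_correlation(x, y)),
                     chord_distance(cosine_correlation(y, x)))
    # distance 0 only at C = 1, i.e. equal unit vectors
    expect_gt(chord_distance(cosine_correlation(x, y)), 0)
    expect_gt(piecewise_distance(cosine_correlation(x, y), 3), 0)
  }
  x <- random_unit(64)
  expect_equal(chord_distance(cosine_correlation(x, x)), 0)
  expect_equal(piecewise_distance(cosine_correlation(x, x), 3), 0)
})

test_that("the pseudo-distance fails the metric axioms where the proper ones hold", {
  # D_r(X, 2X) = 0 with X != 2X: identity of indiscernibles fails
  x <- random_unit(16)
  expect_equal(pseudo_distance(cosine_correlation(x, 2 * x)), 0)
  expect_false(isTRUE(all.equal(x, 2 * x)))

  # randomized search turns up a triangle-inequality violation for D_r
  set.seed(123)
  found <- FALSE
  for (i in 1:5000) {
    x <- random_unit(3); y <- random_unit(3); z <- random_unit(3)
    dxy <- pseudo_distance(cosine_correlation(x, y))
    dyz <- pseudo_distance(cosine_correlation(y, z))
    dxz <- pseudo_distance(cosine_correlation(x, z))
    if (dxz > dxy + dyz + 1e-9) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("all three distances decrease strictly in the correlation", {
  Cs <- seq(-1, 0.999, length.out = 200)
  expect_true(all(diff(pseudo_distance(Cs)) < 0))
  expect_true(all(diff(chord_distance(Cs)) < 0))
  expect_true(all(diff(piecewise_distance(Cs, 3)) < 0))
  # normalized forms stay in [0, 1]
  expect_true(all(chord_distance(Cs, normalized = TRUE) <= 1))
  expect_true(all(piecewise_distance(Cs, 3, normalized = TRUE) <= 1))
})

test_that("PHYLIP and TSV round-trips preserve the matrix", {
  gs <- lapply(1:3, function(i) random_genome(dna, 400, seed = i,
                                              genome_id = paste0("gen", i)))
  dm <- distance_matrix(composition_vectors(gs, 3))
  f <- withr::local_tempfile(fileext = ".phylip")
  write_phylip(dm, f)
  back <- read_phylip(f)
  expect_equal(rownames(back), paste0("gen", 1:3))
  expect_equal(unname(back), matrix(round(as.numeric(dm), 6), 3),
               tolerance = 1e-9)

  ftsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(dm, ftsv)
  tab <- read.delim(ftsv)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$distance[tab$genome_a == "gen1" & tab$genome_b == "gen2"],
               round(unclass(dm)["gen1", "gen2"], 6), tolerance = 1e-9)
})
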