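# Genotype indexing and Kronecker assembly of the system matrix.

test_that("kronecker_sum handles the base cases and the Lynch dimensions", {
  expect_equal(as.matrix(kronecker_sum(list(matrix(2), matrix(3)))),
               matrix(5))
  mats <- lapply(c(5, 5, 5, 2, 5), function(n) diag(0, n))
  expect_equal(dim(kronecker_sum(mats)), c(1250, 1250))
  expect_error(kronecker_sum(list(matrix(1:6, 2, 3))), "square")
  expect_error(kronecker_sum(list()), "at least one")
})

test_that("kronecker_sum equals the brute-force Cartesian-product adjacency", {
  for (seed in 1:5) {
    toy <- make_toy(seed, n_genes = 2 + seed %% 3,
                    states_per_gene = 2 + (seed + 1) %% 3)
    expect_equal(as.matrix(kronecker_sum(toy$factors)),
                 brute_force_product(toy), info = paste("seed", seed))
  }
  # single factor: the Kronecker sum is the factor itself
  toy1 <- make_toy(99, n_genes = 1, states_per_gene = 4)
  expect_equal(as.matrix(kronecker_sum(toy1$factors)), toy1$factors[[1]])
})

test_that("genotype index is a bijection consistent with the Kronecker order", {
  idx <- lynch_sm()$index
  expect_equal(idx$total_dim, 1250L)
  expect_equal(unname(idx$dims), c(5L, 5L, 5L, 2L, 5L))
  # round trip tuple -> flat -> tuple on a sample
  for (i in c(1L, 2L, 7L, 251L, 1250L)) {
    expect_equal(flat_index(idx, idx$tuples[i, ]), i)
  }
  # advancing any single gene increases the flat index
  base <- c("m", "0", "0", "0", "0")
  i0 <- flat_index(idx, base)
  for (k in seq_along(base)) {
    adv <- base
    states_k <- idx$states[[k]]
    pos <- match(base[k], states_k)
    if (pos < length(states_k)) {
      adv[k] <- states_k[pos + 1]
      expect_gt(flat_index(idx, adv), i0)
    }
  }
  expect_match(idx$labels[1], "^MLH1:m\\|CTNNB1:0\\|APC:0\\|KRAS:0\\|TP53:0$")
  expect_error(flat_index(idx, c("0", "0", "0", "0", "0")), "state '0'")
})

test_that("A inherits single-gene rates on the genotype space", {
  sm <- lynch_sm()
  idx <- sm$index
  mmr_q <- sm$graphs[[1]]$Q
  i <- flat_index(idx, c("m", "0", "0", "0", "0"))
  j <- flat_index(idx, c("mm", "0", "0", "0", "0"))
  expect_equal(sm$A[i, j], mmr_q["m", "mm"])
  # with all b = 0, A is a generator
  A0 <- lynch_b0_sm()$A
  expect_lt(max(abs(Matrix::rowSums(A0))), 1e-15)
  # with fitness, each row sums to the genotype's total fitness
  i2 <- flat_index(idx, c("mm", "0", "mm", "m", "0"))
  expect_equal(Matrix::rowSums(sm$A)[i2], -0.01 + 0.10 + 0.01)
})

test_that("B carries the beta-fold APC point-mutation flux in MMR-deficient rows", {
  sm <- lynch_sm()
  idx <- sm$index
  g <- sm$config$globals
  apc <- sm$config$genes[[3]]
  i <- flat_index(idx, c("mm", "0", "0", "0", "0"))
  j <- flat_index(idx, c("mm", "0", "m", "0", "0"))
  expect_equal(sm$B[i, j], 1e3 * point_mutation_rate(apc, 0, g))
  # MMR-proficient rows are untouched
  for (s in c("m", "l")) {
    r <- flat_index(idx, c(s, "0", "0", "0", "0"))
    expect_equal(sum(abs(sm$B[r, ])), 0)
  }
  expect_lt(max(abs(Matrix::rowSums(sm$B))), 1e-18)
  cfg <- preset("lynch-mlh1", deps = dependency_params(beta = 0))
  expect_equal(Matrix::nnzero(build_system_matrix(cfg)$B), 0)
})

test_that("C redirects MLH1 LOH flux onto simultaneous CTNNB1 LOH edges", {
  sm <- lynch_sm()
  idx <- sm$index
  expect_equal(Matrix::nnzero(sm$C), 400)
  expect_lt(max(abs(Matrix::rowSums(sm$C))), 1e-18)
  g <- sm$config$globals
  mlh1 <- sm$config$genes[[1]]
  w <- 0.9 * loh_rate(mlh1, 1, g)
  i <- flat_index(idx, c("m", "0", "0", "0", "0"))
  expect_equal(sm$C[i, flat_index(idx, c("ml", "0", "0", "0", "0"))], -w)
  expect_equal(sm$C[i, flat_index(idx, c("ml", "l", "0", "0", "0"))], w)
  # A + C preserves each row's total outflow: pure flux redirection
  expect_equal(Matrix::rowSums(sm$A + sm$C), Matrix::rowSums(sm$A))
  # the association is MLH1-specific
  msh2 <- build_system_matrix(preset("lynch-msh2"))
  expect_equal(Matrix::nnzero(msh2$C), 0)
  expect_equal(Matrix::nnzero(msh2$E), 0)
})

test_that("D accelerates LOH only in APC-inactivated genotypes", {
  sm <- lynch_sm()
  idx <- sm$index
  g <- sm$config$globals
  mlh1 <- sm$config$genes[[1]]
  i <- flat_index(idx, c("m", "0", "mm", "0", "0"))
  j <- flat_index(idx, c("ml", "0", "mm", "0", "0"))
  expect_equal(sm$D[i, j], 1e2 * loh_rate(mlh1, 1, g))
  for (s in c("0", "m", "l")) {
    r <- flat_index(idx, c("m", "0", s, "0", "0"))
    expect_equal(sum(abs(sm$D[r, ])), 0)
  }
  cfg <- preset("lynch-mlh1", deps = dependency_params(delta = 0))
  expect_equal(Matrix::nnzero(build_system_matrix(cfg)$D), 0)
})

test_that("E applies the C-type redirection with delta enhancement on APC-/- rows", {
  sm <- lynch_sm()
  expect_equal(Matrix::nnzero(sm$E), 160)
  expect_lt(max(abs(Matrix::rowSums(sm$E))), 1e-18)
  idx <- sm$index
  g <- sm$config$globals
  w <- 1e2 * 0.9 * loh_rate(sm$config$genes[[1]], 1, g)
  i <- flat_index(idx, c("m", "0", "mm", "0", "0"))
  expect_equal(sm$E[i, flat_index(idx, c("ml", "l", "mm", "0", "0"))], w)
  for (d in list(dependency_params(delta = 0),
                 dependency_params(r_effloh = 0))) {
    cfg <- preset("lynch-mlh1", deps = d)
    expect_equal(Matrix::nnzero(build_system_matrix(cfg)$E), 0)
  }
})

test_that("F carries the zeta-fold KRAS activation flux after MMR deficiency", {
  sm <- lynch_sm()
  idx <- sm$index
  g <- sm$config$globals
  kras <- sm$config$genes[[4]]
  i <- flat_index(idx, c("mm", "0", "0", "0", "0"))
  j <- flat_index(idx, c("mm", "0", "0", "m", "0"))
  expect_equal(sm$F[i, j], 1e2 * point_mutation_rate(kras, 0, g))
  r <- flat_index(idx, c("l", "ml", "mm", "0", "ml"))
  expect_equal(sum(abs(sm$F[r, ])), 0)
})

test_that("the assembled system matrix is upper triangular and reduces to A", {
  M <- as.matrix(lynch_sm()$M)
  expect_true(all(M[lower.tri(M)] == 0))
  cfg <- preset("lynch-mlh1",
                deps = dependency_params(beta = 0, delta = 0, zeta = 0,
                                         r_effloh = 0))
  sm0 <- build_system_matrix(cfg)
  expect_equal(as.matrix(sm0$M), as.matrix(sm0$A))
  # mass conservation: with b = 0 every row of M sums to zero
  expect_lt(max(abs(Matrix::rowSums(lynch_b0_sm()$M))), 1e-15)
})
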