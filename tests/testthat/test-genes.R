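# Gene-level rates and mutation graphs.

test_that("point-mutation rate reproduces the hand-evaluated MLH1 value and allele scaling", {
  g <- global_params()
  mlh1 <- default_gene("MLH1")
  # 365 * 1.2 * 1500 * 2270 / 3.2e9 * 2.3e-6, evaluated by hand
  expect_equal(point_mutation_rate(mlh1, 0, g), 1.0719365625e-06,
               tolerance = 1e-12)
  for (gene in list(mlh1, default_gene("APC"), default_gene("KRAS"))) {
    expect_identical(point_mutation_rate(gene, 2, g), 0)
    expect_equal(point_mutation_rate(gene, 1, g),
                 point_mutation_rate(gene, 0, g) / 2)
  }
})

test_that("alpha calibration gives the closed-form value and the 2:1 LOH ratio", {
  g <- global_params()
  mlh1 <- default_gene("MLH1")
  # 2 * 2270 * 1.2 / (57500 * 3.2e9)
  expect_equal(calibrate_alpha(g, mlh1), 2.960869565e-11, tolerance = 1e-9)
  g$alpha <- calibrate_alpha(g, mlh1)
  for (k in c(0, 1)) {
    expect_equal(loh_rate(mlh1, k, g) / point_mutation_rate(mlh1, k, g), 2)
  }
  # the ratio is an algebraic identity, independent of the parameter values
  withr::with_seed(11, {
    for (i in 1:10) {
      gr <- global_params(n_pt = runif(1, 0.1, 5), n_cells = runif(1, 100, 5000),
                          n_bp_genome = runif(1, 1e9, 5e9))
      sp <- gene_spec("MLH1", "mmr", c("m", "l", "mm", "ml", "ll"),
                      n_hs = runif(1, 100, 5000), n_bp = runif(1, 1e4, 1e5),
                      f = runif(1, 1e-7, 1e-3))
      gr$alpha <- calibrate_alpha(gr, sp)
      expect_equal(loh_rate(sp, 1, gr), 2 * point_mutation_rate(sp, 1, gr))
    }
  })
  # alpha scales linearly with n_pt
  g0 <- global_params(n_pt = 1e-12)
  expect_equal(calibrate_alpha(g0, mlh1) / 1e-12 * 1.2,
               calibrate_alpha(global_params(), mlh1))
})

test_that("LOH rate follows the length-proportional formula", {
  g <- calibrated_globals()
  ct <- default_gene("CTNNB1")
  expect_equal(loh_rate(ct, 0, g),
               365 * 1500 * g$alpha * 41000 * 1.2e-3)
  expect_identical(loh_rate(ct, 2, g), 0)
  g_raw <- global_params()  # alpha not calibrated
  expect_error(loh_rate(ct, 0, g_raw), "calibrat")
  expect_error(loh_rate(default_gene("KRAS"), 0, g), "n_bp")
})

test_that("mutation graphs have the role-specific edge structure", {
  g <- calibrated_globals()
  kras <- build_gene_graph(default_gene("KRAS"), g)
  offdiag <- function(Q) { diag(Q) <- 0; Q }
  expect_equal(sum(offdiag(kras$Q) != 0), 1L)
  expect_equal(kras$Q["0", "m"],
               point_mutation_rate(default_gene("KRAS"), 0, g))

  apc <- build_gene_graph(default_gene("APC"), g)
  expect_equal(sum(offdiag(apc$Q) != 0), 5L)
  expect_equal(apc$Q["m", "mm"], point_mutation_rate(default_gene("APC"), 1, g))
  expect_equal(apc$Q["0", "l"], loh_rate(default_gene("APC"), 0, g))
  expect_false("ll" %in% apc$states)

  mlh1 <- build_gene_graph(default_gene("MLH1"), g)
  expect_setequal(mlh1$states, c("m", "l", "mm", "ml", "ll"))
  expect_equal(mlh1$Q["l", "ll"], loh_rate(default_gene("MLH1"), 1, g))
})

test_that("graphs are upper triangular and generators when fitness is zero", {
  g <- calibrated_globals()
  for (nm in c("MLH1", "MSH2", "CTNNB1", "APC", "KRAS", "TP53")) {
    gn <- default_gene(nm, b = 0)
    gr <- build_gene_graph(gn, g)
    expect_true(all(gr$Q[lower.tri(gr$Q)] == 0), info = nm)
    expect_equal(rowSums(gr$Q), setNames(rep(0, length(gr$states)), gr$states),
                 info = nm)
    off <- gr$Q; diag(off) <- 0
    expect_true(all(off >= 0) && all(off < 1), info = nm)
  }
  # with fitness, the diagonal is b(state) minus the outgoing flux
  mlh1 <- build_gene_graph(default_gene("MLH1"), g)
  out_m <- sum(mlh1$Q["m", c("mm", "ml")])
  expect_equal(mlh1$Q["m", "m"], -out_m)        # m is not MMR-deficient
  expect_equal(mlh1$Q["mm", "mm"], -0.01)       # absorbing deficient state
})

test_that("invalid gene definitions are rejected", {
  expect_error(gene_spec("X", "oncogene", c("0", "m", "l"), 10, NA, 1e-6),
               "oncogene")
  expect_error(gene_spec("X", "tumor_suppressor",
                         c("0", "m", "l", "mm", "ml", "ll"), 10, 100, 1e-6),
               "lethal")
  expect_error(gene_spec("X", "mmr", c("m", "mm", "l"), 10, 100, 1e-6),
               "canonical")
  expect_error(gene_spec("X", "mmr", c("m", "l", "mm", "ml", "ll"),
                         n_hs = 200, n_bp = 100, f = 1e-6), "exceed")
  expect_error(global_params(n_pt = -1), "positive")
  g <- calibrated_globals()
  expect_error(point_mutation_rate(default_gene("APC"), 3, g), "n_mut")
})
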