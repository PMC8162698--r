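# Small seeded toy models and brute-force oracles, so the assembly and solver
# machinery can be checked against independent references without the full
# genotype space.

#' Generate a seeded toy model
#'
#' Random upper-triangular generator factors: every strictly upper-triangular
#' entry is a rate drawn uniformly from \code{rate_range}, and diagonals are
#' set to minus the row sum (mass-preserving generators, i.e. all fitness
#' terms zero). Deterministic for a fixed seed. The default rate range spans
#' the magnitudes of the gene-level per-year rates.
#'
#' @param seed Integer seed.
#' @param n_genes Number of factor graphs (1--4).
#' @param states_per_gene States per factor (2--4); scalar or vector of
#'   length \code{n_genes}.
#' @param rate_range Length-2 numeric range for the uniform rate draw.
#' @return An object of class \code{toy_model} with \code{factors} (list of
#'   dense matrices) and the generating arguments.
#' @export
make_toy <- function(seed, n_genes = 2, states_per_gene = 3,
                     rate_range = c(1e-6, 1e-1)) {
  if (n_genes < 1 || n_genes > 4) stop("n_genes must be between 1 and 4")
  ns <- rep_len(states_per_gene, n_genes)
  if (any(ns < 2 | ns > 4)) stop("states_per_gene must be between 2 and 4")
  if (length(rate_range) != 2 || any(rate_range < 0) || diff(rate_range) < 0) {
    stop("rate_range must be a nondecreasing nonnegative pair")
  }
  factors <- withr::with_seed(seed, lapply(ns, function(n) {
    Q <- matrix(0, n, n)
    up <- upper.tri(Q)
    Q[up] <- stats::runif(sum(up), rate_range[1], rate_range[2])
    diag(Q) <- -rowSums(Q)
    Q
  }))
  structure(list(factors = factors, seed = seed, n_genes = n_genes,
                 states_per_gene = ns, rate_range = rate_range),
            class = "toy_model")
}

#' Brute-force Cartesian-product adjacency
#'
#' Builds the adjacency matrix of the Cartesian product of the factor graphs
#' by explicit enumeration of vertex tuples: an edge exists where exactly one
#' coordinate moves along a factor edge, and diagonal entries add across
#' factors. This is the independent equality oracle for
#' \code{\link{kronecker_sum}}.
#'
#' @param model A \code{\link{make_toy}} model (total dimension at most 256).
#' @return Dense matrix of the product dimension.
#' @export
brute_force_product <- function(model) {
  stopifnot(inherits(model, "toy_model"))
  dims <- vapply(model$factors, nrow, 1L)
  N <- prod(dims)
  if (N > 256) stop("brute-force oracle refuses dimensions above 256")
  n <- length(dims)
  # tuple of flat index i (1-based), first factor most significant
  tuple_of <- function(i) {
    i <- i - 1L
    out <- integer(n)
    for (k in n:1) {
      out[k] <- i %% dims[k]
      i <- i %/% dims[k]
    }
    out + 1L
  }
  tuples <- matrix(vapply(seq_len(N), tuple_of, integer(n)),
                   nrow = N, ncol = n, byrow = TRUE)
  M <- matrix(0, N, N)
  for (u in seq_len(N)) {
    for (v in seq_len(N)) {
      diff <- which(tuples[u, ] != tuples[v, ])
      if (length(diff) == 0) {
        M[u, v] <- sum(vapply(seq_len(n), function(k) {
          model$factors[[k]][tuples[u, k], tuples[u, k]]
        }, 1))
      } else if (length(diff) == 1) {
        k <- diff
        M[u, v] <- model$factors[[k]][tuples[u, k], tuples[v, k]]
      }
    }
  }
  M
}

#' Reference ODE solution for toy models
#'
#' Integrates \eqn{\dot x = M^\top x} with a stiff ODE solver
#' (\code{deSolve::lsoda}) at tight tolerances. Serves as an oracle for the
#' matrix-exponential solvers; it shares none of their code path.
#'
#' @param model A \code{\link{make_toy}} model, or a plain square matrix M
#'   (dimension at most 256).
#' @param x0 Initial vector.
#' @param t Single nonnegative time.
#' @return Numeric vector x(t).
#' @export
dense_reference_solve <- function(model, x0, t) {
  M <- if (inherits(model, "toy_model")) {
    as.matrix(kronecker_sum(model$factors))
  } else {
    as.matrix(model)
  }
  if (nrow(M) > 256) stop("reference solver refuses dimensions above 256")
  stopifnot(length(x0) == nrow(M), t >= 0)
  if (t == 0) return(as.numeric(x0))
  Mt <- t(M)
  sol <- deSolve::lsoda(y = as.numeric(x0), times = c(0, t),
                        func = function(time, y, parms) list(Mt %*% y),
                        rtol = 1e-10, atol = 1e-12 * max(1, max(abs(x0))))
  as.numeric(sol[2, -1])
}
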