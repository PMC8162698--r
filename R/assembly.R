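# Genotype state space and the Kronecker-structured system matrix.
#
# The independent component A is the Kronecker sum of the per-gene rate
# matrices (the adjacency matrix of the Cartesian product of the gene
# mutation graphs). Each mutational dependency is an additional matrix built
# as a Kronecker product of a modified gene factor, selector diagonals that
# restrict the effect to the triggering genotypes, and identities elsewhere.

#' Genotype index for an ordered gene list
#'
#' Enumerates all genotype tuples (one mutation status per gene) and fixes the
#' bijection with flat indices. The flat index is row-major with the first
#' gene most significant, consistent with the Kronecker ordering
#' \code{e_MMR \%x\% e_CTNNB1 \%x\% e_APC \%x\% e_KRAS \%x\% e_TP53}.
#'
#' @param genes List of \code{\link{gene_spec}} objects in canonical model
#'   order (MMR gene first when present, then CTNNB1, APC, KRAS, TP53).
#' @return An object of class \code{genotype_index} with the gene list, the
#'   per-gene state counts \code{dims}, the genotype tuple matrix
#'   \code{tuples} (characters, one row per flat index) and human-readable
#'   \code{labels} such as \code{"MLH1:m|CTNNB1:0|APC:0|KRAS:0|TP53:0"}.
#' @export
genotype_index <- function(genes) {
  stopifnot(length(genes) >= 1, all(vapply(genes, inherits, TRUE, "gene_spec")))
  gene_names <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(gene_names)) stop("duplicate gene names in gene list")
  state_lists <- lapply(genes, `[[`, "states")
  names(state_lists) <- gene_names
  n <- length(genes)
  # expand.grid varies its first argument fastest; feeding the reversed gene
  # order makes the LAST gene cycle fastest, i.e. the first gene is the most
  # significant digit of the flat index, matching the Kronecker product.
  grid <- expand.grid(rev(state_lists), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tuples <- as.matrix(grid)[, n:1, drop = FALSE]
  colnames(tuples) <- gene_names
  labels <- apply(tuples, 1L, function(row) {
    paste(paste(gene_names, row, sep = ":"), collapse = "|")
  })
  structure(list(genes = genes, gene_names = gene_names,
                 dims = vapply(state_lists, length, 1L),
                 states = state_lists,
                 total_dim = nrow(tuples),
                 tuples = tuples, labels = unname(labels)),
            class = "genotype_index")
}

#' @export
print.genotype_index <- function(x, ...) {
  cat(sprintf("<genotype_index> %d genotypes = %s\n", x$total_dim,
              paste(x$dims, collapse = " x ")))
  invisible(x)
}

#' Flat index of a genotype tuple
#'
#' @param idx A \code{\link{genotype_index}}.
#' @param tuple Character vector of mutation statuses, one per gene, in gene
#'   order.
#' @return 1-based flat index.
#' @export
flat_index <- function(idx, tuple) {
  stopifnot(inherits(idx, "genotype_index"),
            length(tuple) == length(idx$genes))
  i <- 0L
  for (k in seq_along(tuple)) {
    pos <- match(tuple[k], idx$states[[k]])
    if (is.na(pos)) {
      stop("state '", tuple[k], "' is not in the state set of gene '",
           idx$gene_names[k], "'")
    }
    i <- i * idx$dims[k] + (pos - 1L)
  }
  as.integer(i + 1L)
}

as_sparse <- function(m) {
  if (inherits(m, "mutation_graph")) m <- m$Q
  methods::as(methods::as(Matrix::Matrix(m), "generalMatrix"), "CsparseMatrix")
}

kron_list <- function(factors) Reduce(`%x%`, lapply(factors, as_sparse))

#' Kronecker sum of square matrices
#'
#' \eqn{A_1 \oplus \dots \oplus A_n = \sum_i I \otimes \dots \otimes A_i
#' \otimes \dots \otimes I}. This is the adjacency matrix of the Cartesian
#' product of the factor graphs: exactly one coordinate changes per edge.
#'
#' @param matrices Nonempty list of square matrices (base or Matrix).
#' @return Sparse matrix of dimension \code{prod(sapply(matrices, nrow))}.
#' @export
kronecker_sum <- function(matrices) {
  if (length(matrices) == 0) stop("kronecker_sum needs at least one matrix")
  mats <- lapply(matrices, as_sparse)
  for (m in mats) {
    if (nrow(m) != ncol(m)) stop("kronecker_sum inputs must be square")
  }
  Reduce(function(A, B) {
    A %x% Matrix::Diagonal(ncol(B)) + Matrix::Diagonal(ncol(A)) %x% B
  }, mats)
}

# 0/1 selector diagonal over a gene's states
selector_diag <- function(states, selected) {
  Matrix::Diagonal(x = as.numeric(states %in% selected))
}

# Gene factor containing only the gene's edges of one mutation type, scaled,
# with a compensating diagonal so that every row sums to zero (the dependency
# reroutes/speeds up flux without creating or destroying mass).
scaled_edge_factor <- function(gene, g, type, scale) {
  s <- gene$states
  n <- length(s)
  Q <- matrix(0, n, n, dimnames = list(s, s))
  ed <- gene_edges(gene)
  ed <- ed[ed$type == type, , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    Q[ed$from[i], ed$to[i]] <- Q[ed$from[i], ed$to[i]] +
      scale * edge_rate(gene, ed$from[i], ed$type[i], g)
  }
  diag(Q) <- -(rowSums(Q) - diag(Q))
  as_sparse(Q)
}

gene_pos <- function(idx, name) {
  p <- match(name, idx$gene_names)
  if (is.na(p)) stop("gene '", name, "' is not part of this model")
  p
}

mmr_pos <- function(idx) {
  roles <- vapply(idx$genes, `[[`, "", "role")
  p <- which(roles == "mmr")
  if (length(p) == 0) return(NA_integer_)
  p[1]
}

zero_matrix <- function(idx) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(idx$total_dim, idx$total_dim))
}

#' Independent-mutation component A
#'
#' Kronecker sum of the per-gene rate matrices; genotype transitions that
#' change exactly one gene by one mutational event, plus the per-genotype
#' fitness self-loops inherited from the gene diagonals.
#'
#' @param graphs List of \code{\link{mutation_graph}}s in the index gene
#'   order.
#' @param idx The shared \code{\link{genotype_index}}.
#' @return Sparse upper-triangular matrix of size \code{idx$total_dim}.
#' @export
build_A <- function(graphs, idx) {
  stopifnot(inherits(idx, "genotype_index"))
  nm <- vapply(graphs, function(gr) gr$gene$name, "")
  if (!identical(nm, idx$gene_names)) {
    stop("graphs must be given in the index gene order (",
         paste(idx$gene_names, collapse = ", "), ")")
  }
  kronecker_sum(lapply(graphs, `[[`, "Q"))
}

#' Dependency component B: APC point mutations accelerated by MMR deficiency
#'
#' In MMR-deficient genotypes (MMR status mm, ml or ll) the APC
#' point-mutation rate is multiplied by \code{beta + 1}; B carries the extra
#' \code{beta}-fold flux. Built as selector(MMR deficient) x I x
#' (beta-scaled APC point-mutation edges with compensating diagonal) x I x I.
#'
#' @param idx A \code{\link{genotype_index}} containing an MMR gene and APC.
#' @param deps A \code{\link{dependency_params}} object.
#' @param g A \code{\link{global_params}} object.
#' @return Sparse matrix with zero row sums.
#' @export
build_B <- function(idx, deps, g) {
  p_mmr <- mmr_pos(idx)
  if (is.na(p_mmr)) return(zero_matrix(idx))
  p_apc <- gene_pos(idx, "APC")
  factors <- lapply(seq_along(idx$genes), function(k) {
    if (k == p_mmr) {
      selector_diag(idx$states[[k]], altered_states("mmr"))
    } else if (k == p_apc) {
      scaled_edge_factor(idx$genes[[k]], g, "pt", deps$beta)
    } else {
      Matrix::Diagonal(idx$dims[k])
    }
  })
  kron_list(factors)
}

# The eight coupled MLH1 x CTNNB1 edge families shared by components C and E.
# A fraction r of the MLH1 LOH flux out of states m and l (with CTNNB1 not
# yet LOH-hit on both sides) is redirected onto edges where CTNNB1 gains an
# LOH event simultaneously: each plain MLH1 LOH edge receives weight -w and
# its simultaneous counterpart +w, so every row sums to zero.
mlh1_ctnnb1_pair_matrix <- function(idx, w) {
  p_mmr <- mmr_pos(idx)
  p_ct <- gene_pos(idx, "CTNNB1")
  if (is.na(p_mmr) || p_ct != p_mmr + 1L) {
    stop("the MLH1-CTNNB1 coupling needs the MMR gene immediately followed ",
         "by CTNNB1 in the gene order")
  }
  sm <- idx$states[[p_mmr]]
  sc <- idx$states[[p_ct]]
  if (!"ll" %in% sm) {
    stop("the MMR gene factor is misconfigured: state 'll' is required")
  }
  dm <- length(sm)
  dc <- length(sc)
  pair_index <- function(ms, cs) (match(ms, sm) - 1L) * dc + match(cs, sc)
  fam <- rbind(
    # redirected (plain MLH1 LOH) edges: weight -w
    data.frame(mf = "m", cf = "0", mt = "ml", ct = "0", s = -1),
    data.frame(mf = "l", cf = "0", mt = "ll", ct = "0", s = -1),
    data.frame(mf = "m", cf = "m", mt = "ml", ct = "m", s = -1),
    data.frame(mf = "l", cf = "m", mt = "ll", ct = "m", s = -1),
    # simultaneous MLH1+CTNNB1 LOH edges: weight +w
    data.frame(mf = "m", cf = "0", mt = "ml", ct = "l", s = +1),
    data.frame(mf = "l", cf = "0", mt = "ll", ct = "l", s = +1),
    data.frame(mf = "m", cf = "m", mt = "ml", ct = "ml", s = +1),
    data.frame(mf = "l", cf = "m", mt = "ll", ct = "ml", s = +1)
  )
  Matrix::sparseMatrix(i = pair_index(fam$mf, fam$cf),
                       j = pair_index(fam$mt, fam$ct),
                       x = fam$s * w, dims = c(dm * dc, dm * dc))
}

#' Dependency component C: positive association of MLH1 and CTNNB1
#'
#' A fraction \code{r_effloh} of the MLH1 LOH flux is redirected onto edges
#' where CTNNB1 simultaneously suffers an LOH event. Zero unless the model's
#' MMR gene is MLH1 (the association is MLH1-specific). For the Lynch gene
#' order this matrix has exactly 400 structural nonzeros: 8 edge families
#' times the 50 background states of APC, KRAS and TP53.
#'
#' @inheritParams build_B
#' @param mmr_gene Name of the MMR gene in the configuration.
#' @return Sparse matrix with zero row sums (no diagonal entries).
#' @export
build_C <- function(idx, deps, g, mmr_gene) {
  p_mmr <- mmr_pos(idx)
  if (is.na(p_mmr) || !identical(mmr_gene, "MLH1") || deps$r_effloh == 0) {
    return(zero_matrix(idx))
  }
  mlh1 <- idx$genes[[p_mmr]]
  w <- deps$r_effloh * loh_rate(mlh1, 1, g)
  C_mc <- mlh1_ctnnb1_pair_matrix(idx, w)
  rest <- lapply(setdiff(seq_along(idx$genes), c(p_mmr, p_mmr + 1L)),
                 function(k) Matrix::Diagonal(idx$dims[k]))
  kron_list(c(list(C_mc), rest))
}

#' Dependency component D: LOH accelerated after APC inactivation
#'
#' In APC-inactivated genotypes (APC status mm or ml) the LOH rates of the
#' MMR gene, CTNNB1 and TP53 are multiplied by \code{delta + 1}. D is the sum
#' of one term per affected gene, each a Kronecker product of the
#' delta-scaled LOH edges of that gene, the APC selector diagonal, and
#' identities.
#'
#' @inheritParams build_B
#' @return Sparse matrix with zero row sums.
#' @export
build_D <- function(idx, deps, g) {
  p_apc <- gene_pos(idx, "APC")
  targets <- which(vapply(idx$genes, function(gn) {
    gn$name != "APC" && gn$role != "oncogene" && !is.na(gn$n_bp)
  }, TRUE))
  D <- zero_matrix(idx)
  if (deps$delta == 0) return(D)
  for (tg in targets) {
    factors <- lapply(seq_along(idx$genes), function(k) {
      if (k == tg) {
        scaled_edge_factor(idx$genes[[k]], g, "loh", deps$delta)
      } else if (k == p_apc) {
        selector_diag(idx$states[[k]], c("mm", "ml"))
      } else {
        Matrix::Diagonal(idx$dims[k])
      }
    })
    D <- D + kron_list(factors)
  }
  D
}

#' Dependency component E: mutual enhancement of C and D
#'
#' After APC inactivation the redirected MLH1-CTNNB1 LOH flux of component C
#' is itself subject to the delta-fold LOH acceleration: the same eight
#' plus/minus edge families as C, with magnitude
#' \code{delta * r_effloh * p_LOH(MLH1)/2}, applied only on APC-inactivated
#' genotypes via the selector diagonal.
#'
#' @inheritParams build_C
#' @return Sparse matrix with zero row sums.
#' @export
build_E <- function(idx, deps, g, mmr_gene) {
  p_mmr <- mmr_pos(idx)
  if (is.na(p_mmr) || !identical(mmr_gene, "MLH1") ||
      deps$r_effloh == 0 || deps$delta == 0) {
    return(zero_matrix(idx))
  }
  mlh1 <- idx$genes[[p_mmr]]
  w <- deps$delta * deps$r_effloh * loh_rate(mlh1, 1, g)
  E_mc <- mlh1_ctnnb1_pair_matrix(idx, w)
  p_apc <- gene_pos(idx, "APC")
  rest <- lapply(setdiff(seq_along(idx$genes), c(p_mmr, p_mmr + 1L)),
                 function(k) {
                   if (k == p_apc) {
                     selector_diag(idx$states[[k]], c("mm", "ml"))
                   } else {
                     Matrix::Diagonal(idx$dims[k])
                   }
                 })
  kron_list(c(list(E_mc), rest))
}

#' Dependency component F: KRAS mutations accelerated by MMR deficiency
#'
#' In MMR-deficient genotypes the KRAS activating point-mutation rate is
#' multiplied by \code{zeta + 1}; F carries the extra \code{zeta}-fold flux.
#'
#' @inheritParams build_B
#' @return Sparse matrix with zero row sums.
#' @export
build_F <- function(idx, deps, g) {
  p_mmr <- mmr_pos(idx)
  if (is.na(p_mmr)) return(zero_matrix(idx))
  p_kras <- gene_pos(idx, "KRAS")
  factors <- lapply(seq_along(idx$genes), function(k) {
    if (k == p_mmr) {
      selector_diag(idx$states[[k]], altered_states("mmr"))
    } else if (k == p_kras) {
      scaled_edge_factor(idx$genes[[k]], g, "pt", deps$zeta)
    } else {
      Matrix::Diagonal(idx$dims[k])
    }
  })
  kron_list(factors)
}

#' Assemble the full system matrix
#'
#' Builds the per-gene mutation graphs, the genotype index, the independent
#' component A and the active dependency components B--F for a scenario
#' configuration, and sums them into the system matrix M of the linear
#' dynamics \eqn{\dot x(t) = M^\top x(t)}.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return An object of class \code{system_matrix} with the genotype
#'   \code{index}, the per-gene \code{graphs}, the components \code{A},
#'   \code{B}, \code{C}, \code{D}, \code{E}, \code{F}, their sum \code{M},
#'   and the \code{config}.
#' @export
build_system_matrix <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g <- config$globals
  graphs <- lapply(config$genes, build_gene_graph, g = g)
  idx <- genotype_index(config$genes)
  A <- build_A(graphs, idx)
  act <- config$active
  deps <- config$deps
  B <- if ("B" %in% act && deps$beta > 0) build_B(idx, deps, g) else zero_matrix(idx)
  C <- if ("C" %in% act) build_C(idx, deps, g, config$mmr_gene) else zero_matrix(idx)
  D <- if ("D" %in% act && deps$delta > 0) build_D(idx, deps, g) else zero_matrix(idx)
  E <- if ("E" %in% act) build_E(idx, deps, g, config$mmr_gene) else zero_matrix(idx)
  F_ <- if ("F" %in% act && deps$zeta > 0) build_F(idx, deps, g) else zero_matrix(idx)
  M <- A + B + C + D + E + F_
  structure(list(index = idx, graphs = graphs, A = A, B = B, C = C, D = D,
                 E = E, F = F_, M = M, config = config),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat(sprintf("<system_matrix> %s: %d x %d, nnz(M) = %d\n",
              x$config$scenario, x$index$total_dim, x$index$total_dim,
              Matrix::nnzero(x$M)))
  invisible(x)
}
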