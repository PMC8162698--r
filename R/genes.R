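# Gene-level model: mutation-status state sets, per-year point-mutation and
# LOH rates, fitness terms, and the per-gene mutation graphs.

#' Canonical mutation-status order
#'
#' All gene state sets are subsets of \code{0 < m < l < mm < ml < ll}
#' (\code{"0"} is the wild-type, rendered ASCII-safe). Mutations are
#' irreversible, so every transition goes from an earlier to a later state and
#' every rate matrix is upper triangular in this order.
#'
#' @format Character vector of length 6.
#' @export
CANONICAL_STATES <- c("0", "m", "l", "mm", "ml", "ll")

# number of already-hit alleles per mutation status
.N_MUT <- c("0" = 0L, "m" = 1L, "l" = 1L, "mm" = 2L, "ml" = 2L, "ll" = 2L)

#' Number of mutated alleles for a mutation status
#'
#' @param state Character vector of mutation statuses.
#' @return Integer vector: 0 for wild-type, 1 for \code{m}/\code{l}, 2 for
#'   biallelically hit states.
#' @export
n_mut_of_state <- function(state) {
  bad <- setdiff(state, CANONICAL_STATES)
  if (length(bad) > 0) {
    stop("unknown mutation status: ", paste(bad, collapse = ", "))
  }
  unname(.N_MUT[state])
}

#' Global model parameters
#'
#' Collects the crypt- and genome-level constants shared by all genes:
#' point mutations per cell division \code{n_pt}, dividing cells per crypt
#' \code{n_cells}, genome length \code{n_bp_genome} (bp), number of crypts in
#' the colon \code{n_crypts}, the day-to-year conversion factor, and the
#' per-bp LOH proportionality constant \code{alpha} (per bp), which is
#' obtained by \code{\link{calibrate_alpha}} and may be left \code{NA} until
#' calibrated.
#'
#' @param n_pt Point mutations accumulated per cell division (one division
#'   per day is assumed).
#' @param n_cells Number of dividing cells per crypt.
#' @param n_bp_genome Genome length in base pairs.
#' @param n_crypts Number of crypts in the colon.
#' @param days_per_year Conversion constant from per-day to per-year rates.
#' @param alpha Per-bp LOH proportionality constant, or \code{NA} if not yet
#'   calibrated.
#' @return An object of class \code{global_params}.
#' @export
global_params <- function(n_pt = 1.2, n_cells = 1500, n_bp_genome = 3.2e9,
                          n_crypts = 9.95e6, days_per_year = 365,
                          alpha = NA_real_) {
  vals <- list(n_pt = n_pt, n_cells = n_cells, n_bp_genome = n_bp_genome,
               n_crypts = n_crypts, days_per_year = days_per_year)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("global parameter '", nm, "' must be a single positive finite number")
    }
  }
  if (!is.na(alpha) && (!is.finite(alpha) || alpha < 0)) {
    stop("alpha must be nonnegative and finite (or NA before calibration)")
  }
  structure(c(vals, list(alpha = alpha)), class = "global_params")
}

.roles <- c("mmr", "tumor_suppressor", "oncogene", "biallelic_oncogene")

# mutation statuses in which the gene is considered functionally altered
# (MMR deficient, tumor suppressor inactivated, oncogene activated)
altered_states <- function(role) {
  switch(role,
    mmr = c("mm", "ml", "ll"),
    tumor_suppressor = c("mm", "ml"),
    biallelic_oncogene = c("mm", "ml"),
    oncogene = "m",
    stop("unknown gene role: ", role)
  )
}

#' Define a gene
#'
#' A gene is described by its role (which fixes the admissible mutation-status
#' set), its hotspot count \code{n_hs} (driver-relevant base pairs), total
#' length \code{n_bp} (bp, used for LOH; may be \code{NA} for genes without an
#' LOH channel such as KRAS), fixation affinity \code{f} (tendency of a mutant
#' lineage to take over its crypt), and a per-year fitness term
#' \code{b_altered} applied as a self-loop to the functionally altered states.
#'
#' @param name Gene identifier, e.g. \code{"MLH1"}.
#' @param role One of \code{"mmr"}, \code{"tumor_suppressor"},
#'   \code{"oncogene"}, \code{"biallelic_oncogene"}.
#' @param states Ordered mutation statuses; must follow the canonical order
#'   \code{0 < m < l < mm < ml < ll}.
#' @param n_hs Hotspot base pairs.
#' @param n_bp Gene length in base pairs (\code{NA} for no LOH channel).
#' @param f Fixation affinity (dimensionless).
#' @param b_altered Fitness term (per year) on functionally altered states;
#'   may be negative.
#' @return An object of class \code{gene_spec}.
#' @export
gene_spec <- function(name, role, states, n_hs, n_bp = NA_real_, f,
                      b_altered = 0) {
  role <- match.arg(role, .roles)
  states <- as.character(states)
  if (!all(states %in% CANONICAL_STATES)) {
    stop("gene '", name, "': unknown mutation status in state set")
  }
  ord <- match(states, CANONICAL_STATES)
  if (is.unsorted(ord, strictly = TRUE)) {
    stop("gene '", name, "': states must follow the canonical order ",
         paste(CANONICAL_STATES, collapse = " < "))
  }
  if (role == "oncogene" && !identical(states, c("0", "m"))) {
    stop("gene '", name, "': an oncogene has exactly the states {0, m}")
  }
  if (role %in% c("tumor_suppressor", "biallelic_oncogene") &&
      "ll" %in% states) {
    stop("gene '", name, "': biallelic LOH (ll) is lethal for this role and ",
         "is not part of the state space")
  }
  if (role == "mmr" && !all(c("mm", "ml", "ll") %in% states)) {
    stop("gene '", name, "': an MMR gene needs the deficient states mm, ml, ll")
  }
  if (!is.numeric(n_hs) || length(n_hs) != 1L || !is.finite(n_hs) || n_hs <= 0) {
    stop("gene '", name, "': n_hs must be a single positive number")
  }
  if (!is.na(n_bp)) {
    if (!is.finite(n_bp) || n_bp <= 0) {
      stop("gene '", name, "': n_bp must be positive (or NA)")
    }
    if (n_hs > n_bp) stop("gene '", name, "': n_hs must not exceed n_bp")
  }
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0) {
    stop("gene '", name, "': f must be a single nonnegative number")
  }
  if (!is.numeric(b_altered) || length(b_altered) != 1L || !is.finite(b_altered)) {
    stop("gene '", name, "': b_altered must be a single finite number")
  }
  structure(list(name = name, role = role, states = states, n_hs = n_hs,
                 n_bp = n_bp, f = f, b_altered = b_altered),
            class = "gene_spec")
}

#' @export
print.gene_spec <- function(x, ...) {
  cat(sprintf("<gene_spec> %s (%s): states {%s}, n_hs=%g, n_bp=%s, f=%g, b=%g\n",
              x$name, x$role, paste(x$states, collapse = ","), x$n_hs,
              ifelse(is.na(x$n_bp), "NA", format(x$n_bp)), x$f, x$b_altered))
  invisible(x)
}

#' Per-year point-mutation rate of a gene
#'
#' Crypt-level rate of acquiring a driver-relevant point mutation, given
#' \code{n_mut} alleles already hit:
#' \deqn{p_{pt} = 365\, n_{pt}\, n_{cells}\, \frac{n_{hs}}{n_{bp,genome}}\, f\,
#'   (1 - n_{mut}/2).}
#' Alleles mutate independently, so one already-hit allele halves the rate and
#' two already-hit alleles give rate zero.
#'
#' @param gene A \code{\link{gene_spec}}.
#' @param n_mut Number of already mutated alleles (0, 1 or 2).
#' @param g A \code{\link{global_params}} object.
#' @return Rate per year (nonnegative scalar).
#' @export
point_mutation_rate <- function(gene, n_mut, g) {
  stopifnot(inherits(gene, "gene_spec"), inherits(g, "global_params"))
  if (!n_mut %in% c(0, 1, 2)) stop("n_mut must be 0, 1 or 2")
  g$days_per_year * g$n_pt * g$n_cells * (gene$n_hs / g$n_bp_genome) *
    gene$f * (1 - n_mut / 2)
}

#' Per-year LOH rate of a gene
#'
#' Crypt-level rate of a relevant loss-of-heterozygosity event. LOH deletes
#' whole exons, so the rate is proportional to the gene length \code{n_bp}
#' via the gene-independent constant \code{alpha}:
#' \deqn{p_{LOH} = 365\, n_{cells}\, (1 - n_{mut}/2)\, \alpha\, n_{bp}\, f.}
#'
#' @inheritParams point_mutation_rate
#' @return Rate per year.
#' @seealso \code{\link{calibrate_alpha}}
#' @export
loh_rate <- function(gene, n_mut, g) {
  stopifnot(inherits(gene, "gene_spec"), inherits(g, "global_params"))
  if (!n_mut %in% c(0, 1, 2)) stop("n_mut must be 0, 1 or 2")
  if (is.na(g$alpha)) {
    stop("alpha has not been calibrated; run calibrate_alpha() first")
  }
  if (is.na(gene$n_bp)) {
    stop("gene '", gene$name, "' has no length (n_bp); no LOH channel")
  }
  g$days_per_year * g$n_cells * (1 - n_mut / 2) * g$alpha * gene$n_bp * gene$f
}

#' Calibrate the LOH proportionality constant alpha
#'
#' MLH1 inactivation is observed to be twice as likely via LOH as via point
#' mutation, i.e. \eqn{p_{LOH}(MLH1) = 2\, p_{pt}(MLH1)}. Solving for the
#' per-bp constant gives
#' \deqn{\alpha = \frac{2\, n_{hs}(MLH1)\, n_{pt}}{n_{bp}(MLH1)\,
#'   n_{bp,genome}},}
#' which is independent of the gene it is subsequently applied to.
#'
#' @param g A \code{\link{global_params}} object.
#' @param mlh1 The MLH1 \code{\link{gene_spec}} (needs \code{n_hs} and
#'   \code{n_bp}).
#' @return The calibrated alpha (per bp), as a plain number.
#' @export
calibrate_alpha <- function(g, mlh1) {
  stopifnot(inherits(g, "global_params"), inherits(mlh1, "gene_spec"))
  if (is.na(mlh1$n_bp) || mlh1$n_bp == 0) {
    stop("calibration gene must have a nonzero length n_bp")
  }
  2 * mlh1$n_hs * g$n_pt / (mlh1$n_bp * g$n_bp_genome)
}

# Enumerate the mutation edges of a gene as (from, to, type).
# The rate of an edge is the point-mutation or LOH rate evaluated at the
# allele count of the *source* state, which carries the factor (1 - n_mut/2).
gene_edges <- function(gene) {
  s <- gene$states
  if (gene$role == "oncogene") {
    return(data.frame(from = "0", to = "m", type = "pt",
                      stringsAsFactors = FALSE))
  }
  e <- list()
  add <- function(from, to, type) {
    if (from %in% s && to %in% s) {
      e[[length(e) + 1L]] <<- data.frame(from = from, to = to, type = type,
                                         stringsAsFactors = FALSE)
    }
  }
  add("0", "m", "pt")
  add("0", "l", "loh")
  add("m", "mm", "pt")
  add("m", "ml", "loh")
  add("l", "ml", "pt")
  add("l", "ll", "loh")
  do.call(rbind, e)
}

edge_rate <- function(gene, from, type, g) {
  k <- n_mut_of_state(from)
  if (type == "pt") point_mutation_rate(gene, k, g) else loh_rate(gene, k, g)
}

#' Build the mutation graph of one gene
#'
#' Returns the gene's per-year rate matrix over its mutation statuses.
#' Off-diagonal entries are the point-mutation and LOH rates between statuses
#' differing by one mutational event; the diagonal follows the
#' continuous-time generator convention
#' \code{diag = b(state) - sum(outgoing rates)}, where \code{b(state)} is the
#' gene's fitness term on its functionally altered states and 0 elsewhere.
#' With all fitness terms zero every row sums to zero, so the ensuing
#' dynamics conserve the total crypt count.
#'
#' @param gene A \code{\link{gene_spec}}.
#' @param g A \code{\link{global_params}} object with calibrated alpha (unless
#'   the gene has no LOH channel).
#' @return An object of class \code{mutation_graph} with elements
#'   \code{gene}, \code{states} and the rate matrix \code{Q} (per year).
#' @export
build_gene_graph <- function(gene, g) {
  stopifnot(inherits(gene, "gene_spec"), inherits(g, "global_params"))
  s <- gene$states
  n <- length(s)
  Q <- matrix(0, n, n, dimnames = list(s, s))
  ed <- gene_edges(gene)
  for (i in seq_len(nrow(ed))) {
    Q[ed$from[i], ed$to[i]] <- Q[ed$from[i], ed$to[i]] +
      edge_rate(gene, ed$from[i], ed$type[i], g)
  }
  b <- ifelse(s %in% altered_states(gene$role), gene$b_altered, 0)
  diag(Q) <- b - (rowSums(Q) - diag(Q))
  structure(list(gene = gene, states = s, Q = Q), class = "mutation_graph")
}

#' @export
print.mutation_graph <- function(x, ...) {
  cat(sprintf("<mutation_graph> %s (%d states)\n", x$gene$name,
              length(x$states)))
  print(signif(x$Q, 4))
  invisible(x)
}
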