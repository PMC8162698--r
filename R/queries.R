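# Aggregation of trajectories into named genotype classes (MMR-deficient
# foci, adenomatous and cancerous states) and pathway-proportion summaries.

#' Define a genotype-class query
#'
#' A query is a union of conjunctive clauses; each clause restricts some
#' genes to admissible mutation-status sets (genes not mentioned are
#' unrestricted). A genotype matches the query if it matches any clause; the
#' query value at an age is the summed crypt count over matching genotypes.
#'
#' @param name Query label.
#' @param ... One or more clauses, each a named list mapping gene names to
#'   character vectors of admissible statuses.
#' @return An object of class \code{state_query}.
#' @export
state_query <- function(name, ...) {
  clauses <- list(...)
  if (length(clauses) == 0) stop("a query needs at least one clause")
  for (cl in clauses) {
    if (is.null(names(cl)) || any(names(cl) == "")) {
      stop("every clause must be a named list of gene -> states")
    }
  }
  structure(list(name = name, clauses = clauses), class = "state_query")
}

# logical mask over flat indices
query_mask <- function(q, idx) {
  stopifnot(inherits(q, "state_query"), inherits(idx, "genotype_index"))
  mask <- rep(FALSE, idx$total_dim)
  for (cl in clauses <- q$clauses) {
    m <- rep(TRUE, idx$total_dim)
    for (gene in names(cl)) {
      if (!gene %in% idx$gene_names) {
        stop("query '", q$name, "' refers to gene '", gene,
             "' which is not in the model")
      }
      allowed <- cl[[gene]]
      bad <- setdiff(allowed, idx$states[[gene_pos(idx, gene)]])
      if (length(bad) > 0) {
        stop("query '", q$name, "': state(s) ", paste(bad, collapse = ","),
             " not in the state set of gene '", gene, "'")
      }
      m <- m & idx$tuples[, gene] %in% allowed
    }
    mask <- mask | m
  }
  mask
}

# status sets used by the built-in queries
.TS_INACTIVE <- c("mm", "ml")             # both alleles hit
.MMR_DEFICIENT <- c("mm", "ml", "ll")

#' Built-in genotype classes
#'
#' Named classes following the multistage pathway logic:
#' \describe{
#'   \item{mmr_deficient_foci}{MMR deficient (mm/ml/ll) with all other genes
#'     wild-type -- the earliest detectable precursor lesions.}
#'   \item{mmr_deficient}{MMR deficient, other genes unrestricted.}
#'   \item{state1}{early adenomatous: Wnt pathway altered (APC inactivated or
#'     CTNNB1 biallelically activated), KRAS and TP53 intact.}
#'   \item{state2}{late adenomatous: Wnt altered and KRAS activated, TP53
#'     intact.}
#'   \item{state3}{cancerous: Wnt altered, KRAS activated and TP53
#'     inactivated -- alterations in three key pathways.}
#'   \item{state1_apc / state1_ctnnb1 (and state2/state3 analogues)}{the
#'     decomposition of each state by the driving Wnt gene.}
#'   \item{apc_inactivated}{APC in mm/ml, anything else.}
#' }
#' "Intact" is read functionally by default: TP53 intact means not
#' inactivated (0/m/l), KRAS intact means wild-type. Under
#' \code{interpretation = "strict"} intact means strictly wild-type, and the
#' Wnt requirement demands both CTNNB1 activation and APC inactivation.
#'
#' @param name Class name (see above).
#' @param idx A \code{\link{genotype_index}} (used to validate gene presence).
#' @param interpretation \code{"functional"} (default) or \code{"strict"}.
#' @return A \code{\link{state_query}}.
#' @export
builtin_query <- function(name, idx,
                          interpretation = c("functional", "strict")) {
  interpretation <- match.arg(interpretation)
  strict <- interpretation == "strict"
  tp53_intact <- if (strict) "0" else c("0", "m", "l")
  kras_intact <- "0"
  mmr <- idx$gene_names[mmr_pos(idx)]
  wnt_clauses <- function(extra) {
    apc <- c(list(APC = .TS_INACTIVE), extra)
    ct <- c(list(CTNNB1 = .TS_INACTIVE), extra)
    if (strict) list(c(apc, list(CTNNB1 = .TS_INACTIVE))) else list(apc, ct)
  }
  wild <- function(genes) {
    cl <- as.list(rep("0", length(genes)))
    names(cl) <- genes
    cl
  }
  q <- switch(name,
    mmr_deficient_foci = {
      if (is.na(mmr)) stop("no MMR gene in this model")
      others <- setdiff(idx$gene_names, mmr)
      cl <- c(stats::setNames(list(.MMR_DEFICIENT), mmr), wild(others))
      list(cl)
    },
    mmr_deficient = {
      if (is.na(mmr)) stop("no MMR gene in this model")
      list(stats::setNames(list(.MMR_DEFICIENT), mmr))
    },
    state1 = wnt_clauses(list(KRAS = kras_intact, TP53 = tp53_intact)),
    state2 = wnt_clauses(list(KRAS = "m", TP53 = tp53_intact)),
    state3 = wnt_clauses(list(KRAS = "m", TP53 = .TS_INACTIVE)),
    state1_apc = list(list(APC = .TS_INACTIVE, KRAS = kras_intact,
                           TP53 = tp53_intact)),
    state1_ctnnb1 = list(list(CTNNB1 = .TS_INACTIVE, KRAS = kras_intact,
                              TP53 = tp53_intact)),
    state2_apc = list(list(APC = .TS_INACTIVE, KRAS = "m",
                           TP53 = tp53_intact)),
    state2_ctnnb1 = list(list(CTNNB1 = .TS_INACTIVE, KRAS = "m",
                              TP53 = tp53_intact)),
    state3_apc = list(list(APC = .TS_INACTIVE, KRAS = "m",
                           TP53 = .TS_INACTIVE)),
    state3_ctnnb1 = list(list(CTNNB1 = .TS_INACTIVE, KRAS = "m",
                              TP53 = .TS_INACTIVE)),
    apc_inactivated = list(list(APC = .TS_INACTIVE)),
    stop("unknown built-in genotype class '", name, "'")
  )
  do.call(state_query, c(list(name = name), q))
}

#' Aggregate a trajectory over a genotype class
#'
#' @param traj A \code{crypt_trajectory} with a genotype index.
#' @param q A \code{\link{state_query}}, or the name of a built-in class.
#' @param interpretation Passed to \code{\link{builtin_query}} when \code{q}
#'   is a name.
#' @return Numeric vector of summed crypt counts, named by age.
#' @export
aggregate_states <- function(traj, q,
                             interpretation = c("functional", "strict")) {
  stopifnot(inherits(traj, "crypt_trajectory"))
  if (is.null(traj$index)) stop("trajectory has no genotype index")
  if (is.character(q)) {
    q <- builtin_query(q, traj$index, match.arg(interpretation))
  }
  mask <- query_mask(q, traj$index)
  out <- colSums(traj$counts[mask, , drop = FALSE])
  names(out) <- format(traj$ages, trim = TRUE)
  out
}

# Vogelstein-sequence stage clauses for pathway_proportions(). CTNNB1 is
# deliberately unrestricted: the stages follow the classical APC track.
stage_clause <- function(stage) {
  switch(stage,
    apc_inactivated = list(APC = .TS_INACTIVE),
    apc_only = list(APC = .TS_INACTIVE, KRAS = "0", TP53 = c("0", "m", "l")),
    apc_kras = list(APC = .TS_INACTIVE, KRAS = "m"),
    apc_kras_tp53 = list(APC = .TS_INACTIVE, KRAS = "m",
                         TP53 = .TS_INACTIVE),
    stop("unknown stage '", stage, "'")
  )
}

#' MMR-deficient vs MMR-proficient proportions along the adenoma-carcinoma
#' sequence
#'
#' For each progression stage (APC inactivated; plus KRAS activated; plus
#' TP53 inactivated) and each age, the fraction of crypts in that stage that
#' are MMR-deficient (mm/ml/ll) versus MMR-proficient. The two fractions sum
#' to one wherever the stage holds any crypts; stages with zero mass are
#' reported as \code{NA}.
#'
#' @param traj A \code{crypt_trajectory} from a model that includes an MMR
#'   gene.
#' @param stages Character vector of stages from
#'   \code{c("apc_inactivated", "apc_only", "apc_kras", "apc_kras_tp53")}.
#' @return A data frame with columns \code{age}, \code{stage},
#'   \code{n_total}, \code{frac_mmr_deficient}, \code{frac_mmr_proficient}.
#' @export
pathway_proportions <- function(traj, stages = c("apc_inactivated",
                                                 "apc_kras",
                                                 "apc_kras_tp53")) {
  stopifnot(inherits(traj, "crypt_trajectory"))
  idx <- traj$index
  if (is.null(idx)) stop("trajectory has no genotype index")
  p_mmr <- mmr_pos(idx)
  if (is.na(p_mmr)) stop("pathway proportions need an MMR gene in the model")
  mmr <- idx$gene_names[p_mmr]
  res <- lapply(stages, function(st) {
    cl <- stage_clause(st)
    total <- aggregate_states(traj, do.call(state_query, c(list(st), list(cl))))
    def_cl <- c(cl, stats::setNames(list(.MMR_DEFICIENT), mmr))
    deficient <- aggregate_states(
      traj, do.call(state_query, c(list(paste0(st, "_def")), list(def_cl))))
    frac_def <- ifelse(total > 0, deficient / total, NA_real_)
    data.frame(age = traj$ages, stage = st, n_total = unname(total),
               frac_mmr_deficient = unname(frac_def),
               frac_mmr_proficient = unname(ifelse(total > 0,
                                                   1 - deficient / total,
                                                   NA_real_)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Ratio of an aggregate between two runs
#'
#' @param traj_a,traj_b Trajectories on identical age grids.
#' @param q A \code{\link{state_query}} or built-in class name, evaluated in
#'   each trajectory's own genotype index.
#' @return Numeric vector \code{a/b} per age; \code{0/0} is reported as
#'   \code{NA}.
#' @export
compare_runs <- function(traj_a, traj_b, q) {
  stopifnot(inherits(traj_a, "crypt_trajectory"),
            inherits(traj_b, "crypt_trajectory"))
  if (!isTRUE(all.equal(traj_a$ages, traj_b$ages))) {
    stop("trajectories are on different age grids")
  }
  a <- aggregate_states(traj_a, q)
  b <- aggregate_states(traj_b, q)
  out <- ifelse(a == 0 & b == 0, NA_real_, a / b)
  names(out) <- names(a)
  out
}
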