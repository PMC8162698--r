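# Scenario presets: Lynch syndrome (MLH1/MSH2, point-mutation or LOH
# germline), Lynch-like / sporadic MSI, sporadic MSS, FAP and a sporadic-APC
# comparison case, as full configurations plus initial crypt vectors.

#' Dependency parameters
#'
#' Strengths of the modeled mutational dependencies: \code{beta} (APC point
#' mutations run at \code{beta + 1} times the base rate after MMR
#' deficiency), \code{delta} (LOH rates of MMR, CTNNB1 and TP53 run at
#' \code{delta + 1} times the base rate after APC inactivation), \code{zeta}
#' (KRAS activation at \code{zeta + 1} times after MMR deficiency) and
#' \code{r_effloh} (fraction of the MLH1 LOH flux redirected onto
#' simultaneous MLH1+CTNNB1 LOH events).
#'
#' @param beta,delta,zeta Nonnegative fold-change parameters.
#' @param r_effloh Redirection fraction in [0, 1].
#' @return An object of class \code{dependency_params}.
#' @export
dependency_params <- function(beta = 1e3, delta = 1e2, zeta = 1e2,
                              r_effloh = 0.9) {
  vals <- list(beta = beta, delta = delta, zeta = zeta, r_effloh = r_effloh)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("dependency parameter '", nm, "' must be a single nonnegative number")
    }
  }
  if (r_effloh > 1) stop("r_effloh must lie in [0, 1]")
  structure(vals, class = "dependency_params")
}

# Table defaults: hotspot counts, gene lengths, fixation affinities and
# fitness terms for the five modeled genes.
.GENE_DEFAULTS <- list(
  MLH1   = list(role = "mmr", n_hs = 2270, n_bp = 57500, f = 2.3e-6, b = -0.01),
  MSH2   = list(role = "mmr", n_hs = 2800, n_bp = 80000, f = 2.3e-6, b = -0.01),
  CTNNB1 = list(role = "biallelic_oncogene", n_hs = 5, n_bp = 41000,
                f = 1.2e-3, b = 0.0),
  APC    = list(role = "tumor_suppressor", n_hs = 2400, n_bp = 139000,
                f = 8.3e-7, b = 0.10),
  KRAS   = list(role = "oncogene", n_hs = 7, n_bp = NA_real_,
                f = 2.5e-8, b = 0.01),
  TP53   = list(role = "tumor_suppressor", n_hs = 1180, n_bp = 19200,
                f = 1.2e-5, b = 0.0)
)

#' Default specification of one of the modeled genes
#'
#' @param name One of MLH1, MSH2, CTNNB1, APC, KRAS, TP53.
#' @param mmr_states For MMR genes: the mutation-status set, which is
#'   \code{{m, l, mm, ml, ll}} in Lynch syndrome (the monoallelic germline
#'   hit is universal, so there is no wild-type status) and
#'   \code{{0, m, l, mm, ml, ll}} in the Lynch-like/sporadic setting.
#' @param ... Overrides for \code{n_hs}, \code{n_bp}, \code{f}, \code{b}.
#' @return A \code{\link{gene_spec}}.
#' @export
default_gene <- function(name, mmr_states = c("m", "l", "mm", "ml", "ll"),
                         ...) {
  d <- .GENE_DEFAULTS[[name]]
  if (is.null(d)) stop("no default specification for gene '", name, "'")
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% c("n_hs", "n_bp", "f", "b")) {
      stop("unknown gene parameter override '", nm, "'")
    }
    d[[nm]] <- ov[[nm]]
  }
  states <- switch(d$role,
    mmr = mmr_states,
    oncogene = c("0", "m"),
    c("0", "m", "l", "mm", "ml")
  )
  gene_spec(name, d$role, states, n_hs = d$n_hs, n_bp = d$n_bp, f = d$f,
            b_altered = d$b)
}

.SCENARIOS <- c("lynch-mlh1", "lynch-mlh1-loh", "lynch-msh2", "lynch-like",
                "sporadic-msi", "mss", "fap", "sporadic-apc")

#' Scenario configuration
#'
#' Low-level constructor; most users should start from \code{\link{preset}}.
#'
#' @param scenario Scenario identifier.
#' @param mmr_gene MMR gene name (\code{"MLH1"}, \code{"MSH2"}) or \code{NA}
#'   when the MMR factor is excluded (MSS).
#' @param germline One of \code{"point"} (monoallelic MMR point mutation at
#'   birth), \code{"loh"} (monoallelic MMR LOH), \code{"apc"} (monoallelic
#'   APC point mutation, FAP) or \code{"none"} (all crypts wild-type).
#' @param genes Ordered list of \code{\link{gene_spec}}s.
#' @param globals A \code{\link{global_params}}; alpha is calibrated from the
#'   MLH1 defaults if unset.
#' @param deps A \code{\link{dependency_params}}.
#' @param active Character subset of \code{c("B","C","D","E","F")} naming the
#'   dependency components to assemble.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(scenario, mmr_gene, germline, genes,
                            globals = global_params(),
                            deps = dependency_params(),
                            active = c("B", "C", "D", "E", "F")) {
  stopifnot(is.character(scenario), length(scenario) == 1L)
  germline <- match.arg(germline, c("point", "loh", "apc", "none"))
  if (!all(active %in% c("B", "C", "D", "E", "F"))) {
    stop("active components must be a subset of B, C, D, E, F")
  }
  if (is.na(globals$alpha)) {
    globals$alpha <- calibrate_alpha(globals, default_gene("MLH1"))
  }
  gene_names <- vapply(genes, `[[`, "", "name")
  if (!is.na(mmr_gene) && !mmr_gene %in% gene_names) {
    stop("mmr_gene '", mmr_gene, "' is not in the gene list")
  }
  if (germline %in% c("point", "loh") && is.na(mmr_gene)) {
    stop("an MMR germline variant requires an MMR gene in the model")
  }
  structure(list(scenario = scenario, mmr_gene = mmr_gene,
                 germline = germline, genes = genes, globals = globals,
                 deps = deps, active = active),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s: genes %s; germline %s; active {%s}\n",
              x$scenario,
              paste(vapply(x$genes, `[[`, "", "name"), collapse = ","),
              x$germline, paste(x$active, collapse = ",")))
  invisible(x)
}

#' Scenario presets
#'
#' Fully populated configurations with the default parameter tables:
#' \describe{
#'   \item{lynch-mlh1 / lynch-msh2}{Lynch syndrome with a monoallelic MMR
#'     point-mutation germline variant (the common case); the MMR state set
#'     has no wild-type status. MSH2 scenarios deactivate the MLH1-specific
#'     CTNNB1 coupling (components C and E).}
#'   \item{lynch-mlh1-loh}{as lynch-mlh1 but with an LOH germline variant
#'     (the rarer group of carriers).}
#'   \item{lynch-like / sporadic-msi}{no germline variant; the MMR gene gains
#'     the wild-type status 0 and all crypts start wild-type.}
#'   \item{mss}{microsatellite-stable carcinogenesis: the MMR factor is
#'     dropped entirely (250 genotypes); only the APC-triggered LOH
#'     acceleration D remains active.}
#'   \item{fap}{familial adenomatous polyposis: monoallelic APC
#'     point-mutation germline variant, APC hotspot count reduced to 600
#'     (classical codon 1250-1464 variants); MMR kept with the sporadic
#'     6-status set.}
#'   \item{sporadic-apc}{sporadic comparison case for FAP: no germline
#'     variant, no MMR factor.}
#' }
#'
#' @param name Scenario identifier, one of
#'   \code{"lynch-mlh1", "lynch-mlh1-loh", "lynch-msh2", "lynch-like",
#'   "sporadic-msi", "mss", "fap", "sporadic-apc"}.
#' @param globals,deps Optional replacements for the default parameter sets.
#' @return A \code{\link{scenario_config}}.
#' @export
preset <- function(name, globals = global_params(),
                   deps = dependency_params()) {
  name <- match.arg(name, .SCENARIOS)
  lynch_states <- c("m", "l", "mm", "ml", "ll")
  sporadic_states <- c("0", "m", "l", "mm", "ml", "ll")
  non_mmr <- function(apc_n_hs = 2400) {
    list(default_gene("CTNNB1"), default_gene("APC", n_hs = apc_n_hs),
         default_gene("KRAS"), default_gene("TP53"))
  }
  with_mmr <- function(mmr, states, apc_n_hs = 2400) {
    c(list(default_gene(mmr, mmr_states = states)), non_mmr(apc_n_hs))
  }
  switch(name,
    "lynch-mlh1" = scenario_config(name, "MLH1", "point",
      with_mmr("MLH1", lynch_states), globals, deps),
    "lynch-mlh1-loh" = scenario_config(name, "MLH1", "loh",
      with_mmr("MLH1", lynch_states), globals, deps),
    "lynch-msh2" = scenario_config(name, "MSH2", "point",
      with_mmr("MSH2", lynch_states), globals, deps,
      active = c("B", "D", "F")),
    "lynch-like" = scenario_config(name, "MLH1", "none",
      with_mmr("MLH1", sporadic_states), globals, deps),
    "sporadic-msi" = scenario_config(name, "MLH1", "none",
      with_mmr("MLH1", sporadic_states), globals, deps),
    "mss" = scenario_config(name, NA_character_, "none", non_mmr(),
      globals, deps, active = "D"),
    "fap" = scenario_config(name, "MLH1", "apc",
      with_mmr("MLH1", sporadic_states, apc_n_hs = 600), globals, deps),
    "sporadic-apc" = scenario_config(name, NA_character_, "none", non_mmr(),
      globals, deps, active = "D")
  )
}

#' Initial crypt distribution of a scenario
#'
#' All \code{n_crypts} crypts start in the single germline genotype: Lynch
#' point-mutation carriers at (m, 0, 0, 0, 0), Lynch LOH carriers at
#' (l, 0, 0, 0, 0), FAP at (0, 0, m, 0, 0), and Lynch-like/sporadic scenarios
#' fully wild-type.
#'
#' @param config A \code{\link{scenario_config}}.
#' @param idx The matching \code{\link{genotype_index}}.
#' @return Numeric vector of length \code{idx$total_dim}.
#' @export
initial_state <- function(config, idx) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(idx, "genotype_index"))
  tuple <- vapply(idx$genes, function(gn) {
    if (!"0" %in% gn$states) {
      NA_character_  # filled below for the germline gene
    } else {
      "0"
    }
  }, "")
  names(tuple) <- idx$gene_names
  if (config$germline %in% c("point", "loh")) {
    tuple[config$mmr_gene] <- if (config$germline == "point") "m" else "l"
  } else if (config$germline == "apc") {
    tuple["APC"] <- "m"
  }
  if (anyNA(tuple)) {
    stop("scenario '", config$scenario, "': gene '",
         idx$gene_names[which(is.na(tuple))[1]],
         "' has no wild-type status and no germline assignment")
  }
  x0 <- numeric(idx$total_dim)
  x0[flat_index(idx, tuple)] <- config$globals$n_crypts
  x0
}

# per-gene unit vectors reproducing initial_state() as a Kronecker product
initial_state_factors <- function(config, idx) {
  x0 <- initial_state(config, idx)
  pos <- which(x0 > 0)
  tuple <- idx$tuples[pos, ]
  lapply(seq_along(idx$genes), function(k) {
    e <- numeric(idx$dims[k])
    e[match(tuple[k], idx$states[[k]])] <- 1
    e
  })
}
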