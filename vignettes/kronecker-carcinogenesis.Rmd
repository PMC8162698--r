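---
title: "Modeling multiple pathways of colorectal carcinogenesis with Kronecker-structured linear systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling multiple pathways of colorectal carcinogenesis with Kronecker-structured linear systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kroncrc)
```

## The model

`kroncrc` models colorectal carcinogenesis at the level of colonic crypts.
Each crypt carries one genotype: a tuple of mutation statuses, one per driver
gene, drawn from `0` (wild-type), `m` (one allele point-mutated), `l` (one
allele lost by LOH), `mm`, `ml` and `ll`. The default gene set is a mismatch
repair (MMR) gene (MLH1 or MSH2), CTNNB1, APC, KRAS and TP53 — the drivers of
the hypothesized pathways of Lynch syndrome carcinogenesis. Roles constrain
the state sets:

* MMR genes need both alleles hit for deficiency; in Lynch syndrome every
  crypt carries the monoallelic germline hit, so the wild-type status is
  absent and the states are `m, l, mm, ml, ll`.
* APC and TP53 are classical two-hit tumor suppressors; in the colon CTNNB1
  behaves like one in that biallelic alteration is needed for a driver
  effect. Biallelic LOH (`ll`) of these genes is taken as lethal to the cell
  and the state is omitted, so their states are `0, m, l, mm, ml` with no
  `l -> ll` transition.
* KRAS is an oncogene activated by a single point mutation: states `0, m`,
  and no LOH channel.

The state of the whole colon is the vector `x(t)` of crypt counts per
genotype, evolving by the linear ODE

    x'(t) = (A + B + C + D + E + F)^T x(t),    x(0) = x0,

whose exact solution is the matrix exponential
`x(t) = expm(t M^T) x0` with `M = A + B + C + D + E + F`. Mutations are
irreversible, so every component is upper triangular in the canonical state
order and so is `M`.

### Per-gene rates

Crypt-level per-year transition rates combine the cell-level mutation
process with fixation (monoclonal conversion of the crypt):

* point mutation: `p_pt = 365 * n_pt * n_cells * (n_hs / n_bp_genome) * f * (1 - n_mut/2)`
* LOH: `p_loh = 365 * n_cells * (1 - n_mut/2) * alpha * n_bp * f`

with `n_pt = 1.2` point mutations per cell division (one division per day),
`n_cells = 1500` dividing cells per crypt, hotspot counts `n_hs` (bp of the
gene where a hit is a driver), genome length `n_bp_genome = 3.2e9` bp,
fixation affinity `f(gene)`, and `n_mut` the number of alleles already hit —
alleles mutate independently, hence the factor `(1 - n_mut/2)`. LOH events
are assumed large enough to inactivate any gene they touch, so their rate is
proportional to gene length `n_bp` through a single constant `alpha`,
calibrated from the observation that MLH1 is inactivated twice as often by
LOH as by point mutation:

```{r alpha}
g <- global_params()
mlh1 <- default_gene("MLH1")
g$alpha <- calibrate_alpha(g, mlh1)   # 2 n_hs n_pt / (n_bp n_bp_genome)
c(alpha = g$alpha,
  ratio = loh_rate(mlh1, 0, g) / point_mutation_rate(mlh1, 0, g))
```

The ratio is exactly 2 by construction, for any positive parameter set, and
`alpha` is gene-independent thereafter.

### Fitness and the diagonal convention

Clonal expansion or disappearance of crypts with a given mutation status is
modeled by a per-year fitness term `b(gene)` on the functionally altered
states (MMR deficient: `mm/ml/ll`; APC/CTNNB1/TP53 biallelically altered:
`mm/ml`; KRAS activated: `m`). Defaults: `b(MMR) = -0.01` (MMR deficiency is
disadvantageous), `b(APC) = 0.10` and `b(KRAS) = 0.01` (advantageous),
`b(CTNNB1) = b(TP53) = 0`.

The diagonal of each gene matrix follows the continuous-time generator
convention: `diag(state) = b(state) - sum(outgoing rates)`. With all `b = 0`
every row sums to zero, so the dynamics conserve the total crypt count
exactly — a property the test suite exploits as a global correctness check.
An alternative discrete-time reading (`1 - sum(outgoing)` self-loops) would
make the Kronecker sum of five factors grow as `exp(5t)` under the matrix
exponential and is therefore not used. Whether `b` should also act on
intermediate single-hit states is not empirically constrained; we attach it
to fully altered states only.

### Kronecker assembly

The independent-mutation component is the Kronecker sum of the gene matrices,

    A = A_MMR (+) A_CTNNB1 (+) A_APC (+) A_KRAS (+) A_TP53,

equivalently the adjacency of the Cartesian product of the gene mutation
graphs: exactly one gene moves per transition. For the Lynch configuration
the genotype space has `5*5*5*2*5 = 1250` states. The flat genotype index is
row-major with the first gene most significant, matching
`e_MMR %x% e_CTNNB1 %x% e_APC %x% e_KRAS %x% e_TP53`.

Mutational dependencies are additive components, each a Kronecker product of
(i) a modified gene factor carrying the extra flux, (ii) a 0/1 selector
diagonal restricting the effect to triggering genotypes, and (iii)
identities elsewhere:

* **B** — APC point mutations run `beta + 1` times faster after MMR
  deficiency (selector over MMR `mm/ml/ll`).
* **C** — positive association of MLH1 and CTNNB1: a fraction `r_effloh` of
  the MLH1 LOH flux is redirected onto edges where CTNNB1 simultaneously
  gains an LOH event. Eight coupled edge families over the MLH1 x CTNNB1
  pair space, each a `-w` entry (removed flux) paired with a `+w` entry
  (redirected flux) in the same row; crossed with the 50 background states
  of APC, KRAS and TP53 this gives exactly 400 structural nonzeros and no
  diagonal. The component is zero for MSH2 models — the association is
  MLH1-specific.
* **D** — LOH rates of the MMR gene, CTNNB1 and TP53 run `delta + 1` times
  faster after APC inactivation (selector over APC `mm/ml`); one term per
  affected gene, `D = D1 + D2 + D3`.
* **E** — mutual enhancement of C and D: the same eight-family redirection
  with magnitude `delta * r_effloh * p_loh(MLH1)/2`, active only on
  APC-inactivated genotypes (160 nonzeros).
* **F** — KRAS activation runs `zeta + 1` times faster after MMR deficiency.

Every dependency component has zero row sums: the components reroute or
accelerate flux but never create or destroy crypts; all fitness lives in
`A`. On the sign of the redirected C edges we follow the reading under which
each row of C sums to zero and the nonzero count is 400 with no diagonal
compensation — an all-negative C would need diagonal entries, exceed that
count and destroy mass.

Table defaults: `beta = 1e3`, `delta = 1e2`, `zeta = 1e2`,
`r_effloh = 0.9`; hotspots (bp) MLH1 2270, MSH2 2800, CTNNB1 5, APC 2400
(600 in FAP), KRAS 7, TP53 1180; lengths (bp) MLH1 57500, MSH2 80000,
CTNNB1 41000, APC 139000, TP53 19200; fixation affinities `f` 2.3e-6 (MMR),
1.2e-3 (CTNNB1), 8.3e-7 (APC), 2.5e-8 (KRAS), 1.2e-5 (TP53).

```{r assemble}
sm <- build_system_matrix(preset("lynch-mlh1"))
sm
c(nnz_C = Matrix::nnzero(sm$C), nnz_E = Matrix::nnzero(sm$E))
```

## Solving

`solve_trajectory()` evaluates `x(t) = expm(t M^T) x0` on an age grid. For
an autonomous linear system the solution operator over a step `dt` is
`expm(dt M^T)`, so the solver exponentiates once per distinct increment and
chains matrix-vector products — one dense 1250 x 1250 exponential for the
default yearly grid 0..70, a couple of seconds on one core. The rates are
small (`||M||` of order 0.1/yr), far from any stiffness or scaling issue.

Floating-point can produce slightly negative entries; anything within
`-1e-9 * sum(|x0|)` is clamped to zero, anything worse raises an error since
it indicates a violated generator convention. When no dependency is active
the solution factorizes per gene
(`x(t) = scale * kron_i expm(t A_i^T) e_i`), implemented in
`solve_factorized()`; full and factorized solutions agree to ~1e-14 relative
(sup norm), and the test suite requires 1e-8.

Verification is two-route throughout: the Kronecker assembly is compared
against a brute-force Cartesian-product enumeration
(`brute_force_product()`), and the exponential solver against an independent
stiff ODE integration (`dense_reference_solve()`, `deSolve::lsoda`) and
against closed-form small systems, on seeded random toy models
(`make_toy()`, rates uniform in `[1e-6, 1e-1]`/yr to span the real rate
magnitudes).

## Scenarios

`preset()` returns complete configurations:

* **lynch-mlh1 / lynch-mlh1-loh / lynch-msh2** — all `9.95e6` crypts start
  at the germline genotype `(m,0,0,0,0)` (point-mutation variant) or
  `(l,0,0,0,0)` (LOH variant). The two germline groups (roughly 90–95% vs
  5–10% of carriers) are separate runs, not mixed.
* **lynch-like / sporadic-msi** — the MMR gene gains the wild-type status
  (state set `0,m,l,mm,ml,ll`, 1500 genotypes) and all crypts start
  wild-type. The APC-triggered LOH acceleration extends to the MMR `0 -> l`
  edge, a mild extrapolation of the dependency to the enlarged state set.
* **mss / sporadic-apc** — the MMR factor is dropped (250 genotypes); only D
  (restricted to CTNNB1 and TP53) remains active.
* **fap** — germline APC point mutation, `x0` at `(0,0,m,0,0)`; the APC
  hotspot count drops to 600 (the classical codon 1250–1464 germline
  cluster). The MMR factor is kept with the sporadic state set since the
  initial genotype carries an MMR coordinate.

## Queries

`aggregate_states()` sums crypt counts over genotype classes defined as
unions of per-gene state restrictions. Built-ins follow the three-strikes
logic (cancer = three pathways altered): `mmr_deficient_foci` (MMR deficient,
all else wild-type), `state1` (early adenomatous: Wnt altered, KRAS and TP53
intact), `state2` (plus KRAS activated), `state3` (cancerous: plus TP53
inactivated). "Wnt altered" means APC inactivated **or** CTNNB1
biallelically activated — the prose definition is ambiguous on this point,
so the OR reading is the default, an AND/strict-wild-type reading is
available via `interpretation = "strict"`, and `state*_apc` / `state*_ctnnb1`
decompose each class by driver. `pathway_proportions()` reports the
MMR-deficient vs MMR-proficient split along the classical progression stages
(APC inactivated, plus KRAS, plus TP53; CTNNB1 unrestricted there).

```{r queries}
traj <- solve_trajectory(sm, ages = 0:70)
round(aggregate_states(traj, "mmr_deficient_foci")[c("10", "40", "70")], 1)
pp <- pathway_proportions(traj)
subset(pp, age == 70)
```

With every dependency zeroed the three stage proportions are identical (the
genotype distribution factorizes gene by gene); the dependencies are what
make MMR deficiency dominant after KRAS activation.

## Numerical and design notes

* **Problem sizes.** All shipped analyses use the native state spaces (250
  to 1500 genotypes) and yearly grids to age 70; nothing is down-scaled.
  Dense exponentials are the default up to a few thousand states, which
  covers every preset.
* **Ties/degenerate inputs.** Empty progression stages yield `NA` fractions
  (never NaN propagation); `0/0` ratios in `compare_runs()` are `NA`;
  zero-valued dependency parameters short-circuit to structurally zero
  components.
* **FAP magnitude.** With the default parameters the FAP run yields
  `1.075e5` APC-inactivated crypts at age 70. A closed-form corroboration —
  constant influx `n_crypts * (p_pt(APC,1) + p_loh(APC,1)) = 9.81`/yr into
  the APC-inactivated class growing at `b(APC) = 0.1`/yr gives
  `9.81 * (e^7 - 1)/0.1 = 1.075e5` — shows this is forced by the printed
  parameters under the generator convention, at the top of (and ~7.5% above)
  the `1e4`–`1e5` range reported for comparable simulations; the count is
  convention-sensitive and documented as such. It remains far below the
  `~1e7` polypous crypts suggested by polyp-count literature, as expected.
* **TP53 invariance.** No modeled dependency couples TP53 to MMR status, so
  the MMR-deficient share among APC+KRAS crypts should be unchanged by TP53
  inactivation. This holds to 0.0024 at age 70; at very early ages the two
  stages differ by up to 0.027 while the TP53-inactivated stage holds fewer
  than `1e-12` crypts — a transient of an unobservably occupied stage, which
  is why the invariance is asserted at end of life.
* **What the toy generator does and does not emulate.** `make_toy()`
  produces mass-preserving upper-triangular factors with realistic rate
  magnitudes; it deliberately omits fitness terms and dependency overlays,
  so oracle agreement validates the Kronecker/exponential machinery, not the
  biology of the presets. Conversely, the model itself is deterministic and
  crypt-autonomous: no stochastic fluctuations, no immune surveillance, no
  intra-crypt fixation dynamics (fixation enters only through `f`), and
  genotype classes map onto clinical stages only approximately.

## Limitations

Parameter values for fitness and fixation are weakly constrained by data;
absolute crypt counts should be read as order-of-magnitude statements, while
structural results (conservation, triangularity, proportions and orderings)
are robust. Allele phase within `ml` is not tracked, dominant-negative
single-hit effects are ignored, and death/disappearance is folded into the
fitness self-loops rather than modeled as explicit absorbing states.
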