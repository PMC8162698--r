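# Genotype-class aggregation and pathway proportions.

test_that("aggregates over a partition reproduce the total crypt count", {
  traj <- lynch_traj()
  idx <- traj$index
  # partition by KRAS status
  parts <- lapply(c("0", "m"), function(s) {
    aggregate_states(traj, state_query(paste0("kras_", s), list(KRAS = s)))
  })
  expect_equal(Reduce(`+`, parts), colSums(traj$counts))
})

test_that("built-in classes encode the pathway logic", {
  traj <- lynch_traj()
  foci <- aggregate_states(traj, "mmr_deficient_foci")
  expect_equal(unname(foci["0"]), 0)      # x0 has the germline m status
  expect_true(all(foci[-1] > 0))          # foci accumulate over life
  s1 <- aggregate_states(traj, "state1")
  s2 <- aggregate_states(traj, "state2")
  s3 <- aggregate_states(traj, "state3")
  expect_true(all(s1[-1] > 0) && all(s3[-1] > 0))
  # the strict-wild-type reading is a subset of the functional one
  for (q in c("state1", "state2", "state3")) {
    strict <- aggregate_states(traj, q, interpretation = "strict")
    functional <- aggregate_states(traj, q)
    expect_true(all(strict <= functional + 1e-12), info = q)
  }
  # the Wnt decomposition covers state1 (drivers can overlap)
  apc_share <- aggregate_states(traj, "state1_apc")
  ct_share <- aggregate_states(traj, "state1_ctnnb1")
  expect_true(all(s1 <= apc_share + ct_share + 1e-12))
  expect_true(all(pmax(apc_share, ct_share) <= s1 + 1e-12))
})

test_that("unknown labels and missing genes are query errors", {
  traj <- lynch_traj()
  expect_error(aggregate_states(traj, "state99"), "unknown built-in")
  expect_error(aggregate_states(traj, state_query("x", list(BRAF = "m"))),
               "not in the model")
  expect_error(aggregate_states(traj, state_query("x", list(KRAS = "ll"))),
               "not in the state set")
  mss_traj <- solve_trajectory(build_system_matrix(preset("mss")),
                               ages = c(0, 1))
  expect_error(aggregate_states(mss_traj, "mmr_deficient_foci"), "MMR")
  expect_error(pathway_proportions(mss_traj), "MMR")
})

test_that("pathway proportions sum to one and flag empty stages as NA", {
  pp <- pathway_proportions(lynch_traj())
  occupied <- !is.na(pp$frac_mmr_deficient)
  expect_true(any(occupied))
  expect_equal(pp$frac_mmr_deficient[occupied] + pp$frac_mmr_proficient[occupied],
               rep(1, sum(occupied)))
  # at age 0 every stage is empty: proportions undefined, not NaN
  at0 <- pp[pp$age == 0, ]
  expect_true(all(is.na(at0$frac_mmr_deficient)))
  expect_false(any(is.nan(pp$frac_mmr_deficient)))
})

test_that("with independent mutations the stage proportions coincide", {
  pp <- pathway_proportions(lynch_indep_traj())
  for (a in c(30, 50, 70)) {
    f <- pp$frac_mmr_deficient[pp$age == a]
    expect_lt(max(f) - min(f), 1e-10)
  }
})

test_that("compare_runs forms ratios with undefined 0/0 entries", {
  traj <- lynch_traj()
  r_self <- compare_runs(traj, traj, "mmr_deficient_foci")
  expect_equal(unname(r_self[-1]), rep(1, length(traj$ages) - 1))
  expect_true(is.na(r_self["0"]))  # 0/0 at birth
  short <- solve_trajectory(lynch_sm(), ages = c(0, 10))
  expect_error(compare_runs(traj, short, "mmr_deficient_foci"), "age grid")
})
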