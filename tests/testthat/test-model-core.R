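test_that("zero mortality with identity transitions gives a constant cohort", {
  epi <- toy_epi(p_death_delivery = 0, p_live_discharge = 1, s_d2 = 1,
                 annual = rep(1, 8),
                 init = c(none = 0.25, mild = 0.25, moderate = 0.25,
                          severe = 0.25))
  traj <- run_cohort(epi, "early")
  expect_equal(unname(traj$survival_by_age), rep(1, 11))
  for (age in 2:10) {
    expect_equal(unname(disability_distribution_at(traj, age)), rep(0.25, 4))
  }
})

test_that("stage survival unrolls as the product of stage probabilities", {
  # hand arithmetic: (1 - 0.1) * (1 * 0.5) = 0.45 at discharge,
  # then 0.45 * 0.9 = 0.405 one annual step later
  epi <- toy_epi(p_death_delivery = 0.1, p_admit = 1, p_live_discharge = 0.5,
                 s_d2 = 1, annual = rep(0.9, 8))
  traj <- run_cohort(epi, "early")
  expect_equal(traj$survival_at_discharge, 0.45)
  expect_equal(traj$survival_by_age[["2"]], 0.45)
  expect_equal(traj$survival_by_age[["3"]], 0.405)
  # full unroll to age 10
  expect_equal(traj$survival_by_age[["10"]], 0.45 * 0.9^8)
})

test_that("survival is monotone, conserves mass, and orders strata", {
  epi <- default_epi_params()
  trajs <- lapply(c("early", "moderate", "late"),
                  function(g) run_cohort(epi, g))
  for (tr in trajs) {
    s <- tr$survival_by_age
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0 & s <= 1))
    # survival fraction + cumulative death fraction = 1
    expect_equal(unname(s + (1 - s)), rep(1, 11), tolerance = 1e-12)
    expect_equal(s[["0"]], 1)
  }
  s_mat <- sapply(trajs, function(tr) tr$survival_by_age)
  expect_true(all(s_mat[, 1] <= s_mat[, 2] + 1e-12))
  expect_true(all(s_mat[, 2] <= s_mat[, 3] + 1e-12))
})

test_that("disability propagates by one-step matrix products", {
  # 10%/yr flow none -> mild: after one step (0.5,0.5,0,0) -> (0.45,0.55,0,0)
  P <- diag(4)
  P[1, 1] <- 0.9; P[1, 2] <- 0.1
  epi <- toy_epi(init = c(none = 0.5, mild = 0.5, moderate = 0, severe = 0),
                 transition = P)
  traj <- run_cohort(epi, "late")
  expect_equal(unname(disability_distribution_at(traj, 3)),
               c(0.45, 0.55, 0, 0))
  # every age sums to one
  expect_equal(unname(rowSums(traj$disability_dist_by_age)), rep(1, 9),
               tolerance = 1e-12)
})

test_that("a stationary initial distribution stays stationary", {
  P <- matrix(c(0.8, 0.2, 0, 0,
                0.1, 0.8, 0.1, 0,
                0, 0.2, 0.7, 0.1,
                0, 0, 0.2, 0.8), nrow = 4, byrow = TRUE)
  # stationary distribution of P (left eigenvector)
  e <- eigen(t(P))
  pi0 <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi0 <- pi0 / sum(pi0)
  epi <- toy_epi(init = setNames(pi0, c("none", "mild", "moderate", "severe")),
                 transition = P)
  traj <- run_cohort(epi, "moderate")
  for (age in 2:10) {
    expect_equal(unname(disability_distribution_at(traj, age)), pi0,
                 tolerance = 1e-10)
  }
})

test_that("disability lookup rejects ages outside the modelled range", {
  traj <- run_cohort(default_epi_params(), "late")
  expect_error(disability_distribution_at(traj, 1), "between 2 and 10")
  expect_error(disability_distribution_at(traj, 11), "between 2 and 10")
})

test_that("parameter validation reports each violated invariant by field", {
  expect_equal(nrow(validate_epi_params(default_epi_params())), 0)

  bad <- default_epi_params()
  bad$strata$early$disability_transition[2, ] <- c(0.5, 0.3, 0.05, 0.05)
  rep1 <- validate_epi_params(bad)
  expect_equal(nrow(rep1), 1)
  expect_match(rep1$field, "disability_transition\\[2,\\] \\(mild\\)")
  expect_error(run_cohort(bad, "early"), "mild")

  bad2 <- default_epi_params()
  bad2$strata$late$p_death_delivery <- 1.2
  rep2 <- validate_epi_params(bad2)
  expect_equal(nrow(rep2), 1)
  expect_match(rep2$field, "strata\\$late\\$p_death_delivery")
})

test_that("epidemiology round-trips through the YAML config", {
  epi <- default_epi_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_epi_params(epi, path)
  back <- read_epi_params(path)
  expect_equal(back$strata, epi$strata, tolerance = 1e-12)
})

test_that("trajectory export has one row per stratum and age", {
  epi <- default_epi_params()
  tab <- trajectory_table(lapply(c("early", "moderate", "late"),
                                 function(g) run_cohort(epi, g)))
  expect_equal(nrow(tab), 33)
  expect_true(all(is.na(tab$none[tab$age < 2])))
  expect_equal(tab$survival[tab$age == 0], rep(1, 3))
})
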