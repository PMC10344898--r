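# closed-form normal-equations oracle for the 6-indicator + intercept OLS
oracle_step_ols <- function(obs) {
  X <- cbind(1,
             obs$nt_i == "A", obs$nt_i == "C", obs$nt_i == "T",
             obs$nt_i1 == "A", obs$nt_i1 == "C", obs$nt_i1 == "T") * 1
  beta <- solve(crossprod(X), crossprod(X, obs$delta_ep))
  list(intercept = beta[1], a0 = setNames(beta[2:4], c("A", "C", "T")),
       a1 = setNames(beta[5:7], c("A", "C", "T")))
}

# simulate observations directly from known coefficients
simulate_steps <- function(n, a0, a1, intercept, noise_sd, seed) {
  set.seed(seed)
  nts <- c("A", "C", "G", "T")
  obs <- data.frame(
    locus = paste0("L", rep(seq_len(ceiling(n / 10)), each = 10)[seq_len(n)]),
    i = rep(10:19, length.out = n),
    nt_i = sample(nts, n, replace = TRUE),
    nt_i1 = sample(nts, n, replace = TRUE)
  )
  eff <- function(map, nt) ifelse(nt == "G", 0, map[nt])
  obs$delta_ep <- intercept + eff(a0, obs$nt_i) + eff(a1, obs$nt_i1) +
    rnorm(n, 0, noise_sd)
  obs
}

truth_a0 <- c(A = -1.2, C = 0.8, T = 1.5)
truth_a1 <- c(A = 2.0, C = -0.6, T = 0.9)

test_that("step observation builder indexes templated nucleotides correctly", {
  w <- random_windows(2, seed = 8)
  windows <- setNames(w, c("L1", "L2"))
  ep <- expand.grid(locus = c("L1", "L2"), rttl = 10:20)
  ep$ep <- seq_len(nrow(ep)) * 1.5
  obs <- build_step_observations(ep, windows)
  expect_equal(nrow(obs), 20L)  # 10 adjacent pairs per locus
  o <- obs[obs$locus == "L1" & obs$i == 10L, ]
  expect_equal(o$nt_i, window_base(windows[["L1"]], 10L))
  expect_equal(o$nt_i1, window_base(windows[["L1"]], 11L))
  expect_equal(o$delta_ep,
               ep$ep[ep$locus == "L1" & ep$rttl == 11] -
               ep$ep[ep$locus == "L1" & ep$rttl == 10])
  # non-consecutive grids skip the broken pair with a message
  gap <- ep[!(ep$locus == "L1" & ep$rttl == 15), ]
  expect_message(obs_gap <- build_step_observations(gap, windows), "skipped")
  expect_equal(nrow(obs_gap), 18L)
})

test_that("noiseless data are interpolated exactly and match the oracle", {
  obs <- simulate_steps(300, truth_a0, truth_a1, 0.5, noise_sd = 0, seed = 2)
  fit <- fit_stepwise(obs)
  expect_equal(fit$a0, truth_a0, tolerance = 1e-10)
  expect_equal(fit$a1, truth_a1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.5, tolerance = 1e-10)
  o <- oracle_step_ols(obs)
  expect_equal(unname(fit$a0), unname(o$a0), tolerance = 1e-9)
})

test_that("coefficients recover planted truth within +/-0.15 at n=500, noise 0.5", {
  obs <- simulate_steps(500, truth_a0, truth_a1, 0.3, noise_sd = 0.5, seed = 5)
  fit <- fit_stepwise(obs)
  expect_true(all(abs(fit$a0 - truth_a0) < 0.15))
  expect_true(all(abs(fit$a1 - truth_a1) < 0.15))
  expect_lt(abs(fit$intercept - 0.3), 0.15)
  # exact agreement with the normal-equations oracle
  o <- oracle_step_ols(obs)
  expect_equal(unname(c(fit$intercept, fit$a0, fit$a1)),
               unname(c(o$intercept, o$a0, o$a1)), tolerance = 1e-9)
})

test_that("constant response gives the intercept and zero nucleotide effects", {
  obs <- simulate_steps(400, c(A = 0, C = 0, T = 0), c(A = 0, C = 0, T = 0),
                        3.7, noise_sd = 0, seed = 9)
  fit <- fit_stepwise(obs)
  expect_equal(fit$intercept, 3.7, tolerance = 1e-10)
  expect_true(all(abs(c(fit$a0, fit$a1)) < 1e-10))
})

test_that("fit is invariant to observation order and EP translation", {
  obs <- simulate_steps(200, truth_a0, truth_a1, 0, noise_sd = 1, seed = 11)
  fit1 <- fit_stepwise(obs)
  set.seed(1)
  fit2 <- fit_stepwise(obs[sample.int(nrow(obs)), ])
  expect_equal(fit1$a0, fit2$a0)
  # translation of EP leaves all deltas unchanged by construction: adding a
  # constant to EP at every RTTL changes no delta_ep, hence no coefficient
  w <- random_windows(3, seed = 1)
  windows <- setNames(w, paste0("L", 1:3))
  ep <- expand.grid(locus = paste0("L", 1:3), rttl = 10:20)
  set.seed(3); ep$ep <- runif(nrow(ep), 0, 30)
  f_orig <- fit_stepwise(build_step_observations(ep, windows))
  ep2 <- ep; ep2$ep <- ep2$ep + 12.5
  f_shift <- fit_stepwise(build_step_observations(ep2, windows))
  expect_equal(f_orig$a0, f_shift$a0)
  expect_equal(f_orig$intercept, f_shift$intercept)
})

test_that("rank deficiency names the missing level", {
  obs <- simulate_steps(100, truth_a0, truth_a1, 0, noise_sd = 0, seed = 3)
  obs$nt_i[obs$nt_i == "T"] <- "A"
  expect_error(fit_stepwise(obs), "nt_iT")
})

test_that("aggregated-range fits telescope EP differences and match signs", {
  cfg <- seq_only_config(seed = 23, n_sites = 120, noise_sd = 0.5)
  sites <- generate_sites(cfg)
  windows <- setNames(sites$window, sites$site_id)
  full <- generate_edit_percentages(sites, design_grid(sites, 13L, 10:20), cfg)
  agg <- generate_edit_percentages(sites, design_grid(sites, 13L, c(10L, 12L, 15L, 20L)), cfg)
  ep_full <- data.frame(locus = full$designs$site_id, rttl = full$designs$rttl,
                        ep = full$designs$true_ep)
  ep_agg <- data.frame(locus = agg$designs$site_id, rttl = agg$designs$rttl,
                       ep = agg$designs$true_ep)
  fits <- fit_stepwise_aggregated(ep_agg, windows)
  expect_named(fits, c("10-12", "12-15", "15-20"))
  # range response telescopes: EP(12) - EP(10)
  l1 <- sites$site_id[1]
  resp <- ep_agg$ep[ep_agg$locus == l1 & ep_agg$rttl == 12] -
    ep_agg$ep[ep_agg$locus == l1 & ep_agg$rttl == 10]
  deltas <- diff(ep_full$ep[ep_full$locus == l1][order(ep_full$rttl[ep_full$locus == l1])])
  expect_equal(resp, sum(deltas[1:2]), tolerance = 1e-9)
  # the planted long-band G penalty appears with consistent sign in the
  # 15-20 aggregated fit and the consecutive fit restricted to that range
  obs_full <- build_step_observations(ep_full, windows)
  fit_long <- fit_stepwise(obs_full[obs_full$i >= 15, ])
  f_agg <- fits[["15-20"]]
  for (nt in c("C", "T")) {
    expect_equal(sign(f_agg$a1[[nt]]), sign(fit_long$a1[[nt]]))
  }
  expect_error(fit_stepwise_aggregated(ep_agg[ep_agg$rttl != 15, ], windows),
               "RTTLs 10, 12, 15")
})

test_that("trajectory reconstruction anchors to the observed mean", {
  w <- random_windows(1, seed = 13)
  obs <- simulate_steps(200, truth_a0, truth_a1, 0.4, noise_sd = 0, seed = 7)
  fit <- fit_stepwise(obs)
  traj <- predict_trajectory(fit, w, 10:20, observed_mean = 14)
  expect_equal(mean(traj$predicted_ep), 14)
  # zero-effect fit gives a flat curve at the observed mean
  flat <- fit_stepwise(simulate_steps(200, c(A = 0, C = 0, T = 0),
                                      c(A = 0, C = 0, T = 0), 0, 0, seed = 8))
  traj0 <- predict_trajectory(flat, w, 10:20, observed_mean = 9)
  expect_equal(traj0$predicted_ep, rep(9, 11))
  # a planted G penalty makes every G-entering step decrease
  gpen <- fit_stepwise(simulate_steps(400, c(A = 0, C = 0, T = 0),
                                      c(A = 3, C = 3, T = 3), -1, 0, seed = 10))
  wg <- window_with(`12` = "G", `16` = "G", fill = "C")
  tg <- predict_trajectory(gpen, wg, 10:20, observed_mean = 10)
  steps_in <- window_base(wg, 11:20)
  dd <- diff(tg$predicted_ep)
  expect_true(all(dd[steps_in == "G"] < 0))
})

test_that("locus-grouped cross-validation partitions loci and nails noiseless data", {
  obs <- simulate_steps(400, truth_a0, truth_a1, 1, noise_sd = 0, seed = 15)
  cv <- crossvalidate_stepwise(obs, k = 8, seed = 1)
  expect_lte(cv$mean_rmse, 1e-8)
  obs_n <- simulate_steps(400, truth_a0, truth_a1, 1, noise_sd = 1, seed = 16)
  cv_n <- crossvalidate_stepwise(obs_n, k = 8, seed = 1)
  expect_lt(cv_n$mean_rmse / mean(cv_n$per_fold$train_rmse), 2)
  # leave-one-locus-out equals k = number of loci
  loo <- crossvalidate_stepwise(obs_n, k = length(unique(obs_n$locus)), seed = 1)
  expect_equal(nrow(loo$per_fold), length(unique(obs_n$locus)))
  expect_error(crossvalidate_stepwise(obs_n, k = 1000), "exceed")
})
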