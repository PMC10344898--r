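# surrogate scorer with a known analytic optimum: count of G in the PBS arm
g_count_scorer <- function(pbsl) {
  function(w) sum(window_base(w, -pbsl:-1) == "G")
}

test_that("Tsallis acceptance has the Boltzmann q->1 limit and cools correctly", {
  d <- 0.7; temp <- 0.3
  expect_equal(pegforge:::tsallis_accept(d, temp, 1 + 1e-13),
               exp(-d / temp), tolerance = 1e-9)
  # q = 2 closed form: (1 + d/T)^-1
  expect_equal(pegforge:::tsallis_accept(d, temp, 2), 1 / (1 + d / temp))
  expect_equal(pegforge:::tsallis_accept(-1, temp, 1.5), 1)  # improvements always accepted
  # frozen chain accepts no worsening move
  p_cold <- pegforge:::tsallis_accept(0.5, 1e-12, 1.5)
  expect_lt(p_cold, 1e-6)
})

test_that("SA finds the analytic optimum of the G-counting surrogate, 3/3 seeds", {
  scorer <- g_count_scorer(7L)
  init <- window_with(fill = "A")
  for (seed in 1:3) {
    res <- sa_optimize(scorer, init, sa_config(n_steps = 5000, seed = seed))
    expect_equal(res$best_score, 7)
    expect_true(all(window_base(res$best_window, -7:-1) == "G"))
  }
})

test_that("SA trace best score is non-decreasing and proposals respect the PAM", {
  scorer <- function(w) sum(strsplit(w, "")[[1]] == "C")
  res <- sa_optimize(scorer, window_with(fill = "T"),
                     sa_config(n_steps = 2000, seed = 4))
  expect_true(all(diff(res$trace$best_score) >= 0))
  expect_equal(window_base(res$best_window, 5L), "G")
  expect_equal(window_base(res$best_window, 6L), "G")
})

test_that("MaxEnt with delta = Inf converges to per-position uniform", {
  scorer <- function(w) 0
  anchor <- window_with(fill = "A")
  me <- maxent_sample(scorer, anchor, delta = Inf, n_samples = 50000,
                      burn_in = 2000, thin = 3, seed = 2)
  prof <- kl_profile(me$samples, pseudocount = 0)
  # total variation from uniform at every free position < 0.05
  tv <- apply(as.matrix(prof[, c("pA", "pC", "pG", "pT")]), 1,
              function(p) sum(abs(p - 0.25)) / 2)
  expect_lt(max(tv), 0.05)
  expect_equal(me$acceptance, 1)
})

test_that("MaxEnt hard constraint concentrates the constrained position only", {
  # score depends only on position +1: 1 iff C
  scorer <- function(w) as.numeric(window_base(w, 1L) == "C")
  anchor <- window_with(`1` = "C", fill = "A")
  me <- maxent_sample(scorer, anchor, delta = 0.5, n_samples = 20000,
                      burn_in = 2000, thin = 3, seed = 3)
  prof <- kl_profile(me$samples, pseudocount = 0)
  expect_equal(prof$pC[prof$position == 1], 1)
  others <- prof[prof$position != 1, ]
  tv <- apply(as.matrix(others[, c("pA", "pC", "pG", "pT")]), 1,
              function(p) sum(abs(p - 0.25)) / 2)
  expect_lt(max(tv), 0.08)
})

test_that("MaxEnt aborts on hopeless tolerance and returns anchor-dominated chains", {
  # score equals 0 only at the anchor pattern; any substitution leaves the band
  scorer <- function(w) sum(strsplit(w, "")[[1]] != strsplit(window_with(fill = "A"), "")[[1]])
  anchor <- window_with(fill = "A")
  expect_error(
    maxent_sample(scorer, anchor, delta = 0.5, n_samples = 100,
                  burn_in = 300, seed = 1),
    "acceptance rate"
  )
})

test_that("detailed balance on an enumerable toy space: uniform occupancy", {
  # restrict proposals to the full window but score in-band always; occupancy
  # of each nucleotide at a tracked position should equalize (uniform target)
  scorer <- function(w) 0
  me <- maxent_sample(scorer, window_with(fill = "G"), delta = Inf,
                      n_samples = 40000, burn_in = 2000, thin = 2, seed = 9)
  occ <- table(window_base(me$samples, -3L))
  expect_true(all(abs(occ / sum(occ) - 0.25) < 0.05))
})

test_that("KL profile analytic values and invariances", {
  # exactly uniform frequencies -> 0
  base <- c("A", "C", "G", "T")
  wins <- vapply(1:4, function(i) window_with(`1` = base[i], fill = base[i]),
                 character(1))
  prof_u <- kl_profile(wins, pseudocount = 0)
  expect_equal(prof_u$kl, rep(0, 45), tolerance = 1e-12)
  # point mass -> ln 4
  prof_p <- kl_profile(rep(window_with(fill = "A"), 8), pseudocount = 0)
  expect_equal(prof_p$kl, rep(log(4), 45))
  # half-half -> ln 2
  prof_h <- kl_profile(c(window_with(fill = "A"), window_with(fill = "C")),
                       pseudocount = 0)
  expect_equal(prof_h$kl, rep(log(2), 45))
  # sample order is irrelevant; pseudocount -> 0 recovers the raw estimate
  s <- random_windows(30, seed = 90)
  expect_equal(kl_profile(s), kl_profile(rev(s)))
  expect_equal(kl_profile(s, pseudocount = 1e-12)$kl,
               kl_profile(s, pseudocount = 0)$kl, tolerance = 1e-6)
})

test_that("conditional stratification recovers a planted three-way interaction", {
  set.seed(95)
  wins <- random_windows(4000, seed = 95)
  base_ep <- runif(4000, 5, 15)
  t8 <- window_base(wins, 8L) == "T"
  t9 <- window_base(wins, 9L) == "T"
  g10 <- window_base(wins, 10L) == "G"
  ep <- base_ep + 8 * (t8 & t9 & g10)  # interaction only, no marginal effect
  cond <- conditional_effect(wins, ep, focal_pos = 9L,
                             condition = list(`8` = "T", `10` = "G"))
  marg <- conditional_effect(wins, ep, focal_pos = 9L)
  gap_cond <- cond$mean_ep[cond$nucleotide == "T"] -
    mean(cond$mean_ep[cond$nucleotide != "T"])
  gap_marg <- marg$mean_ep[marg$nucleotide == "T"] -
    mean(marg$mean_ep[marg$nucleotide != "T"])
  expect_gt(gap_cond, 6)
  expect_lt(abs(gap_marg), 1.5)
  # no-condition case reproduces plain stratified means
  expect_equal(marg$mean_ep[marg$nucleotide == "A"],
               mean(ep[window_base(wins, 9L) == "A"]))
  # conditions excluding everything are reported, not dropped
  empty <- conditional_effect(wins[1:5], ep[1:5], focal_pos = 9L,
                              condition = list(`8` = "T", `10` = "G", `12` = "A"))
  expect_equal(nrow(empty), 4L)
  expect_true(all(!empty$ok))
})

test_that("KL saliency of a trained network peaks at a planted dominant position, 3/3 seeds", {
  # one overwhelming planted effect at +3; observed EP carries little noise
  cfg <- synthetic_config(
    seed = 99, n_sites = 400, noise_sd = 1, chromatin_slope = 0,
    gc_pbsl_gamma = 0, baseline = -1.5,
    position_effects = data.frame(pos = 3L, nt = "G", effect = 3),
    last_nt_effects = matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"),
                                                      c("short", "mid", "long")))
  )
  sites <- generate_sites(cfg)
  d <- design_grid(sites, pbsl = c(9L, 13L), rttl = c(10L, 15L))
  ds <- generate_edit_percentages(sites, d, cfg)
  win <- sites$window[match(d$site_id, sites$site_id)]
  X <- build_input_matrix(win, d$pbsl, d$rttl)
  ep <- ds$designs$mean_observed_ep
  for (seed in 1:3) {
    sp <- split_grouped(d$site_id, seed = seed)
    # uniform weights: the EP-bin balancing rule targets skewed real-data
    # distributions and degenerates on this deliberately bimodal world
    tr <- dnn_train(dnn_new(seed = seed), X[sp$train, ], ep[sp$train],
                    X[sp$val, ], ep[sp$val],
                    weights = rep(1, length(sp$train)),
                    max_epochs = 50, seed = seed)
    scorer <- function(w) dnn_predict(
      tr$model, matrix(pegforge:::flatten_input(build_input(w, 13L, 15L)), 1L))
    sa <- sa_optimize(scorer, win[1], sa_config(n_steps = 1500, seed = seed))
    me <- maxent_sample(scorer, sa$best_window,
                        delta = max(0.05 * abs(sa$best_score), 0.5),
                        n_samples = 2000, burn_in = 500, thin = 3, seed = seed)
    prof <- kl_profile(me$samples)
    expect_equal(prof$position[which.max(prof$kl)], 3L)
  }
})
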