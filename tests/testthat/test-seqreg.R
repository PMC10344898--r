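test_that("one-hot encoding geometry and round trip", {
  w <- random_windows(20, seed = 31)
  X <- one_hot_encode(w)
  expect_equal(dim(X), c(20L, 180L))
  expect_true(all(rowSums(X) == 45L))
  for (i in c(1, 7, 20)) expect_equal(one_hot_decode(X[i, ]), w[i])
  # all-A window lights every A indicator
  wa <- window_with(fill = "A")
  Xa <- one_hot_encode(wa)
  expect_equal(unname(Xa[1, seq(1, 180, by = 4)]), rep(1, 45))
  # a single substitution changes exactly 2 entries
  wb <- window_with(`-3` = "T", fill = "A")
  expect_equal(sum(one_hot_encode(wb) != Xa), 2)
  expect_error(one_hot_encode("ACGT"), "47")
})

test_that("lambda = 0 elastic net equals the normal-equations OLS solution", {
  # the complete one-hot encoding is collinear with the intercept (the four
  # indicators of a position sum to 1), so the exact-OLS limit is exercised
  # on the full-rank reduced design with A as reference per position
  set.seed(41)
  n <- 400
  w <- random_windows(n, seed = 41)
  X <- one_hot_encode(w)
  X <- X[, !grepl("\\.A$", colnames(X))]
  ep <- 10 + X %*% rnorm(ncol(X), 0, 0.3) + rnorm(n, 0, 1)
  fit <- fit_elastic(X, drop(ep), lambda = 0)
  Xi <- cbind(1, X)
  beta_oracle <- solve(crossprod(Xi), crossprod(Xi, ep))
  expect_lt(max(abs(c(fit$intercept, fit$beta) - drop(beta_oracle))), 1e-6)
  # interpolation: training predictions equal responses when noiseless
  ep0 <- drop(10 + X %*% rnorm(ncol(X), 0, 0.3))
  fit0 <- fit_elastic(X, ep0, lambda = 0)
  expect_equal(unname(predict(fit0, X)), ep0, tolerance = 1e-8)
})

test_that("huge lambda shrinks everything to the mean", {
  w <- random_windows(100, seed = 43)
  set.seed(43)
  ep <- runif(100, 0, 40)
  fit <- fit_elastic(w, ep, lambda = 1e6)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, mean(ep), tolerance = 1e-6)
})

test_that("elastic net recovers 6 planted position effects at n=2000", {
  cfg <- seq_only_config(seed = 47, n_sites = 2000, noise_sd = 3,
                         gc_pbsl_gamma = 0)
  sites <- generate_sites(cfg)
  d <- design_grid(sites, pbsl = 13L, rttl = 15L)
  ds <- generate_edit_percentages(sites, d, cfg)
  fit <- fit_elastic(sites$window, ds$designs$mean_observed_ep, seed = 2,
                     pbsl = 13L, rttl = 15L)
  planted <- default_position_effects()
  feat <- sprintf("p%+d.%s", planted$pos, planted$nt)
  top10 <- names(sort(abs(fit$beta), decreasing = TRUE))[1:10]
  expect_true(all(feat %in% top10))
  expect_true(all(sign(fit$beta[feat]) == sign(planted$effect)))
})

test_that("held-out prediction quality on generator defaults (gate off)", {
  cfg <- seq_only_config(seed = 53, n_sites = 1200)
  sites <- generate_sites(cfg)
  d <- design_grid(sites, pbsl = 13L, rttl = 15L)
  ds <- generate_edit_percentages(sites, d, cfg)
  train <- 1:1000; test <- 1001:1200
  fit <- fit_elastic(sites$window[train], ds$designs$mean_observed_ep[train], seed = 3)
  r <- cor(predict(fit, sites$window[test]), ds$designs$mean_observed_ep[test])
  expect_gte(r, 0.6)
})

test_that("objective descent and coefficient-path monotonicity", {
  set.seed(59)
  w <- random_windows(300, seed = 59)
  X <- one_hot_encode(w)
  ep <- drop(8 + X %*% rnorm(180, 0, 0.2) + rnorm(300, 0, 2))
  lambdas <- c(0.01, 0.05, 0.2, 1)
  norms <- vapply(lambdas, function(l) {
    # standardize = FALSE so the solver minimizes exactly the stated objective
    fit <- fit_elastic(X, ep, lambda = l, standardize = FALSE)
    obj_hat <- elastic_objective(fit$beta, fit$intercept, X, ep, l, 0.5)
    expect_lte(obj_hat,
               elastic_objective(rep(0, 180), mean(ep), X, ep, l, 0.5) + 1e-8)
    sum(abs(fit$beta))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("constant response falls back to an intercept-only fit", {
  w <- random_windows(50, seed = 61)
  expect_warning(fit <- fit_elastic(w, rep(12, 50)), "constant")
  expect_true(all(fit$beta == 0))
  expect_equal(unname(predict(fit, w)), rep(12, 50))
})

test_that("PBSL grouping rule follows the verbatim definitions", {
  # [-9..-1] = A T | GCGCGCG : group1
  w1 <- window_with(`-9` = "A", `-8` = "T", `-7` = "G", `-6` = "C", `-5` = "G",
                    `-4` = "C", `-3` = "G", `-2` = "C", `-1` = "G")
  expect_equal(as.character(pbsl_group_split(w1)), "group1")
  # five G/C in [-7,-1] -> group2
  w2 <- window_with(`-7` = "G", `-6` = "C", `-5` = "G", `-4` = "C", `-3` = "G",
                    `-2` = "A", `-1` = "A")
  expect_equal(as.character(pbsl_group_split(w2)), "group2")
  # all G/C in [-7,-1] but G at -9 -> neither
  w3 <- window_with(`-9` = "G", `-8` = "T", `-7` = "G", `-6` = "C", `-5` = "G",
                    `-4` = "C", `-3` = "G", `-2` = "C", `-1` = "G")
  expect_equal(as.character(pbsl_group_split(w3)), "neither")
  # six G/C in [-7,-1] -> neither (not group2, not group1)
  w4 <- window_with(`-7` = "G", `-6` = "C", `-5` = "G", `-4` = "C", `-3` = "G",
                    `-2` = "C", `-1` = "A")
  expect_equal(as.character(pbsl_group_split(w4)), "neither")
})

test_that("design recommender applies the flowchart", {
  w1 <- window_with(`-9` = "A", `-8` = "T", `-7` = "G", `-6` = "C", `-5` = "G",
                    `-4` = "C", `-3` = "G", `-2` = "C", `-1` = "G",
                    `4` = "A", `-17` = "G", fill = "T")
  rec1 <- recommend_design(w1)
  expect_equal(rec1$designs$pbsl[1], 7L)
  expect_true(rec1$bonus_agg_pam)
  expect_true(rec1$bonus_g_minus17)
  # group2 site: top PBSL in [11,13]
  w2 <- window_with(fill = "A")
  rec2 <- recommend_design(w2)
  expect_true(rec2$designs$pbsl[1] %in% 11:13)
  # last-nt priority: RTTL 17 (T) outranks RTTL 16 (G)
  w3 <- window_with(`16` = "G", `17` = "T", fill = "A")
  rec3 <- recommend_design(w3, rttl_candidates = c(16L, 17L))
  first_pbsl <- rec3$designs[rec3$designs$pbsl == rec3$designs$pbsl[1], ]
  expect_equal(first_pbsl$rttl[1], 17L)
  # a broken PAM errors
  broken <- paste0(strrep("A", 47))
  expect_error(recommend_design(broken), "PAM")
})

test_that("group1 sites have higher median EP at PBSL 7 than 13 with the GC x PBSL term on", {
  cfg <- seq_only_config(seed = 67, n_sites = 200)
  sites <- generate_sites(cfg)
  # GC-saturated upstream arms are rare in random sequence; plant them so the
  # group carries enough sites for a stable median
  plant <- seq_len(60)
  for (i in plant) {
    ch <- strsplit(sites$window[i], "")[[1]]
    set.seed(1000 + i)
    ch[position_index(-7:-1)] <- sample(c("G", "C"), 7, replace = TRUE)
    ch[position_index(c(-9L, -8L))] <- sample(c("A", "T"), 2, replace = TRUE)
    sites$window[i] <- paste(ch, collapse = "")
  }
  grp <- pbsl_group_split(sites$window)
  expect_true(all(grp[plant] == "group1"))
  d <- design_grid(sites, pbsl = c(7L, 13L), rttl = 15L)
  ds <- generate_edit_percentages(sites, d, cfg)
  dd <- ds$designs
  dd$group <- grp[match(dd$site_id, sites$site_id)]
  med <- function(g, p) median(dd$mean_observed_ep[dd$group == g & dd$pbsl == p])
  expect_gt(med("group1", 7L), med("group1", 13L))
})
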