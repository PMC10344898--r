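#' Build stepwise-difference observations from an EP-by-RTTL table
#'
#' For each locus and each pair of adjacent RT template lengths present in
#' the table, records the stepwise difference in edit percentage
#' `delta_ep = EP(i+1) - EP(i)` together with the last templated nucleotides
#' at the two lengths (the edited-strand bases at nick-relative positions
#' +i and +(i+1)).
#'
#' @param ep_table Data frame with columns `locus`, `rttl`, `ep`; RTTLs in
#'   the 10..20 range are used.
#' @param windows Named character vector of 47-nt windows, names matching
#'   `ep_table$locus`.
#' @return Data frame of observations: `locus`, `i`, `nt_i`, `nt_i1`,
#'   `delta_ep`. Pairs with a missing consecutive RTTL are skipped with a
#'   message.
#' @export
build_step_observations <- function(ep_table, windows) {
  stopifnot(all(c("locus", "rttl", "ep") %in% names(ep_table)))
  missing_win <- setdiff(unique(ep_table$locus), names(windows))
  if (length(missing_win)) stop("no window for locus: ", paste(missing_win, collapse = ", "))
  out <- list()
  skipped <- 0L
  for (locus in unique(ep_table$locus)) {
    sub <- ep_table[ep_table$locus == locus & ep_table$rttl >= 10 & ep_table$rttl <= 20, ]
    sub <- sub[order(sub$rttl), ]
    rt <- sub$rttl
    for (j in seq_len(max(0L, nrow(sub) - 1L))) {
      if (rt[j + 1L] != rt[j] + 1L) { skipped <- skipped + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        locus = locus, i = rt[j],
        nt_i = window_base(windows[[locus]], rt[j]),
        nt_i1 = window_base(windows[[locus]], rt[j] + 1L),
        delta_ep = sub$ep[j + 1L] - sub$ep[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0L) message(skipped, " non-consecutive RTTL pair(s) skipped")
  if (length(out) == 0L) stop("no consecutive RTTL pairs found")
  do.call(rbind, out)
}

nt_factor <- function(x) factor(x, levels = c("G", "A", "C", "T"))

# OLS on the 6 last-templated-nucleotide indicators (G = reference level)
fit_step_lm <- function(df) {
  for (col in c("nt_i", "nt_i1")) {
    absent <- setdiff(c("G", "A", "C", "T"), unique(df[[col]]))
    if (length(absent)) {
      stop("rank-deficient design: level(s) ",
           paste0(col, absent, collapse = ", "), " never observed")
    }
  }
  df$nt_i <- nt_factor(df$nt_i)
  df$nt_i1 <- nt_factor(df$nt_i1)
  fit <- stats::lm(delta_ep ~ nt_i + nt_i1, data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design: level(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         " never observed")
  }
  pick <- function(prefix) stats::setNames(cf[paste0(prefix, c("A", "C", "T"))],
                                           c("A", "C", "T"))
  # summary.lm warns on noiseless (interpolating) fits; those are legitimate here
  fit_summary <- suppressWarnings(summary(fit))
  structure(list(a0 = pick("nt_i"), a1 = pick("nt_i1"),
                 intercept = unname(cf["(Intercept)"]),
                 residual_sd = fit_summary$sigma,
                 r_squared = fit_summary$r.squared,
                 n = nrow(df), lm = fit),
            class = "stepwise_fit")
}

#' Fit the stepwise last-templated-nucleotide regression
#'
#' Ordinary least squares for the model
#' `delta_ep = a0[nt_i] + a1[nt_i1] + a + e`, where `a0`/`a1` are effects of
#' the i-th and (i+1)-th templated nucleotides with G as the implicit
#' reference level for both positions.
#'
#' @param observations Data frame from [build_step_observations()].
#' @return Object of class `stepwise_fit` with coefficient maps `a0`, `a1`
#'   (named A/C/T; G = 0), `intercept` and `residual_sd`.
#' @export
fit_stepwise <- function(observations) {
  stopifnot(all(c("nt_i", "nt_i1", "delta_ep") %in% names(observations)))
  fit_step_lm(observations)
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("stepwise last-templated-nucleotide OLS (G = reference)\n")
  cat("  a0 (i-th nt):  ", paste(sprintf("%s=%+.3f", names(x$a0), x$a0), collapse = " "), "\n")
  cat("  a1 ((i+1)-th): ", paste(sprintf("%s=%+.3f", names(x$a1), x$a1), collapse = " "), "\n")
  cat(sprintf("  intercept %+.3f, residual sd %.3f, n=%d\n",
              x$intercept, x$residual_sd, x$n))
  invisible(x)
}

#' Predicted stepwise difference for given boundary nucleotides
#'
#' @param object A `stepwise_fit`.
#' @param nt_i,nt_i1 Last templated nucleotides at the lower/upper RTTL.
#' @param ... Unused.
#' @return Predicted `delta_ep` in percentage points.
#' @export
predict.stepwise_fit <- function(object, nt_i, nt_i1, ...) {
  eff <- function(map, nt) ifelse(nt == "G", 0, map[nt])
  unname(object$intercept + eff(object$a0, nt_i) + eff(object$a1, nt_i1))
}

#' Aggregated-range stepwise fits for the 10/12/15/20 RTTL grid
#'
#' When edit percentages are only available at RTTLs 10, 12, 15 and 20, the
#' stepwise model is applied to the summed differences over three ranges
#' ([10,12), [12,15), [15,20)): the response for a range is
#' `EP(upper) - EP(lower)` (the telescoped sum of its stepwise differences)
#' and the predictors are the last templated nucleotides at the two
#' boundary RTTLs. One OLS fit is returned per range.
#'
#' @param ep_table Data frame with columns `locus`, `rttl`, `ep` containing
#'   exactly the RTTLs 10, 12, 15, 20 per locus.
#' @param windows Named character vector of 47-nt windows by locus.
#' @return Named list (`"10-12"`, `"12-15"`, `"15-20"`) of `stepwise_fit`s.
#' @export
fit_stepwise_aggregated <- function(ep_table, windows) {
  ranges <- list(c(10L, 12L), c(12L, 15L), c(15L, 20L))
  wide <- stats::reshape(ep_table[c("locus", "rttl", "ep")], idvar = "locus",
                         timevar = "rttl", direction = "wide")
  need <- paste0("ep.", c(10, 12, 15, 20))
  if (!all(need %in% names(wide)) || anyNA(wide[need])) {
    stop("every locus needs edit percentages at RTTLs 10, 12, 15 and 20")
  }
  fits <- lapply(ranges, function(r) {
    df <- data.frame(
      locus = wide$locus,
      nt_i = vapply(wide$locus, function(l) window_base(windows[[l]], r[1]), character(1)),
      nt_i1 = vapply(wide$locus, function(l) window_base(windows[[l]], r[2]), character(1)),
      delta_ep = wide[[paste0("ep.", r[2])]] - wide[[paste0("ep.", r[1])]],
      stringsAsFactors = FALSE
    )
    fit_step_lm(df)
  })
  stats::setNames(fits, vapply(ranges, function(r) paste(r, collapse = "-"), character(1)))
}

#' Reconstruct an EP-vs-RTTL trajectory from stepwise predictions
#'
#' Accumulates the predicted stepwise differences along the RTTL range and
#' anchors the curve so that the mean of the predicted edit percentages
#' equals the supplied observed mean.
#'
#' @param fit A `stepwise_fit`.
#' @param window 47-nt target window supplying the templated nucleotides.
#' @param rttls Integer vector of consecutive RTTLs (default 10:20).
#' @param observed_mean Mean observed edit percentage used as the anchor.
#' @return Data frame with `rttl` and `predicted_ep`.
#' @export
predict_trajectory <- function(fit, window, rttls = 10:20, observed_mean) {
  stopifnot(all(diff(rttls) == 1L))
  nt_i <- window_base(window, utils::head(rttls, -1))
  nt_i1 <- window_base(window, utils::tail(rttls, -1))
  deltas <- predict(fit, nt_i, nt_i1)
  curve <- c(0, cumsum(deltas))
  curve <- curve - mean(curve) + observed_mean
  data.frame(rttl = rttls, predicted_ep = curve)
}

#' Locus-grouped cross-validation of the stepwise model
#'
#' Partitions loci (never individual observations) into `k` folds, fits on
#' the held-in loci and evaluates on the held-out loci.
#'
#' @param observations Data frame from [build_step_observations()].
#' @param k Number of folds; `k =` number of loci gives leave-one-locus-out.
#' @param seed Seed for the fold assignment.
#' @return List with `per_fold` (data frame of fold, n_test, rmse, pearson_r,
#'   train_rmse) and `mean_rmse`, `mean_r` (fold averages).
#' @export
crossvalidate_stepwise <- function(observations, k, seed = 1L) {
  loci <- unique(observations$locus)
  if (k > length(loci)) stop("k cannot exceed the number of loci")
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep(seq_len(k), length.out = length(loci))), loci)
  per_fold <- lapply(seq_len(k), function(f) {
    test <- observations[fold_of[observations$locus] == f, ]
    train <- observations[fold_of[observations$locus] != f, ]
    fit <- fit_step_lm(train)
    pred <- predict(fit, test$nt_i, test$nt_i1)
    pred_train <- predict(fit, train$nt_i, train$nt_i1)
    r <- if (stats::sd(pred) > 0 && stats::sd(test$delta_ep) > 0) {
      stats::cor(pred, test$delta_ep)
    } else NA_real_
    data.frame(fold = f, n_test = nrow(test),
               rmse = sqrt(mean((pred - test$delta_ep)^2)),
               pearson_r = r,
               train_rmse = sqrt(mean((pred_train - train$delta_ep)^2)))
  })
  per_fold <- do.call(rbind, per_fold)
  list(per_fold = per_fold, mean_rmse = mean(per_fold$rmse),
       mean_r = mean(per_fold$pearson_r, na.rm = TRUE))
}
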