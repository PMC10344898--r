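#' Feature names for the one-hot target-window encoding
#'
#' 45 encoded positions (the fixed PAM GG at +5,+6 carries no feature) times
#' 4 nucleotides, position-major with nucleotides ordered A < C < G < T.
#'
#' @return Character vector of 180 feature names, e.g. `"p+1.C"`.
#' @export
one_hot_features <- function() {
  pos <- free_positions()
  as.vector(t(outer(sprintf("p%+d", pos), c("A", "C", "G", "T"), paste, sep = ".")))
}

#' One-hot encode target windows
#'
#' @param windows Character vector of 47-nt edited-strand windows.
#' @return Binary matrix with one row per window and 180 columns named as in
#'   [one_hot_features()]; each row sums to 45.
#' @export
one_hot_encode <- function(windows) {
  pos <- free_positions()
  idx <- position_index(pos)
  nts <- c("A", "C", "G", "T")
  for (w in windows) assert_window(w)
  chars <- t(vapply(windows, function(w)
    strsplit(w, "")[[1]][idx], character(length(idx))))
  X <- matrix(0L, nrow = length(windows), ncol = 4L * length(idx),
              dimnames = list(NULL, one_hot_features()))
  for (k in seq_along(nts)) {
    cols <- seq(k, by = 4L, length.out = length(idx))
    X[, cols] <- (chars == nts[k]) * 1L
  }
  X
}

#' Decode a one-hot vector back to a 47-nt window
#'
#' @param x A 180-length one-hot vector (one 1 per encoded position).
#' @return The 47-nt window string, with the fixed GG restored at +5,+6.
#' @export
one_hot_decode <- function(x) {
  nts <- c("A", "C", "G", "T")
  m <- matrix(x, nrow = 4L)
  if (!all(colSums(m) == 1L)) stop("not a valid one-hot encoding")
  bases <- nts[apply(m, 2, which.max)]
  out <- character(47L)
  out[position_index(free_positions())] <- bases
  out[position_index(c(5L, 6L))] <- "G"
  paste(out, collapse = "")
}

#' Fit a per-design-cell elastic net on one-hot sequence features
#'
#' Penalized linear regression of edit percentage on the 180 one-hot
#' indicators, minimizing
#' `(1/(2n)) * ||EP - I b||^2 + lambda * (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)`
#' (the residual term is per-observation-normalized so that `lambda` is
#' sample-size-stable; multiply `lambda` by `2n` to recover the unscaled
#' objective). When `lambda` is `NULL` it is tuned by 10-fold
#' cross-validation to minimize mean validation MSE. `lambda = 0` is the
#' exact least-squares limit and is computed directly by OLS.
#'
#' @param windows Character vector of 47-nt windows, or a pre-encoded
#'   one-hot matrix.
#' @param ep Numeric edit percentages.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param lambda `NULL` for CV tuning, or a single penalty value.
#' @param nfolds CV folds (default 10).
#' @param standardize Standardize features inside the solver (coefficients
#'   are always reported back on the indicator scale).
#' @param seed Seed for the CV fold assignment.
#' @param pbsl,rttl Optional design-cell metadata stored on the fit.
#' @return Object of class `elastic_fit` with `beta` (named 180-vector),
#'   `intercept`, `lambda`, `alpha` and optional `cv` results.
#' @export
fit_elastic <- function(windows, ep, alpha = 0.5, lambda = NULL, nfolds = 10L,
                        standardize = TRUE, seed = 1L,
                        pbsl = NA_integer_, rttl = NA_integer_) {
  X <- if (is.matrix(windows)) windows else one_hot_encode(windows)
  stopifnot(nrow(X) == length(ep))
  cv <- NULL
  if (stats::var(ep) == 0) {
    warning("constant response: returning an intercept-only fit")
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    intercept <- ep[1]
    lambda <- lambda %||% Inf
  } else if (!is.null(lambda) && lambda == 0) {
    # exact OLS limit; iterative shrinkage solvers are only approximate here
    fit <- stats::lm.fit(cbind(1, X), ep)
    cf <- fit$coefficients
    if (anyNA(cf)) stop("lambda = 0 requires a full-rank design")
    intercept <- unname(cf[1])
    beta <- stats::setNames(cf[-1], colnames(X))
  } else {
    if (is.null(lambda)) {
      set.seed(seed)
      cv <- glmnet::cv.glmnet(X, ep, alpha = alpha, nfolds = nfolds,
                              standardize = standardize)
      lambda <- cv$lambda.min
      g <- cv$glmnet.fit
    } else {
      g <- glmnet::glmnet(X, ep, alpha = alpha, standardize = standardize,
                          lambda = sort(unique(c(lambda * c(64, 16, 4, 2), lambda)),
                                        decreasing = TRUE))
    }
    cf <- stats::coef(g, s = lambda)
    intercept <- cf[1, 1]
    beta <- stats::setNames(cf[-1, 1], colnames(X))
  }
  structure(list(beta = beta, intercept = intercept, lambda = lambda,
                 alpha = alpha, cv = cv, pbsl = pbsl, rttl = rttl,
                 n = nrow(X)),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf("elastic net fit (alpha=%.2f, lambda=%.4g, n=%d%s)\n",
              x$alpha, x$lambda, x$n,
              if (!is.na(x$pbsl)) sprintf(", PBSL=%d, RTTL=%d", x$pbsl, x$rttl) else ""))
  nz <- sum(x$beta != 0)
  cat(sprintf("  %d/%d nonzero coefficients; intercept %.3f\n",
              nz, length(x$beta), x$intercept))
  top <- utils::head(sort(abs(x$beta), decreasing = TRUE), 5)
  cat("  top |beta|:", paste(sprintf("%s=%+.3f", names(top), x$beta[names(top)]),
                             collapse = " "), "\n")
  invisible(x)
}

#' Predict edit percentages from an elastic-net fit
#'
#' @param object An `elastic_fit`.
#' @param windows Windows or pre-encoded one-hot matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted edit percentages.
#' @export
predict.elastic_fit <- function(object, windows, ...) {
  X <- if (is.matrix(windows)) windows else one_hot_encode(windows)
  if (ncol(X) != length(object$beta)) stop("encoding does not match the fitted model")
  drop(X %*% object$beta) + object$intercept
}

#' Elastic-net objective value (per-observation-normalized form)
#'
#' @param beta Coefficient vector.
#' @param intercept Intercept.
#' @param X One-hot matrix.
#' @param ep Responses.
#' @param lambda,alpha Penalty parameters.
#' @return Objective value.
#' @export
elastic_objective <- function(beta, intercept, X, ep, lambda, alpha) {
  r <- ep - drop(X %*% beta) - intercept
  sum(r^2) / (2 * length(ep)) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

#' Split target sites by the GC composition upstream of the nick
#'
#' Group 1: only G or C at nick-relative [-7,-1] and only A or T at -9 and
#' -8. Group 2: fewer than six G/C nucleotides in [-7,-1]. Sites satisfying
#' neither definition are labelled `neither`.
#'
#' @param windows Character vector of 47-nt windows.
#' @return Factor with levels `group1`, `group2`, `neither`.
#' @export
pbsl_group_split <- function(windows) {
  lab <- vapply(windows, function(w) {
    assert_window(w)
    up7 <- window_base(w, -7:-1)
    up98 <- window_base(w, c(-9L, -8L))
    gc7 <- sum(up7 %in% c("G", "C"))
    if (gc7 == 7L && all(up98 %in% c("A", "T"))) "group1"
    else if (gc7 < 6L) "group2"
    else "neither"
  }, character(1), USE.NAMES = FALSE)
  factor(lab, levels = c("group1", "group2", "neither"))
}

#' Recommend pegRNA designs for a target site
#'
#' Applies the design flowchart distilled from the sequence models:
#' PBSL = 7 when the upstream sequence is GC-saturated (group 1 of
#' [pbsl_group_split()]), otherwise PBSL in [11,13] (13 first); RT template
#' lengths ranked by the last-templated-nucleotide priority T ~ C > A > G,
#' with G tolerated for short templates (RTTL <= 12) but avoided for longer
#' ones, and shorter templates preferred at equal priority. AGG PAM and G at
#' -17 are reported as site-level bonuses.
#'
#' @param window 47-nt edited-strand window (must carry the GG PAM).
#' @param rttl_candidates Candidate RT template lengths (default 10:20).
#' @param pbsl_candidates Candidate PBS lengths (default the assay grid).
#' @return List with `designs` (ranked data frame of `pbsl`, `rttl`,
#'   `last_nt`, `rationale`), `group`, and logical `bonus_agg_pam`,
#'   `bonus_g_minus17`.
#' @export
recommend_design <- function(window, rttl_candidates = 10:20,
                             pbsl_candidates = c(7L, 9L, 11L, 13L, 15L, 17L)) {
  if (nchar(window) != 47L || grepl("[^ACGT]", window) ||
      window_base(window, 5L) != "G" || window_base(window, 6L) != "G") {
    stop("no NGG PAM at nick-relative +4..+6 in the supplied window")
  }
  group <- as.character(pbsl_group_split(window))
  pbsl_order <- if (group == "group1") {
    c(7L, setdiff(pbsl_candidates, 7L))
  } else {
    c(intersect(c(13L, 12L, 11L), pbsl_candidates),
      setdiff(pbsl_candidates, 11:13))
  }
  pbsl_order <- intersect(pbsl_order, pbsl_candidates)
  last_nt <- window_base(window, rttl_candidates)
  priority <- ifelse(last_nt %in% c("T", "C"), 3,
                     ifelse(last_nt == "A", 2,
                            ifelse(rttl_candidates <= 12L, 2.5, 1)))
  rt_rank <- order(-priority, rttl_candidates)
  grid <- expand.grid(rttl_idx = rt_rank, pbsl = pbsl_order,
                      KEEP.OUT.ATTRS = FALSE)
  designs <- data.frame(
    pbsl = grid$pbsl,
    rttl = rttl_candidates[grid$rttl_idx],
    last_nt = last_nt[grid$rttl_idx],
    stringsAsFactors = FALSE
  )
  designs$rationale <- paste0(
    ifelse(designs$pbsl == pbsl_order[1], "preferred PBSL for ", "alternative PBSL for "),
    group, "; last templated nt ", designs$last_nt,
    ifelse(designs$last_nt == "G" & designs$rttl > 12L,
           " (G avoided for RTTL > 12)", "")
  )
  rownames(designs) <- NULL  # expand.grid already yields PBSL-major ranked order
  list(designs = designs,
       group = group,
       bonus_agg_pam = window_base(window, 4L) == "A",
       bonus_g_minus17 = window_base(window, -17L) == "G")
}
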