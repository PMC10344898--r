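#' Construct a binned signal track
#'
#' @param values Non-negative numeric vector, one value per genomic bin (or
#'   per base when `bin_size = 1`).
#' @param bin_size Bin width in bases (1,000 for ChIP-style tracks; 1 for
#'   per-base MNase signal).
#' @param label Sample role, `"IP"` or `"input"` (or `"signal"` for
#'   unpaired tracks such as MNase).
#' @param sample Sample name.
#' @param chrom Chromosome name.
#' @return Object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size = 1000L, label = "signal",
                         sample = label, chrom = "chrS") {
  stopifnot(is.numeric(values), all(values >= 0), bin_size >= 1L)
  structure(list(values = as.numeric(values), bin_size = as.integer(bin_size),
                 label = label, sample = sample, chrom = chrom),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track '%s' (%s): %d bins of %d bp on %s\n",
              x$sample, x$label, length(x$values), x$bin_size, x$chrom))
  invisible(x)
}

# l1 normalization: each track becomes a read-density vector summing to 1
l1_normalize <- function(v) {
  s <- sum(v)
  if (s <= 0) stop("cannot l1-normalize an all-zero track")
  v / s
}

#' Consensus enrichment regions from IP and input tracks by SVD
#'
#' Stacks the l1-normalized tracks as the rows of a samples-by-bins matrix
#' and computes its singular value decomposition. The right-singular vector
#' whose left-singular sample loadings best separate the IP from the input
#' group (largest gap between group means) is taken as the consensus
#' IP-vs-input contrast, oriented so that the IP group loads positively.
#' Bins whose component on that vector exceeds the `quantile` threshold are
#' flagged and merged into intervals.
#'
#' @param tracks List of [signal_track()] objects with labels `IP`/`input`;
#'   at least 2 IP and 1 input tracks, identical bin grids.
#' @param quantile Bin-component quantile above which bins are flagged
#'   (default 0.995).
#' @return A [GenomicRanges::GRanges] of consensus intervals (1-based,
#'   closed; written as 0-based half-open when exported to BED). Metadata
#'   columns record the selected component and per-interval mean component.
#' @export
consensus_enrichment <- function(tracks, quantile = 0.995) {
  labels <- vapply(tracks, function(t) t$label, character(1))
  if (sum(labels == "IP") < 2L || sum(labels == "input") < 1L) {
    stop("need at least 2 IP and 1 input track")
  }
  n_bins <- unique(vapply(tracks, function(t) length(t$values), integer(1)))
  bin_size <- unique(vapply(tracks, function(t) t$bin_size, integer(1)))
  chrom <- unique(vapply(tracks, function(t) t$chrom, character(1)))
  if (length(n_bins) != 1L || length(bin_size) != 1L || length(chrom) != 1L) {
    stop("all tracks must share the same bin grid and chromosome")
  }
  M <- do.call(rbind, lapply(tracks, function(t) l1_normalize(t$values)))
  sv <- svd(M)
  ip <- labels == "IP"
  gaps <- apply(sv$u, 2, function(u) mean(u[ip]) - mean(u[!ip]))
  k <- which.max(abs(gaps))
  v <- sv$v[, k] * sign(gaps[k])
  thr <- stats::quantile(v, quantile)
  flagged <- which(v > thr)
  if (length(flagged) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    runs <- split(flagged, cumsum(c(1L, diff(flagged) != 1L)))
    start_bin <- vapply(runs, min, integer(1))
    end_bin <- vapply(runs, max, integer(1))
    gr <- GenomicRanges::GRanges(
      seqnames = rep(chrom, length(runs)),
      ranges = IRanges::IRanges(start = (start_bin - 1L) * bin_size + 1L,
                                end = end_bin * bin_size)
    )
    gr$mean_component <- vapply(runs, function(r) mean(v[r]), numeric(1))
  }
  S4Vectors::metadata(gr) <- list(component = k, bin_values = v,
                                  quantile = quantile, bin_size = bin_size)
  gr
}

#' Base-level Jaccard index between two interval sets
#'
#' @param a,b [GenomicRanges::GRanges] objects.
#' @return Intersection bases / union bases (1 when both are empty).
#' @export
interval_jaccard <- function(a, b) {
  a <- GenomicRanges::reduce(a)
  b <- GenomicRanges::reduce(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  inter <- sum(IRanges::width(GenomicRanges::intersect(a, b)))
  uni <- sum(IRanges::width(GenomicRanges::union(a, b)))
  inter / uni
}

# genomic span of the protospacer (nick-relative -17..+3) of a site row
protospacer_range <- function(site) {
  GenomicRanges::GRanges(site$chrom,
                         IRanges::IRanges(start = site$nick_pos - 17L,
                                          end = site$nick_pos + 2L))
}

#' Distance from target sites to the nearest peak
#'
#' Zero when the protospacer overlaps a peak, otherwise the gap to the
#' closest interval end, in kb. Distances are floored at `floor_kb` before
#' the log10 transform so that overlapping sites remain finite.
#'
#' @param sites Site table (columns `chrom`, `nick_pos`).
#' @param peaks [GenomicRanges::GRanges] of peak intervals.
#' @param floor_kb Floor applied before `log10` (default 0.1 kb).
#' @return Data frame with `dist_kb` (`Inf` when no peak shares the
#'   chromosome) and `log10_kb`.
#' @export
distance_to_nearest_peak <- function(sites, peaks, floor_kb = 0.1) {
  proto <- protospacer_range(sites)
  d <- rep(Inf, length(proto))
  if (length(peaks) > 0L) {
    hit <- GenomicRanges::distanceToNearest(proto, peaks, ignore.strand = TRUE)
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  }
  dist_kb <- d / 1000
  data.frame(dist_kb = dist_kb,
             log10_kb = log10(pmax(dist_kb, floor_kb)))
}

# ridge-penalized logistic log-likelihood fit, used when glm separates
penalized_logistic <- function(X, y, ridge = 1e-2) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(log1p(exp(-(2 * y - 1) * eta))) + ridge * sum(beta[-1]^2) / 2
  }
  gr <- function(beta) {
    eta <- drop(X %*% beta)
    p <- logistic(eta)
    g <- drop(crossprod(X, p - y))
    g + ridge * c(0, beta[-1])
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS", hessian = TRUE)
  se <- sqrt(diag(solve(fit$hessian)))
  list(coef = fit$par, se = se)
}

#' Fit the logistic editability classifier
#'
#' Regresses the binary editability label (edit percentage above 1%) on the
#' log10 distance to the nearest heterochromatin region, optionally with
#' further distance covariates. The decision threshold is the probability
#' cutoff maximizing the finite positive likelihood ratio TPR/FPR over all
#' observed-score cutoffs with FPR > 0 (ties broken by larger TPR), and is
#' converted to a distance threshold by inverting the univariate logit.
#'
#' @param log10_dist Numeric vector, log10 distance (kb) per site.
#' @param editable Logical (or 0/1) editability labels; both classes must
#'   be present.
#' @param extra Optional numeric matrix of additional covariates (e.g., the
#'   log10 distance to H3K27me3 regions).
#' @param drop_insignificant Drop `extra` covariates whose Wald p-value is
#'   >= 0.05 and refit (default TRUE, mirroring the univariate fallback).
#' @return Object of class `editability_model` with `coefficients`, `se`,
#'   `z`, `p_value`, `prob_threshold`, `distance_threshold_kb` and a
#'   `separation` flag (TRUE when the penalized fallback fit was used).
#' @export
fit_editability <- function(log10_dist, editable, extra = NULL,
                            drop_insignificant = TRUE) {
  y <- as.integer(editable)
  if (length(unique(y)) < 2L) stop("both editable and non-editable sites are required")
  df <- data.frame(y = y, log10_dist = log10_dist)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    colnames(extra) <- colnames(extra) %||% paste0("extra", seq_len(ncol(extra)))
    df <- cbind(df, extra)
  }
  fit_once <- function(df) {
    X <- cbind(`(Intercept)` = 1, as.matrix(df[setdiff(names(df), "y")]))
    separated <- FALSE
    g <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          separated <<- TRUE
        }
        invokeRestart("muffleWarning")
      }
    )
    if (separated || any(abs(stats::coef(g)) > 50)) {
      pen <- penalized_logistic(X, df$y)
      list(coef = stats::setNames(pen$coef, colnames(X)), se = pen$se,
           prob = logistic(drop(X %*% pen$coef)), separation = TRUE)
    } else {
      sm <- summary(g)
      list(coef = stats::coef(g), se = sm$coefficients[, "Std. Error"],
           prob = stats::fitted(g), separation = FALSE)
    }
  }
  f <- fit_once(df)
  z <- f$coef / f$se
  p_value <- 2 * stats::pnorm(-abs(z))
  if (drop_insignificant && !is.null(extra)) {
    drop <- intersect(names(p_value)[p_value >= 0.05], colnames(extra))
    if (length(drop)) {
      df <- df[setdiff(names(df), drop)]
      f <- fit_once(df)
      z <- f$coef / f$se
      p_value <- 2 * stats::pnorm(-abs(z))
    }
  }
  # finite positive likelihood-ratio threshold over observed scores
  cand <- sort(unique(f$prob))
  stats_at <- function(t) {
    pred <- f$prob >= t
    c(tpr = sum(pred & y == 1L) / sum(y == 1L),
      fpr = sum(pred & y == 0L) / sum(y == 0L))
  }
  sweep <- t(vapply(cand, stats_at, numeric(2)))
  ok <- sweep[, "fpr"] > 0
  if (!any(ok)) stop("no threshold with positive FPR; degenerate score distribution")
  lr <- sweep[ok, "tpr"] / sweep[ok, "fpr"]
  best <- which(lr == max(lr))
  if (length(best) > 1L) best <- best[which.max(sweep[ok, "tpr"][best])]
  prob_threshold <- cand[ok][best]
  # invert the univariate logit for the distance threshold
  if (length(f$coef) == 2L) {
    b <- f$coef
  } else {
    b <- fit_once(df[c("y", "log10_dist")])$coef
  }
  log10_thr <- (stats::qlogis(prob_threshold) - b[1]) / b[2]
  structure(list(coefficients = f$coef, se = f$se, z = z, p_value = p_value,
                 prob_threshold = unname(prob_threshold),
                 distance_threshold_kb = unname(10^log10_thr),
                 separation = f$separation,
                 lr_sweep = cbind(threshold = cand, sweep)),
            class = "editability_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.editability_model <- function(x, ...) {
  cat("logistic editability classifier\n")
  print(round(cbind(coef = x$coefficients, se = x$se, z = x$z, p = x$p_value), 4))
  cat(sprintf("probability threshold %.4f -> distance threshold %.2f kb%s\n",
              x$prob_threshold, x$distance_threshold_kb,
              if (x$separation) " (penalized fit: separation detected)" else ""))
  invisible(x)
}

#' Predicted editability probability
#'
#' @param object An `editability_model`.
#' @param log10_dist log10 distances (kb).
#' @param extra Optional covariate matrix matching the fitted model.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.editability_model <- function(object, log10_dist, extra = NULL, ...) {
  X <- cbind(1, log10_dist)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  if (ncol(X) != length(object$coefficients)) {
    stop("covariates do not match the fitted model")
  }
  logistic(drop(X %*% object$coefficients))
}

#' ROC curve, AUROC, confusion matrix and accuracy of a classifier
#'
#' @param scores Numeric classification scores (higher = more editable).
#' @param labels Logical/0-1 true labels; both classes must be present.
#' @param threshold Score threshold for the confusion matrix (predict
#'   positive when `scores >= threshold`); defaults to 0.5.
#' @return List with `roc` (data frame of FPR/TPR points over the full
#'   threshold sweep), `auroc` (trapezoidal rule), `confusion` (2x2 matrix)
#'   and `accuracy`.
#' @export
evaluate_classifier <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("AUROC undefined: test set contains a single class")
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(y[ord] == 1L) / sum(y == 1L))
  fpr <- c(0, cumsum(y[ord] == 0L) / sum(y == 0L))
  keep <- !duplicated(fpr, fromLast = TRUE)  # step curve vertices
  roc <- data.frame(fpr = fpr[keep], tpr = tpr[keep])
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  pred <- factor(scores >= threshold, levels = c(FALSE, TRUE),
                 labels = c("pred_neg", "pred_pos"))
  truth <- factor(y == 1L, levels = c(FALSE, TRUE), labels = c("neg", "pos"))
  confusion <- table(truth, pred)
  list(roc = roc, auroc = auroc, confusion = confusion,
       accuracy = sum(diag(confusion)) / sum(confusion))
}

#' Mean nucleosome occupancy over a protospacer
#'
#' Sums the per-base MNase signal over every coordinate of the protospacer
#' interval and normalizes by its length.
#'
#' @param track A per-base [signal_track()] (`bin_size = 1`) or numeric
#'   vector of per-base signal.
#' @param interval Integer vector `c(start, end)`, 1-based inclusive
#'   coordinates covered by the track.
#' @return Mean signal over the interval.
#' @export
mnase_protospacer_mean <- function(track, interval) {
  values <- if (inherits(track, "signal_track")) {
    if (track$bin_size != 1L) stop("MNase summary requires a per-base track (bin_size = 1)")
    track$values
  } else {
    as.numeric(track)
  }
  start <- interval[1]; end <- interval[2]
  if (start < 1L || end > length(values) || start > end) {
    stop("protospacer interval not covered by the track")
  }
  mean(values[start:end])
}
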