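#' Build the 47x5 network input for one pegRNA design
#'
#' Columns 1-4 one-hot encode the edited-strand nucleotide at nick-relative
#' positions -21..+26; column 5 marks coverage of each position by the union
#' of the design's PBS (-PBSL..-1) and RT template (+1..+RTTL) regions, so
#' that designs of different lengths targeting the same site are
#' distinguishable.
#'
#' @param window 47-nt edited-strand window.
#' @param pbsl PBS length (1..21).
#' @param rttl RT template length (1..26).
#' @return 47 x 5 numeric matrix (rows in window order, columns A,C,G,T,cov).
#' @export
build_input <- function(window, pbsl, rttl) {
  assert_window(window)
  if (pbsl > 21L) stop("PBSL cannot exceed 21")
  if (rttl > 26L) stop("RTTL cannot exceed 26")
  chars <- strsplit(window, "")[[1]]
  m <- matrix(0, 47L, 5L, dimnames = list(NULL, c("A", "C", "G", "T", "cov")))
  for (k in 1:4) m[, k] <- (chars == c("A", "C", "G", "T")[k]) * 1
  pos <- window_positions()
  m[, 5L] <- ((pos >= -pbsl & pos <= -1L) | (pos >= 1L & pos <= rttl)) * 1
  m
}

# flatten to the network's input layout: position-major, 5 channels per position
flatten_input <- function(m) as.vector(t(m))

#' Encode a design table into the network input matrix
#'
#' @param windows Character vector of 47-nt windows (one per design).
#' @param pbsl,rttl Integer vectors of design lengths.
#' @return Numeric matrix, designs x 235.
#' @export
build_input_matrix <- function(windows, pbsl, rttl) {
  stopifnot(length(windows) == length(pbsl), length(pbsl) == length(rttl))
  t(mapply(function(w, p, r) flatten_input(build_input(w, p, r)),
           windows, pbsl, rttl, USE.NAMES = FALSE))
}

#' Training weights balancing the edit-percentage distribution
#'
#' Designs with EP >= 30% get weight 1; below that, designs are partitioned
#' into 1%-wide EP bins and weighted by `N_30 / N_bin`, where `N_30` is the
#' count in the [30,31) bin, down-weighting over-represented poorly edited
#' designs.
#'
#' @param ep Edit percentages in `[0, 100]`.
#' @return Numeric weight vector.
#' @export
compute_weights <- function(ep) {
  stopifnot(all(ep >= 0 & ep <= 100))
  bin <- floor(ep)
  n30 <- sum(bin == 30L)
  if (n30 == 0L && any(ep < 30)) {
    warning("empty [30,31) bin: falling back to N_30 = 1")
    n30 <- 1L
  }
  counts <- table(bin)
  w <- ifelse(ep >= 30, 1, n30 / as.numeric(counts[as.character(bin)]))
  unname(w)
}

#' Site-grouped train/validation/test split
#'
#' All designs sharing a target site land in the same split: 80% of sites in
#' training, 10% in validation, 10% in test.
#'
#' @param site_ids Character vector, one site id per design.
#' @param seed Seed for the site shuffle.
#' @param props Split proportions (train, val, test).
#' @return List with `train`, `val`, `test`: integer design indices; and
#'   `sites`: the per-split site ids.
#' @export
split_grouped <- function(site_ids, seed = 1L, props = c(0.8, 0.1, 0.1)) {
  sites <- unique(site_ids)
  if (length(sites) < 10L) stop("at least 10 distinct sites are required")
  set.seed(seed)
  sites <- sample(sites)
  n <- length(sites)
  n_val <- floor(props[2] * n)
  n_test <- floor(props[3] * n)
  s_val <- sites[seq_len(n_val)]
  s_test <- sites[n_val + seq_len(n_test)]
  s_train <- sites[-seq_len(n_val + n_test)]
  list(train = which(site_ids %in% s_train),
       val = which(site_ids %in% s_val),
       test = which(site_ids %in% s_test),
       sites = list(train = s_train, val = s_val, test = s_test))
}

# block-sparsity mask realising 40 position blocks x 10 independent filters
# of kernel 8x5: filter f of block b connects only to the 40 inputs of
# positions b..b+7 and to output unit (b-1)*10 + f
dnn_mask <- function() {
  mask <- matrix(0, 235L, 400L)
  for (b in 1:40) {
    rows <- (5L * (b - 1L) + 1L):(5L * (b + 7L))
    cols <- (10L * (b - 1L) + 1L):(10L * b)
    mask[rows, cols] <- 1
  }
  mask
}

#' Initialize the position-specific-filter network
#'
#' Architecture: 40 overlapping 8-mer blocks x 10 independent filters of
#' kernel 8x5 (no weight sharing across positions), a fully connected layer
#' of 10 units, and a single output unit; ReLU activations throughout, with
#' 20% dropout applied after the input and after the filter layer during
#' training. The output is trained against `log(EP + 1)`.
#'
#' @param seed Seed for the weight initialization.
#' @param dropout Dropout rate applied after the input and filter layers
#'   during training (0.2 as stated; 0 disables regularization noise, useful
#'   for optimization sanity checks).
#' @return Object of class `dnn_model`.
#' @export
dnn_new <- function(seed = 1L, dropout = 0.2) {
  set.seed(seed)
  mask <- dnn_mask()
  # Glorot uniform, with the filter layer's true fan-in of 40 inputs per unit
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  model <- list(
    W1 = glorot(235L, 400L, 40L, 10L) * mask, b1 = rep(0, 400L),
    W2 = glorot(400L, 10L, 400L, 10L), b2 = rep(0, 10L),
    W3 = glorot(10L, 1L, 10L, 1L), b3 = 1,
    mask = mask, dropout = dropout
  )
  class(model) <- "dnn_model"
  model
}

#' Parameter count of the network
#'
#' @param model A `dnn_model`.
#' @return Named vector of parameter counts per layer and their total
#'   (40*10*(8*5+1) filter parameters plus the dense layers).
#' @export
dnn_param_count <- function(model) {
  filt <- sum(model$mask) + length(model$b1)
  dense <- length(model$W2) + length(model$b2)
  out <- length(model$W3) + length(model$b3)
  c(filters = filt, dense = dense, output = out, total = filt + dense + out)
}

relu <- function(x) x * (x > 0)

# forward pass; when training, applies inverted dropout after input and
# after the filter layer and returns the cached intermediates for backprop
dnn_forward <- function(model, X, training = FALSE) {
  keep <- 1 - model$dropout
  if (training) {
    D0 <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X)) / keep
    X <- X * D0
  }
  Z1 <- X %*% model$W1 + rep(model$b1, each = nrow(X))
  A1 <- relu(Z1)
  A1d <- A1
  if (training) {
    D1 <- matrix(stats::runif(length(A1)) < keep, nrow(A1), ncol(A1)) / keep
    A1d <- A1 * D1
  }
  Z2 <- A1d %*% model$W2 + rep(model$b2, each = nrow(X))
  A2 <- relu(Z2)
  Z3 <- A2 %*% model$W3 + model$b3
  Y <- relu(Z3)
  out <- list(Y = Y, Z3 = Z3, A2 = A2, Z2 = Z2, A1d = A1d, Z1 = Z1, X = X)
  if (training) out$D1 <- D1
  out
}

# weighted MSE on the log scale, normalized by the summed batch weights so
# the optimization is invariant to uniform rescaling of the weights
dnn_loss <- function(y_hat, target, w) sum(w * (y_hat - target)^2) / sum(w)

dnn_gradients <- function(model, fw, target, w) {
  n <- length(target)
  dY <- matrix(2 * w * (fw$Y - target) / sum(w), n, 1L)
  dZ3 <- dY * (fw$Z3 > 0)
  dA2 <- dZ3 %*% t(model$W3)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dA1d <- dZ2 %*% t(model$W2)
  dA1 <- if (is.null(fw$D1)) dA1d else dA1d * fw$D1
  dZ1 <- dA1 * (fw$Z1 > 0)
  list(
    W1 = crossprod(fw$X, dZ1) * model$mask, b1 = colSums(dZ1),
    W2 = crossprod(fw$A1d, dZ2), b2 = colSums(dZ2),
    W3 = crossprod(fw$A2, dZ3), b3 = sum(dZ3)
  )
}

#' Train the network with weighted log-scale loss and early stopping
#'
#' Minimizes the weighted mean-squared error between the network output and
#' `log(EP + 1)` using stochastic gradient descent with Nesterov momentum
#' 0.9, initial learning rate 1e-3 and per-update decay 1e-6
#' (`lr_t = lr / (1 + decay * t)`). Training stops when the validation loss
#' has not improved for `patience` consecutive epochs (or at `max_epochs`),
#' and the epoch-best model is returned.
#'
#' @param model A `dnn_model` from [dnn_new()].
#' @param X_train,ep_train Training inputs (designs x 235) and edit
#'   percentages.
#' @param X_val,ep_val Validation inputs and edit percentages.
#' @param weights Training weights (default [compute_weights()] of
#'   `ep_train`).
#' @param batch_size Minibatch size.
#' @param lr,momentum,decay Optimizer hyperparameters.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Epoch budget cap.
#' @param seed Seed for batch shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return List with `model` (epoch-best weights), `history` (data frame of
#'   train/val loss per epoch) and `best_epoch`.
#' @export
dnn_train <- function(model, X_train, ep_train, X_val, ep_val,
                      weights = compute_weights(ep_train),
                      batch_size = 32L, lr = 1e-3, momentum = 0.9,
                      decay = 1e-6, patience = 10L, max_epochs = 200L,
                      seed = 1L, verbose = FALSE) {
  stopifnot(nrow(X_train) == length(ep_train), nrow(X_val) == length(ep_val))
  t_train <- log(ep_train + 1)
  t_val <- log(ep_val + 1)
  # the monitored quantity is the weighted validation loss, with weights
  # assigned by the same EP-binning rule as the training set
  # (the empty-bin fallback is benign for a monitoring-only quantity)
  w_val <- suppressWarnings(compute_weights(ep_val))
  set.seed(seed)
  pars <- c("W1", "b1", "W2", "b2", "W3", "b3")
  vel <- lapply(model[pars], function(p) p * 0)
  best <- list(loss = Inf, model = model, epoch = 0L)
  history <- NULL
  iter <- 0L
  wait <- 0L
  n <- nrow(X_train)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- dnn_forward(model, X_train[idx, , drop = FALSE], training = TRUE)
      loss <- dnn_loss(fw$Y, t_train[idx], weights[idx])
      if (!is.finite(loss)) stop("divergent loss (non-finite) at epoch ", epoch)
      g <- dnn_gradients(model, fw, t_train[idx], weights[idx])
      lr_t <- lr / (1 + decay * iter)
      for (p in pars) {
        vel[[p]] <- momentum * vel[[p]] - lr_t * g[[p]]
        # Nesterov update: look-ahead step along the new velocity
        model[[p]] <- model[[p]] + momentum * vel[[p]] - lr_t * g[[p]]
      }
      iter <- iter + 1L
      ep_loss <- ep_loss + loss * length(idx)
    }
    val_loss <- dnn_loss(dnn_forward(model, X_val)$Y, t_val, w_val)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, ep_loss / n, val_loss))
    }
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, model = model, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(model = best$model, history = history, best_epoch = best$epoch)
}

#' Predict edit percentages with a trained network
#'
#' The raw network output `y` approximates `log(EP + 1)`; predictions are
#' reported as `clip(exp(y) - 1, 0, 100)`.
#'
#' @param model A `dnn_model`.
#' @param X Input matrix (designs x 235).
#' @param raw Return the raw log-scale output instead of edit percentages.
#' @return Numeric vector of predictions (dropout disabled).
#' @export
dnn_predict <- function(model, X, raw = FALSE) {
  y <- drop(dnn_forward(model, X)$Y)
  if (raw) y else pmin(pmax(exp(y) - 1, 0), 100)
}

#' Numerical gradient check of the network
#'
#' Compares analytic backpropagation gradients with central finite
#' differences on a small random subset of parameters.
#'
#' @param model A `dnn_model`.
#' @param X,ep Inputs and edit percentages of a tiny batch.
#' @param n_checks Number of randomly sampled parameters per layer.
#' @param eps Finite-difference step.
#' @param seed Seed for the parameter sample.
#' @return Maximum relative discrepancy across checked parameters.
#' @export
dnn_gradient_check <- function(model, X, ep, n_checks = 12L, eps = 1e-5,
                               seed = 1L) {
  target <- log(ep + 1)
  w <- rep(1, length(ep))
  ana <- dnn_gradients(model, dnn_forward(model, X), target, w)
  set.seed(seed)
  worst <- 0
  for (p in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    free <- if (p == "W1") which(model$mask != 0) else seq_along(model[[p]])
    for (j in sample(free, min(n_checks, length(free)))) {
      m2 <- model
      m2[[p]][j] <- model[[p]][j] + eps
      up <- dnn_loss(dnn_forward(m2, X)$Y, target, w)
      m2[[p]][j] <- model[[p]][j] - eps
      dn <- dnn_loss(dnn_forward(m2, X)$Y, target, w)
      num <- (up - dn) / (2 * eps)
      rel <- abs(num - ana[[p]][j]) / max(abs(num), abs(ana[[p]][j]), 1e-8)
      worst <- max(worst, rel)
    }
  }
  worst
}

#' @export
print.dnn_model <- function(x, ...) {
  pc <- dnn_param_count(x)
  cat("position-specific-filter network: 40 blocks x 10 filters (8x5) -> 10 -> 1\n")
  cat(sprintf("  parameters: %d filter + %d dense + %d output = %d\n",
              pc["filters"], pc["dense"], pc["output"], pc["total"]))
  invisible(x)
}
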