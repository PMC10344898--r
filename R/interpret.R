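#' Configuration for generalized simulated annealing
#'
#' @param q Tsallis parameter of the generalized acceptance rule (q >= 1;
#'   q -> 1 recovers Boltzmann acceptance, larger q broadens sampling).
#' @param t0 Initial temperature (score units).
#' @param cooling Geometric cooling factor per step (0 < cooling < 1).
#' @param n_steps Number of proposal steps.
#' @param seed Integer seed.
#' @return Object of class `sa_config`.
#' @export
sa_config <- function(q = 1.5, t0 = 1, cooling = 0.999, n_steps = 5000L,
                      seed = 1L) {
  stopifnot(q >= 1, t0 > 0, cooling > 0, cooling < 1, n_steps >= 1L)
  structure(list(q = q, t0 = t0, cooling = cooling,
                 n_steps = as.integer(n_steps), seed = as.integer(seed)),
            class = "sa_config")
}

# generalized (Tsallis) acceptance probability for a score decrease d >= 0
# at temperature temp; q -> 1 limit is exp(-d/temp)
tsallis_accept <- function(d, temp, q) {
  if (d <= 0) return(1)
  if (abs(q - 1) < 1e-12) return(exp(-d / temp))
  (1 + (q - 1) * d / temp)^(-1 / (q - 1))
}

# single-position substitution proposal; the PAM GG at +5,+6 is never touched
propose_substitution <- function(window) {
  pos <- sample(free_positions(), 1L)
  idx <- position_index(pos)
  old <- substr(window, idx, idx)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  substr(window, idx, idx) <- new
  window
}

#' Maximize a sequence scorer by generalized simulated annealing
#'
#' Metropolis-type search over 47-nt windows with single-position
#' substitution proposals (the PAM GG is pinned): score increases are always
#' accepted; a decrease `d` is accepted with the Tsallis-generalized
#' probability `(1 + (q-1) d/T)^(-1/(q-1))` under geometric cooling
#' `T_k = t0 * cooling^k`. Returns the best sequence ever visited.
#'
#' @param scorer Function mapping a 47-nt window to a numeric score.
#' @param init 47-nt starting window.
#' @param config An [sa_config()].
#' @return List with `best_window`, `best_score`, and `trace` (data frame of
#'   step, temperature, current and best-ever score).
#' @export
sa_optimize <- function(scorer, init, config = sa_config()) {
  assert_window(init)
  set.seed(config$seed)
  cur <- init
  cur_score <- scorer(cur)
  best <- cur
  best_score <- cur_score
  trace <- data.frame(step = 0L, temperature = config$t0,
                      score = cur_score, best_score = best_score)
  temp <- config$t0
  for (k in seq_len(config$n_steps)) {
    cand <- propose_substitution(cur)
    cand_score <- scorer(cand)
    d <- cur_score - cand_score  # positive = worsening move
    if (d <= 0 || stats::runif(1) < tsallis_accept(d, temp, config$q)) {
      cur <- cand
      cur_score <- cand_score
      if (cur_score > best_score) {
        best <- cur
        best_score <- cur_score
      }
    }
    temp <- temp * config$cooling
    if (k %% 100L == 0L || k == config$n_steps) {
      trace <- rbind(trace, data.frame(step = k, temperature = temp,
                                       score = cur_score, best_score = best_score))
    }
  }
  list(best_window = best, best_score = best_score, trace = trace)
}

#' MaxEnt sampling of sequences with similar model scores
#'
#' Metropolis chain whose stationary distribution is uniform (maximum
#' entropy) over the set of windows whose score lies within `delta` of the
#' anchor's score: single-position substitution proposals are accepted if
#' and only if the proposed window stays inside the score band (symmetric
#' proposals on a hard constraint set).
#'
#' @param scorer Function mapping a 47-nt window to a numeric score.
#' @param anchor Anchor window (e.g. an SA optimum); its score defines the
#'   band center.
#' @param delta Half-width of the score band; default 5% of the absolute
#'   anchor score. Use `Inf` for unconstrained uniform sampling.
#' @param n_samples Number of retained samples.
#' @param burn_in Discarded initial steps.
#' @param thin Keep every `thin`-th state after burn-in.
#' @param seed Integer seed.
#' @param min_acceptance Abort below this post-burn-in acceptance rate.
#' @return List with `samples` (character vector of windows), `acceptance`
#'   and `anchor_score`.
#' @export
maxent_sample <- function(scorer, anchor, delta = NULL, n_samples = 1000L,
                          burn_in = 500L, thin = 5L, seed = 1L,
                          min_acceptance = 0.01) {
  assert_window(anchor)
  s0 <- scorer(anchor)
  if (!is.finite(s0)) stop("scorer is not finite at the anchor")
  delta <- delta %||% (0.05 * abs(s0))
  set.seed(seed)
  cur <- anchor
  samples <- character(n_samples)
  kept <- 0L
  accepted <- 0L
  proposed <- 0L
  step <- 0L
  while (kept < n_samples) {
    step <- step + 1L
    cand <- propose_substitution(cur)
    proposed <- proposed + 1L
    if (abs(scorer(cand) - s0) <= delta) {
      cur <- cand
      accepted <- accepted + 1L
    }
    if (step > burn_in && (step - burn_in) %% thin == 0L) {
      kept <- kept + 1L
      samples[kept] <- cur
    }
    if (proposed == burn_in + 200L && accepted / proposed < min_acceptance) {
      stop("MaxEnt acceptance rate below ", min_acceptance,
           "; consider raising delta")
    }
  }
  list(samples = samples, acceptance = accepted / proposed, anchor_score = s0)
}

#' Position-wise nucleotide profile and KL saliency of sampled sequences
#'
#' Empirical per-position nucleotide frequencies of the sampled windows
#' (pseudocount-smoothed) and their Kullback-Leibler divergence from the
#' uniform null, `KL(p || u) = sum_k p_k log(4 p_k)` in nats. Positions with
#' large KL are the ones the sampled (score-constrained) sequences care
#' about.
#'
#' @param samples Character vector of 47-nt windows.
#' @param pseudocount Added to each nucleotide count before normalization
#'   (default 0.5; 0 recovers the raw empirical estimate).
#' @return Data frame of class `nucleotide_profile` with columns `position`,
#'   `pA`, `pC`, `pG`, `pT`, `kl` for the 45 free positions.
#' @export
kl_profile <- function(samples, pseudocount = 0.5) {
  if (length(samples) < 1L) stop("at least one sample is required")
  pos <- free_positions()
  idx <- position_index(pos)
  chars <- do.call(rbind, strsplit(samples, ""))[, idx, drop = FALSE]
  prof <- t(apply(chars, 2, function(col) {
    counts <- table(factor(col, levels = c("A", "C", "G", "T"))) + pseudocount
    as.numeric(counts / sum(counts))
  }))
  kl <- apply(prof, 1, function(p) {
    terms <- ifelse(p > 0, p * log(4 * p), 0)
    sum(terms)
  })
  out <- data.frame(position = pos, pA = prof[, 1], pC = prof[, 2],
                    pG = prof[, 3], pT = prof[, 4], kl = kl)
  class(out) <- c("nucleotide_profile", "data.frame")
  out
}

#' Stratified mean edit percentage at a focal position
#'
#' Mean edit percentage by focal-position nucleotide, optionally restricted
#' to designs whose windows satisfy nucleotide conditions at other
#' positions. The no-condition case reproduces the marginal means.
#'
#' @param windows Character vector of 47-nt windows (one per design).
#' @param ep Numeric edit percentages.
#' @param focal_pos Nick-relative focal position.
#' @param condition Named list mapping position (as character, e.g. `"8"`
#'   or `"-4"`) to a required nucleotide; `NULL` for the marginal case.
#' @param min_n Strata smaller than this are flagged (`ok = FALSE`), never
#'   silently dropped.
#' @return Data frame with `nucleotide`, `mean_ep`, `n`, `ok`.
#' @export
conditional_effect <- function(windows, ep, focal_pos, condition = NULL,
                               min_n = 30L) {
  stopifnot(length(windows) == length(ep))
  keep <- rep(TRUE, length(windows))
  for (p in names(condition)) {
    keep <- keep & vapply(windows, function(w)
      window_base(w, as.integer(p)) == condition[[p]], logical(1), USE.NAMES = FALSE)
  }
  focal <- vapply(windows, window_base, character(1), pos = focal_pos,
                  USE.NAMES = FALSE)
  out <- do.call(rbind, lapply(c("A", "C", "G", "T"), function(nt) {
    sel <- keep & focal == nt
    data.frame(nucleotide = nt,
               mean_ep = if (any(sel)) mean(ep[sel]) else NA_real_,
               n = sum(sel))
  }))
  out$ok <- out$n >= min_n
  out
}
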