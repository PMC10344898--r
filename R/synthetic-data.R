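#' Configuration for the synthetic prime-editing world
#'
#' Describes the generative model used for all synthetic inputs: a latent
#' additive score per pegRNA design passed through a logistic link, scaled to
#' a percentage, and multiplicatively gated by distance to the nearest
#' heterochromatin region. The planted effect families mirror the
#' determinants the package models downstream: position-specific nucleotide
#' effects in the 47-nt window, a GC-content-by-PBS-length interaction, band-
#' specific last-templated-nucleotide effects, and heterochromatin gating.
#'
#' @param seed Integer seed; all randomness in `generate_*` calls derives
#'   from it deterministically.
#' @param n_sites Number of target sites to generate.
#' @param genome_length Length of the synthetic chromosome in bases.
#' @param position_effects Data frame with columns `pos` (nick-relative),
#'   `nt` and `effect` (latent score units) giving planted per-position
#'   nucleotide effects.
#' @param gc_pbsl_gamma Coefficient (score units per GC-fraction per 1/PBSL)
#'   of the GC x PBSL interaction: contribution is
#'   `gc_pbsl_gamma * GC(PBS) / PBSL`, so a short PBS leans harder on its GC
#'   content.
#' @param last_nt_effects 4 x 3 numeric matrix (rows A,C,G,T; columns
#'   `short`, `mid`, `long` RTTL bands) of last-templated-nucleotide effects
#'   in score units.
#' @param chromatin_midpoint Gate midpoint in log10 kilobases: a site at
#'   distance `10^chromatin_midpoint` kb has gate factor exactly 0.5.
#' @param chromatin_slope Gate steepness per log10-kb unit; `0` disables the
#'   gate entirely (factor 1 for every site).
#' @param noise_sd Replicate noise standard deviation in percentage points.
#' @param baseline Latent score intercept.
#' @param n_replicates Biological replicates per design (3 by default,
#'   matching the in-house protocol the data model emulates).
#' @param dist_log10_range Range of log10 distances (kb) from which per-site
#'   heterochromatin distances are drawn uniformly.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_sites = 200L,
                             genome_length = 200000L,
                             position_effects = default_position_effects(),
                             gc_pbsl_gamma = 8,
                             last_nt_effects = default_last_nt_effects(),
                             chromatin_midpoint = log10(25),
                             chromatin_slope = 4,
                             noise_sd = 3,
                             baseline = -2,
                             n_replicates = 3L,
                             dist_log10_range = c(-1, 3.5)) {
  cfg <- list(
    seed = as.integer(seed), n_sites = as.integer(n_sites),
    genome_length = as.integer(genome_length),
    position_effects = position_effects,
    gc_pbsl_gamma = gc_pbsl_gamma,
    last_nt_effects = last_nt_effects,
    chromatin_midpoint = chromatin_midpoint,
    chromatin_slope = chromatin_slope,
    noise_sd = noise_sd, baseline = baseline,
    n_replicates = as.integer(n_replicates),
    dist_log10_range = dist_log10_range
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1L, cfg$noise_sd >= 0, cfg$n_replicates >= 1L)
  pe <- cfg$position_effects
  if (!is.data.frame(pe) || !all(c("pos", "nt", "effect") %in% names(pe))) {
    stop("position_effects must be a data frame with columns pos, nt, effect")
  }
  if (nrow(pe) > 0L) {
    position_index(pe$pos)  # validates the coordinate range
    if (any(pe$pos %in% c(5L, 6L))) {
      stop("position_effects may not target the fixed PAM GG at +5,+6")
    }
    if (!all(pe$nt %in% c("A", "C", "G", "T"))) stop("position_effects nt must be A/C/G/T")
  }
  lne <- cfg$last_nt_effects
  if (!is.matrix(lne) || !identical(rownames(lne), c("A", "C", "G", "T")) ||
      !identical(colnames(lne), c("short", "mid", "long"))) {
    stop("last_nt_effects must be a 4x3 matrix with rows A,C,G,T and columns short,mid,long")
  }
  cfg
}

#' Default planted position-specific nucleotide effects
#'
#' Six nonzero effects, one per effect direction the sequence models are
#' expected to recover: C at +1 and G at +3 favourable immediately 3' of the
#' nick, G at -17 favourable, T at -2 and G at +7 unfavourable, C at +20
#' favourable. Magnitudes are in latent score units (0.4-0.6 corresponds to
#' roughly 8-14 percentage points of edit percentage near the logistic
#' midpoint).
#'
#' @return Data frame with columns `pos`, `nt`, `effect`.
#' @export
default_position_effects <- function() {
  data.frame(
    pos = c(1L, 3L, -17L, -2L, 7L, 20L),
    nt = c("C", "G", "G", "T", "G", "C"),
    effect = c(0.6, 0.5, 0.4, -0.5, -0.5, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Default last-templated-nucleotide effects by RTTL band
#'
#' Encodes the band-dependent pattern the regression models look for:
#' G mildly favourable when the RT template is short (RTTL <= 12), and the
#' T ~ C > A > G ordering with G clearly unfavourable for long templates.
#'
#' @return 4 x 3 numeric matrix (rows A,C,G,T; columns short, mid, long).
#' @export
default_last_nt_effects <- function() {
  m <- rbind(
    A = c(0, 0, 0),
    C = c(0, 0.2, 0.5),
    G = c(0.4, -0.3, -0.8),
    T = c(0, 0.2, 0.5)
  )
  colnames(m) <- c("short", "mid", "long")
  m
}

#' RTTL band used by the last-templated-nucleotide effect map
#'
#' @param rttl RT template length(s) in nt.
#' @return Character vector in `c("short","mid","long")`: short for
#'   RTTL <= 12, mid for 13..15, long for RTTL > 15.
#' @export
rttl_band <- function(rttl) {
  ifelse(rttl <= 12, "short", ifelse(rttl <= 15, "mid", "long"))
}

#' Generate synthetic target sites on a toy genome
#'
#' Builds a random chromosome and places `n_sites` non-overlapping 47-nt
#' edited-strand windows on it, each with the fixed GG PAM dinucleotide
#' written at nick-relative +5,+6 (so every site is a valid NGG target).
#' Each site also receives a planted distance to the nearest heterochromatin
#' region, drawn log-uniformly over `dist_log10_range`.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `site_id`, `chrom`, `strand`, `nick_pos`
#'   (1-based genomic coordinate of the +1 base), `dist_kb` and `window`.
#'   The genome sequence is attached as attribute `"genome"` (a named
#'   character vector usable with [Biostrings::DNAStringSet()]).
#' @export
generate_sites <- function(config) {
  cfg <- validate_synthetic_config(config)
  set.seed(cfg$seed)
  slot <- 60L  # 47-nt window + margin so windows can never overlap
  n_slots <- (cfg$genome_length - 26L) %/% slot
  if (n_slots < cfg$n_sites) {
    stop("genome_length cannot host ", cfg$n_sites, " non-overlapping windows")
  }
  genome <- sample(c("A", "C", "G", "T"), cfg$genome_length, replace = TRUE)
  slots <- sort(sample.int(n_slots, cfg$n_sites))
  nick_pos <- (slots - 1L) * slot + 22L
  genome[nick_pos + 4L] <- "G"  # +5
  genome[nick_pos + 5L] <- "G"  # +6
  genome_str <- paste(genome, collapse = "")
  windows <- substring(genome_str, nick_pos - 21L, nick_pos + 25L)
  dist_kb <- 10^stats::runif(cfg$n_sites, cfg$dist_log10_range[1], cfg$dist_log10_range[2])
  sites <- data.frame(
    site_id = sprintf("site%04d", seq_len(cfg$n_sites)),
    chrom = "chrS", strand = "+",
    nick_pos = nick_pos, dist_kb = dist_kb,
    window = windows, stringsAsFactors = FALSE
  )
  attr(sites, "genome") <- c(chrS = genome_str)
  sites
}

#' Expand a pegRNA design grid over sites
#'
#' @param sites Site table from [generate_sites()].
#' @param pbsl PBS lengths (default the 7..17 odd grid).
#' @param rttl RT template lengths (default the 10/12/15/20 grid; a
#'   consecutive grid such as `10:20` is equally valid).
#' @return Data frame with `design_id`, `site_id`, `pbsl`, `rttl`.
#' @export
design_grid <- function(sites, pbsl = c(7L, 9L, 11L, 13L, 15L, 17L),
                        rttl = c(10L, 12L, 15L, 20L)) {
  stopifnot(all(pbsl >= 1 & pbsl <= 21), all(rttl >= 1 & rttl <= 26))
  g <- expand.grid(site_id = sites$site_id, pbsl = as.integer(pbsl),
                   rttl = as.integer(rttl), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$site_id, g$pbsl, g$rttl), , drop = FALSE]
  rownames(g) <- NULL
  data.frame(design_id = sprintf("d%05d", seq_len(nrow(g))), g,
             stringsAsFactors = FALSE)
}

# latent score of one design under the planted-effect model
latent_score <- function(window, pbsl, rttl, cfg) {
  s <- cfg$baseline
  pe <- cfg$position_effects
  if (nrow(pe) > 0L) {
    hit <- window_base(window, pe$pos) == pe$nt
    s <- s + sum(pe$effect[hit])
  }
  s <- s + cfg$gc_pbsl_gamma * gc_fraction(pbs_sequence(window, pbsl)) / pbsl
  last_nt <- window_base(window, rttl)
  s + cfg$last_nt_effects[last_nt, rttl_band(rttl)]
}

#' Generate edit percentages with planted effects
#'
#' Evaluates the latent-score model for each design, applies the logistic
#' link and the multiplicative chromatin gate, and adds replicate noise:
#' `true_ep = 100 * logistic(s) * logistic(slope * (log10(dist_kb) - midpoint))`
#' (gate factor 1 when `chromatin_slope = 0`), and
#' `observed_ep = clip(true_ep + N(0, noise_sd), 0, 100)` per replicate.
#'
#' @param sites Site table from [generate_sites()].
#' @param designs Design table from [design_grid()].
#' @param config The [synthetic_config()] used to generate the sites.
#' @return An object of class `synthetic_dataset`: a list with `sites`,
#'   `designs` (augmented with `true_ep` and `mean_observed_ep`),
#'   `observed_ep` (designs x replicates matrix) and `config` (so planted
#'   parameters remain available for recovery tests).
#' @export
generate_edit_percentages <- function(sites, designs, config) {
  cfg <- validate_synthetic_config(config)
  stopifnot(all(designs$site_id %in% sites$site_id))
  set.seed(cfg$seed + 1000L)
  win <- sites$window[match(designs$site_id, sites$site_id)]
  dist_kb <- sites$dist_kb[match(designs$site_id, sites$site_id)]
  s <- mapply(latent_score, win, designs$pbsl, designs$rttl,
              MoreArgs = list(cfg = cfg), USE.NAMES = FALSE)
  gate <- if (cfg$chromatin_slope == 0) {
    rep(1, length(s))
  } else {
    logistic(cfg$chromatin_slope * (log10(dist_kb) - cfg$chromatin_midpoint))
  }
  true_ep <- 100 * logistic(s) * gate
  n <- length(true_ep)
  obs <- matrix(true_ep, n, cfg$n_replicates) +
    matrix(stats::rnorm(n * cfg$n_replicates, 0, cfg$noise_sd), n, cfg$n_replicates)
  obs <- pmin(pmax(obs, 0), 100)
  colnames(obs) <- sprintf("rep%d", seq_len(cfg$n_replicates))
  designs$true_ep <- true_ep
  designs$mean_observed_ep <- rowMeans(obs)
  out <- list(sites = sites, designs = designs, observed_ep = obs, config = cfg)
  class(out) <- "synthetic_dataset"
  out
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$sites), "sites,", nrow(x$designs),
      "designs,", ncol(x$observed_ep), "replicates\n")
  cat("  mean true EP:", round(mean(x$designs$true_ep), 2), "%\n")
  invisible(x)
}

#' Generate IP/input ChIP-like binned tracks with planted enrichment
#'
#' Poisson read counts per 1-kb bin; IP samples have their rate multiplied
#' by `fold` inside the planted intervals. Input samples never see the fold.
#'
#' @param n_bins Number of 1-kb bins on the toy chromosome. The default of
#'   10,000 makes the default planted material (10 intervals x 5 bins) match
#'   the 0.5% flagging tail of [consensus_enrichment()]'s default quantile.
#' @param n_ip,n_input Number of IP and input samples (>= 2 IP and >= 1
#'   input required downstream).
#' @param base_rate Poisson rate per bin outside planted intervals.
#' @param fold Enrichment fold inside planted intervals; must be > 1 when
#'   `n_peaks > 0` (fold = 1 is allowed only as the explicit no-signal case
#'   via `n_peaks = 0`).
#' @param n_peaks Number of planted enriched intervals.
#' @param peak_width_bins Width of each planted interval, in bins.
#' @param bin_size Bin width in bases (1 kb by default).
#' @param seed Integer seed.
#' @return List with `tracks` (list of `signal_track` objects) and `truth`
#'   (a [GenomicRanges::GRanges] of planted intervals; empty if none).
#' @export
generate_chip_tracks <- function(n_bins = 10000L, n_ip = 3L, n_input = 3L,
                                 base_rate = 50, fold = 8, n_peaks = 10L,
                                 peak_width_bins = 5L, bin_size = 1000L,
                                 seed = 1L) {
  stopifnot(n_ip >= 2L, n_input >= 1L, n_bins >= peak_width_bins)
  if (n_peaks > 0L && fold <= 1) stop("enrichment fold must be > 1")
  set.seed(seed)
  rate <- rep(base_rate, n_bins)
  truth_start <- integer(0)
  if (n_peaks > 0L) {
    slot <- max(2L * peak_width_bins, peak_width_bins + 2L)
    n_slots <- n_bins %/% slot
    if (n_slots < n_peaks) stop("too many peaks for the number of bins")
    truth_start <- (sort(sample.int(n_slots, n_peaks)) - 1L) * slot + 1L
  }
  in_peak <- rep(FALSE, n_bins)
  for (s in truth_start) in_peak[s:(s + peak_width_bins - 1L)] <- TRUE
  ip_rate <- ifelse(in_peak, base_rate * fold, base_rate)
  tracks <- c(
    lapply(seq_len(n_ip), function(i)
      signal_track(stats::rpois(n_bins, ip_rate), bin_size = bin_size,
                   label = "IP", sample = sprintf("IP%d", i))),
    lapply(seq_len(n_input), function(i)
      signal_track(stats::rpois(n_bins, rate), bin_size = bin_size,
                   label = "input", sample = sprintf("input%d", i)))
  )
  truth <- GenomicRanges::GRanges(
    seqnames = rep("chrS", length(truth_start)),
    ranges = IRanges::IRanges(
      start = (truth_start - 1L) * bin_size + 1L,
      width = peak_width_bins * bin_size
    )
  )
  list(tracks = tracks, truth = truth)
}

#' Generate classified amplicon reads for one locus
#'
#' Emits single-end and proper-pair read records labelled
#' `edited_perfect`, `wildtype_perfect` or `other`. Fragments are classified
#' first (edited with probability `true_ep/100` among perfect fragments,
#' `other` with probability `frac_other` overall) and then emitted either as
#' a mate pair sharing a `pair_id` or as a lone single-end record.
#'
#' @param site_id Locus identifier carried into the read table.
#' @param true_ep True edit percentage in `[0, 100]`.
#' @param n_pairs Number of fragments to simulate.
#' @param seed Integer seed.
#' @param frac_single Fraction of fragments emitted as single-end records.
#' @param frac_other Fraction of fragments classified `other` (imperfect).
#' @return Data frame with `read_id`, `pair_id` (NA for single-end) and
#'   `class`.
#' @export
generate_reads <- function(site_id, true_ep, n_pairs, seed = 1L,
                           frac_single = 0.1, frac_other = 0.05) {
  stopifnot(true_ep >= 0, true_ep <= 100, n_pairs >= 1L)
  set.seed(seed)
  is_other <- stats::runif(n_pairs) < frac_other
  edited <- stats::runif(n_pairs) < true_ep / 100
  cls <- ifelse(is_other, "other",
                ifelse(edited, "edited_perfect", "wildtype_perfect"))
  paired <- stats::runif(n_pairs) >= frac_single
  n_rec <- sum(paired) * 2L + sum(!paired)
  frag <- rep(seq_len(n_pairs), times = ifelse(paired, 2L, 1L))
  data.frame(
    read_id = sprintf("%s_r%06d", site_id, seq_len(n_rec)),
    pair_id = ifelse(paired[frag], sprintf("%s_p%06d", site_id, frag), NA_character_),
    class = cls[frag],
    stringsAsFactors = FALSE
  )
}
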