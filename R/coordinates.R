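#' Nick-relative coordinates of the 47-nt target window
#'
#' Target sites are represented as 47-nt edited-strand windows indexed
#' relative to the PE2 nick site: positions -21..-1 lie 5' of the nick
#' (the primer-binding-site side) and +1..+26 lie 3' of it (the RT-template
#' side). There is no position 0. The NGG PAM occupies +4..+6 with the GG
#' dinucleotide fixed at +5 and +6.
#'
#' @return Integer vector of the 47 nick-relative positions, in window order.
#' @export
window_positions <- function() c(-21:-1, 1:26)

#' Convert a nick-relative position to a 1-based window index
#'
#' @param pos Integer vector of nick-relative positions (no 0 allowed).
#' @return Integer vector of indices into the 47-character window.
#' @export
position_index <- function(pos) {
  pos <- as.integer(pos)
  if (any(pos == 0L) || any(pos < -21L) || any(pos > 26L)) {
    stop("positions must lie in -21..-1 or +1..+26 (there is no position 0)")
  }
  ifelse(pos < 0L, pos + 22L, pos + 21L)
}

#' Extract bases at nick-relative positions from a target window
#'
#' @param window A 47-character edited-strand window string (or a vector of
#'   windows, recycled against `pos`).
#' @param pos Nick-relative position(s).
#' @return Character vector of single bases.
#' @export
window_base <- function(window, pos) {
  idx <- position_index(pos)
  substring(window, idx, idx)
}

# positions that carry sequence features (PAM GG at +5,+6 is fixed)
free_positions <- function() setdiff(window_positions(), c(5L, 6L))

logistic <- function(x) 1 / (1 + exp(-x))

assert_window <- function(window) {
  if (!is.character(window) || length(window) != 1L) {
    stop("window must be a single character string")
  }
  if (nchar(window) != 47L) stop("window must be exactly 47 nt long")
  if (grepl("[^ACGT]", window)) stop("window contains non-ACGT characters")
  if (window_base(window, 5L) != "G" || window_base(window, 6L) != "G") {
    stop("window must carry the fixed GG PAM dinucleotide at +5,+6")
  }
  invisible(window)
}

# PBS subsequence on the edited strand: positions -PBSL..-1
pbs_sequence <- function(window, pbsl) {
  if (pbsl < 1L || pbsl > 21L) stop("PBSL must lie in 1..21")
  substr(window, 22L - pbsl, 21L)
}

# RT-template subsequence on the edited strand: positions +1..+RTTL
rtt_sequence <- function(window, rttl) {
  if (rttl < 1L || rttl > 26L) stop("RTTL must lie in 1..26")
  substr(window, 22L, 21L + rttl)
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
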