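#' Edit percentage from classified reads
#'
#' Computes the fraction of perfectly matching reads that carry the intended
#' edit, with the paired-end correction: for reads found in complete mate
#' pairs, half of their number is excluded from both the edited and the
#' wild-type counts, so that a sequenced fragment is never counted twice.
#' With `E`, `W` the edited/wild-type read counts and `E_p`, `W_p` the
#' counts of such reads in complete concordant pairs, the statistic is
#' `100 * (E - E_p/2) / ((E - E_p/2) + (W - W_p/2))`.
#'
#' A pair is halved only when both mates are present and agree in class;
#' discordant pairs are counted as two independent reads. Reads of class
#' `other` (imperfect) never enter the statistic.
#'
#' @param reads Data frame with columns `read_id`, `pair_id` (NA for
#'   single-end) and `class` in `c("edited_perfect","wildtype_perfect","other")`.
#' @return Edit percentage in `[0, 100]`.
#' @export
edit_percentage <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("pair_id", "class") %in% names(reads)))
  bad <- setdiff(unique(reads$class), c("edited_perfect", "wildtype_perfect", "other"))
  if (length(bad)) stop("unknown read class: ", paste(bad, collapse = ", "))
  paired_counts <- function(cls) {
    sub <- reads[reads$class == cls & !is.na(reads$pair_id), , drop = FALSE]
    if (nrow(sub) == 0L) return(0L)
    # complete concordant pairs: both mates present with this same class
    sum(table(sub$pair_id) == 2L) * 2L
  }
  E <- sum(reads$class == "edited_perfect")
  W <- sum(reads$class == "wildtype_perfect")
  E_eff <- E - paired_counts("edited_perfect") / 2
  W_eff <- W - paired_counts("wildtype_perfect") / 2
  denom <- E_eff + W_eff
  if (denom <= 0) stop("no informative reads: no perfectly matching edited or wild-type fragments")
  100 * E_eff / denom
}

#' Average edit percentage over biological replicates
#'
#' @param per_replicate Numeric vector of per-replicate edit percentages.
#' @return List of class `edit_percentage_summary` with fields
#'   `per_replicate` and `mean` (unweighted arithmetic mean).
#' @export
mean_over_replicates <- function(per_replicate) {
  if (length(per_replicate) < 1L) stop("at least one replicate is required")
  if (any(!is.finite(per_replicate)) || any(per_replicate < 0 | per_replicate > 100)) {
    stop("edit percentages must be finite and in [0, 100]")
  }
  structure(list(per_replicate = per_replicate, mean = mean(per_replicate)),
            class = "edit_percentage_summary")
}

#' @export
print.edit_percentage_summary <- function(x, ...) {
  cat(sprintf("edit percentage: mean %.2f%% over %d replicate(s)\n",
              x$mean, length(x$per_replicate)))
  invisible(x)
}

# integer-encode a DNA string; anything outside ACGT maps to 0 and can
# never match (IUPAC ambiguity codes in the genome are treated as mismatches)
encode_dna <- function(seq) {
  v <- utf8ToInt(seq)
  code <- integer(length(v))
  code[v == utf8ToInt("A")] <- 1L
  code[v == utf8ToInt("C")] <- 2L
  code[v == utf8ToInt("G")] <- 3L
  code[v == utf8ToInt("T")] <- 4L
  code
}

scan_strand <- function(genome_code, proto_code, max_mismatch) {
  L <- length(genome_code)
  n <- L - 22L
  if (n < 1L) return(integer(0))
  starts <- seq_len(n)
  pam_ok <- genome_code[starts + 21L] == 3L & genome_code[starts + 22L] == 3L
  mm <- integer(n)
  for (k in 1:20) {
    gk <- genome_code[starts + k - 1L]
    mm <- mm + (gk != proto_code[k] | gk == 0L)
  }
  starts[pam_ok & mm <= max_mismatch]
}

#' Find genome-wide protospacer matches upstream of an NGG PAM
#'
#' Scans both strands for 23-nt loci whose last two bases are the GG of an
#' NGG PAM (the N is free) and whose first 20 bases match the protospacer
#' with at most `max_mismatch` mismatches. Non-ACGT genome characters never
#' match.
#'
#' @param protospacer 20-nt A/C/G/T protospacer (PAM-proximal orientation).
#' @param genome Genome sequence: a character string, or a
#'   [Biostrings::DNAString]/[Biostrings::DNAStringSet] (first sequence used).
#' @param max_mismatch Maximum Hamming mismatches outside the PAM (default 3).
#' @return Data frame with `start` (1-based leftmost forward-strand
#'   coordinate of the 23-nt locus), `strand` and `mismatches`.
#' @export
find_spacer_hits <- function(protospacer, genome, max_mismatch = 3L) {
  if (nchar(protospacer) != 20L) stop("protospacer must be exactly 20 nt")
  if (grepl("[^ACGT]", protospacer)) stop("ambiguous bases in protospacer are not supported")
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome[[1]])
  if (methods::is(genome, "DNAString")) genome <- as.character(genome)
  if (nchar(genome) == 0L) stop("genome is empty")
  p <- encode_dna(protospacer)
  g_fwd <- encode_dna(genome)
  g_rev <- encode_dna(revcomp(genome))
  L <- nchar(genome)
  mism <- function(code, starts) {
    vapply(starts, function(s) sum(code[s:(s + 19L)] != p | code[s:(s + 19L)] == 0L), integer(1))
  }
  fwd <- scan_strand(g_fwd, p, max_mismatch)
  rev <- scan_strand(g_rev, p, max_mismatch)
  out <- rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+", mismatches = mism(g_fwd, fwd)),
    if (length(rev)) data.frame(start = L - rev - 21L, strand = "-", mismatches = mism(g_rev, rev))
  )
  if (is.null(out)) out <- data.frame(start = integer(0), strand = character(0),
                                      mismatches = integer(0))
  rownames(out) <- NULL
  out
}

#' Count potential off-target loci of a protospacer
#'
#' Wraps [find_spacer_hits()] and optionally removes the on-target locus
#' from the count when its coordinates are supplied.
#'
#' @inheritParams find_spacer_hits
#' @param on_target Optional list with `start` (1-based leftmost
#'   forward-strand coordinate of the 23-nt on-target locus) and `strand`;
#'   matching hits are excluded from the count.
#' @return Integer count of off-target loci.
#' @export
count_off_targets <- function(protospacer, genome, max_mismatch = 3L,
                              on_target = NULL) {
  hits <- find_spacer_hits(protospacer, genome, max_mismatch)
  n <- nrow(hits)
  if (!is.null(on_target)) {
    n <- n - sum(hits$start == on_target$start & hits$strand == on_target$strand)
  }
  n
}
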