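# deterministic fixtures shared across test files

# random valid 47-nt windows (GG forced at +5,+6)
random_windows <- function(n, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    chars <- sample(c("A", "C", "G", "T"), 47L, replace = TRUE)
    chars[position_index(c(5L, 6L))] <- "G"
    paste(chars, collapse = "")
  }, character(1))
}

# window with prescribed bases at given nick-relative positions
window_with <- function(..., fill = "A") {
  spec <- list(...)
  chars <- rep(fill, 47L)
  for (p in names(spec)) chars[position_index(as.integer(p))] <- spec[[p]]
  chars[position_index(c(5L, 6L))] <- "G"
  paste(chars, collapse = "")
}

# gate-off world with only the stated planted effects, used by the
# sequence-model recovery tests
seq_only_config <- function(seed, n_sites, noise_sd = 3, ...) {
  synthetic_config(seed = seed, n_sites = n_sites, noise_sd = noise_sd,
                   chromatin_slope = 0, ...)
}

# brute-force per-character summation oracle for hybridization energies:
# walks the DNA string base by base, forming each RNA step explicitly
oracle_hybridization <- function(seq, params) {
  comp <- c(A = "U", C = "G", G = "C", T = "A")
  total <- params$initiation
  for (i in seq_len(nchar(seq) - 1L)) {
    d1 <- substr(seq, i, i)
    d2 <- substr(seq, i + 1L, i + 1L)
    rna <- paste0(comp[[d2]], comp[[d1]])  # antiparallel complement, 5'->3'
    total <- total + params$steps[[rna]]
  }
  total
}

# exhaustive all-window Hamming scan oracle for spacer hits (both strands)
oracle_spacer_hits <- function(protospacer, genome, max_mismatch = 3L) {
  hits <- 0L
  scan_one <- function(g) {
    n <- 0L
    L <- nchar(g)
    for (s in seq_len(max(0L, L - 22L))) {
      win <- substr(g, s, s + 22L)
      if (substr(win, 22L, 23L) != "GG") next
      a <- strsplit(substr(win, 1L, 20L), "")[[1]]
      b <- strsplit(protospacer, "")[[1]]
      if (sum(a != b | !a %in% c("A", "C", "G", "T")) <= max_mismatch) n <- n + 1L
    }
    n
  }
  scan_one(genome) +
    scan_one(as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome))))
}
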