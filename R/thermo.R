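#' Load nearest-neighbor RNA/DNA hybrid free-energy parameters
#'
#' Reads the dinucleotide-step table of hybrid-duplex Gibbs free energies at
#' 37 degrees C. Steps are keyed by the RNA strand read 5'->3'; the helix
#' initiation term accounts for forming the first base pair.
#'
#' @param file Path to a TSV with columns `step` and `dG_kcal_mol`; 16
#'   dinucleotide rows plus an `initiation` row. Defaults to the packaged
#'   table.
#' @return Object of class `nn_param_table`: list with `steps` (named
#'   16-vector, kcal/mol) and `initiation` (kcal/mol).
#' @export
nn_params <- function(file = system.file("extdata", "nn_params.tsv",
                                         package = "pegforge")) {
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  steps <- stats::setNames(tab$dG_kcal_mol, tab$step)
  init <- steps[["initiation"]]
  steps <- steps[names(steps) != "initiation"]
  expected <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  if (!setequal(names(steps), expected)) {
    stop("parameter table must contain exactly the 16 RNA dinucleotide steps")
  }
  if (any(!is.finite(c(steps, init)))) stop("non-finite free-energy values")
  structure(list(steps = steps[expected], initiation = init),
            class = "nn_param_table")
}

# RNA dinucleotide step (5'->3') pairing a DNA dinucleotide step (5'->3'):
# the hybrid is antiparallel, so the RNA step is the reverse complement
# with U opposite A.
dna_step_to_rna <- function(dna_steps) {
  chartr("ACGT", "UGCA", sapply(strsplit(dna_steps, ""), function(x)
    paste(rev(x), collapse = "")))
}

#' Hybridization free energy of an RNA/DNA duplex
#'
#' Total Gibbs free energy at 37 degrees C of the duplex formed by the given
#' DNA strand and its complementary RNA: the helix initiation term plus the
#' sum over all L-1 dinucleotide steps. The length-normalized value
#' (`per_nt_dG = total_dG / L`) is the statistic correlated with editing
#' efficiency downstream.
#'
#' @param seq DNA strand bound by the RNA (e.g. the edited-strand PBS
#'   footprint), 5'->3', A/C/G/T only, length >= 2.
#' @param params An [nn_params()] table.
#' @return Object of class `hybridization_result`: list with `total_dG`,
#'   `per_nt_dG` (kcal/mol) and `length`.
#' @export
hybridization_energy <- function(seq, params = nn_params()) {
  if (!is.character(seq) || length(seq) != 1L) stop("seq must be a single string")
  L <- nchar(seq)
  if (L < 2L) stop("sequence must be at least 2 nt long")
  if (grepl("[^ACGT]", seq)) stop("ambiguous bases are not supported")
  dna_steps <- substring(seq, 1:(L - 1L), 2:L)
  total <- params$initiation + sum(params$steps[dna_step_to_rna(dna_steps)])
  structure(list(total_dG = unname(total), per_nt_dG = unname(total) / L,
                 length = L),
            class = "hybridization_result")
}

#' @export
print.hybridization_result <- function(x, ...) {
  cat(sprintf("RNA-DNA hybrid dG37: %.2f kcal/mol (%.3f per nt over %d nt)\n",
              x$total_dG, x$per_nt_dG, x$length))
  invisible(x)
}

#' PBS-target hybridization energy for a pegRNA design
#'
#' Extracts the edited-strand PBS footprint (nick-relative positions
#' -PBSL..-1) from the target window and computes its RNA/DNA hybridization
#' energy.
#'
#' @param window 47-nt edited-strand target window.
#' @param pbsl PBS length in nt (2..21).
#' @param params An [nn_params()] table.
#' @return A `hybridization_result`.
#' @export
pbs_energy_for_design <- function(window, pbsl, params = nn_params()) {
  if (pbsl > 21L) stop("PBSL cannot exceed the 21-nt window arm")
  if (nchar(window) != 47L) stop("window must be 47 nt")
  hybridization_energy(pbs_sequence(window, pbsl), params)
}
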