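#' Monoisotopic residue masses and mass-spectrometry constants
#'
#' `aa_monoisotopic` holds the monoisotopic residue (not free amino acid)
#' masses of the 20 standard amino acids in Daltons; a peptide's neutral
#' monoisotopic mass is the sum of its residue masses plus one water.
#' `mass_constants` collects the fixed physical constants used throughout
#' the crosslink arithmetic: the mass of water, of a hydrogen atom, of a
#' proton, and the disulfide delta (forming S-S between two cysteines
#' removes two hydrogen atoms, hence -2 * 1.0078250 = -2.0156500 Da).
#'
#' @format `aa_monoisotopic` is a named numeric vector keyed by one-letter
#'   amino-acid code; `mass_constants` is a named list with elements
#'   `water`, `hydrogen`, `proton`, `disulfide_delta` (all Da).
#' @examples
#' sum(aa_monoisotopic[c("G")]) + mass_constants$water  # glycine peptide
#' @export
aa_monoisotopic <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047679, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' @rdname aa_monoisotopic
#' @export
mass_constants <- list(
  water = 18.0105646,
  hydrogen = 1.0078250,
  proton = 1.0072765,
  disulfide_delta = -2 * 1.0078250
)

# one-letter <-> three-letter code tables shared by the PDB parser
AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

is_standard_resname <- function(x) x %in% names(AA3)

check_peptide_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(aa_monoisotopic))
  if (length(bad) > 0) {
    stop("non-standard residue(s) in sequence: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  res
}
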