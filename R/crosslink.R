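#' Monoisotopic peptide mass
#'
#' Neutral monoisotopic mass of a peptide: the sum of its residue masses
#' plus one water. Optional fixed modifications are given as a named
#' mass-delta table applied per matching residue (e.g.
#' `c(C = 57.021464)` for carbamidomethyl-cysteine); none are applied by
#' default, because a disulfide-verification workflow keeps cysteines
#' unmodified.
#'
#' @param sequence one-letter amino-acid string.
#' @param fixed_mods named numeric vector of per-residue mass deltas (Da).
#' @return mass in Da.
#' @export
peptide_monoisotopic_mass <- function(sequence, fixed_mods = NULL) {
  res <- check_peptide_sequence(sequence)
  m <- sum(aa_monoisotopic[res]) + mass_constants$water
  if (!is.null(fixed_mods)) {
    hit <- res %in% names(fixed_mods)
    if (any(hit)) m <- m + sum(fixed_mods[res[hit]])
  }
  unname(m)
}

#' Neutral mass of a disulfide-crosslinked peptide pair
#'
#' Two cysteine-containing peptides joined by an S-S bond lose two
#' hydrogen atoms, so the crosslinked species' neutral mass is
#' `mass(a) + mass(b) - 2.01565 Da`. Both peptides must contain at least
#' one cysteine.
#'
#' @param pep_a,pep_b peptide sequences (one-letter).
#' @param fixed_mods passed to [peptide_monoisotopic_mass()].
#' @return neutral monoisotopic mass, Da.
#' @export
disulfide_crosslink_mass <- function(pep_a, pep_b, fixed_mods = NULL) {
  for (p in c(pep_a, pep_b)) {
    if (!grepl("C", p, fixed = TRUE)) {
      stop("peptide without cysteine cannot form a disulfide: ", p, call. = FALSE)
    }
  }
  peptide_monoisotopic_mass(pep_a, fixed_mods) +
    peptide_monoisotopic_mass(pep_b, fixed_mods) +
    mass_constants$disulfide_delta
}

#' m/z of a protonated species
#'
#' For a neutral monoisotopic mass M and positive charge z, the
#' mass-to-charge ratio of the \[M + zH\]^z+ ion is
#' `(M + z * 1.0072765) / z`.
#'
#' @param neutral_mass neutral monoisotopic mass, Da.
#' @param z charge state, integer >= 1.
#' @return m/z.
#' @export
mz_for_charge <- function(neutral_mass, z) {
  if (any(z < 1) || any(z != round(z))) {
    stop("charge state must be a positive integer", call. = FALSE)
  }
  (neutral_mass + z * mass_constants$proton) / z
}

#' Enumerate diagnostic disulfide-crosslinked peptide species
#'
#' Pairs every peptide of `digest_a` that covers an engineered cysteine
#' position with every such peptide of `digest_b`, and computes the
#' crosslinked neutral mass and the m/z ladder over a charge range. A
#' species is flagged `diagnostic` when neither of its peptides occurs
#' (by sequence) in the corresponding wild-type digest — those are the
#' peaks that prove the engineered disulfide formed, because they cannot
#' arise from the unmutated receptor. Same-peptide (intra-peptide)
#' disulfides are not enumerated.
#'
#' @param digest_a,digest_b fragment tables from [digest()] /
#'   [sequential_digest()] of the two mutant chains.
#' @param positions_a,positions_b engineered-cysteine positions (construct
#'   numbering on each chain's sequence).
#' @param charges integer charge states for the m/z columns.
#' @param wildtype_a,wildtype_b optional fragment tables of the wild-type
#'   digests used for the diagnostic flag (when absent, all species are
#'   flagged diagnostic).
#' @return data.frame sorted by neutral mass: pep_a, start_a, end_a,
#'   pep_b, start_b, end_b, neutral_mass, one `mz_z<k>` column per charge,
#'   diagnostic.
#' @export
enumerate_diagnostic_crosslinks <- function(digest_a, digest_b,
                                            positions_a, positions_b,
                                            charges = 1:4,
                                            wildtype_a = NULL, wildtype_b = NULL) {
  stopifnot(nrow(digest_a) > 0, nrow(digest_b) > 0)
  covering <- function(dg, pos) {
    hit <- rep(FALSE, nrow(dg))
    for (p in pos) hit <- hit | (dg$start <= p & dg$end >= p)
    dg[hit & grepl("C", dg$sequence, fixed = TRUE), , drop = FALSE]
  }
  fa <- covering(digest_a, positions_a)
  fb <- covering(digest_b, positions_b)
  empty <- data.frame(pep_a = character(), start_a = integer(), end_a = integer(),
                      pep_b = character(), start_b = integer(), end_b = integer(),
                      neutral_mass = numeric(), diagnostic = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(fa) == 0L || nrow(fb) == 0L) return(empty)
  idx <- expand.grid(i = seq_len(nrow(fa)), j = seq_len(nrow(fb)))
  out <- data.frame(
    pep_a = fa$sequence[idx$i], start_a = fa$start[idx$i], end_a = fa$end[idx$i],
    pep_b = fb$sequence[idx$j], start_b = fb$start[idx$j], end_b = fb$end[idx$j],
    neutral_mass = fa$mass[idx$i] + fb$mass[idx$j] + mass_constants$disulfide_delta,
    stringsAsFactors = FALSE
  )
  seen_a <- if (is.null(wildtype_a)) character() else wildtype_a$sequence
  seen_b <- if (is.null(wildtype_b)) character() else wildtype_b$sequence
  out$diagnostic <- !(out$pep_a %in% seen_a) & !(out$pep_b %in% seen_b)
  for (z in charges) out[[paste0("mz_z", z)]] <- mz_for_charge(out$neutral_mass, z)
  out <- out[order(out$neutral_mass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match observed peaks against predicted crosslink species
#'
#' Compares an observed (m/z, charge) peak list against the predicted m/z
#' ladder of crosslink species using a symmetric ppm tolerance at the same
#' charge state. Each match reports the signed ppm error
#' `(observed - predicted) / predicted * 1e6`.
#'
#' @param species output of [enumerate_diagnostic_crosslinks()].
#' @param observed data.frame with columns `mz` and `z`.
#' @param tol_ppm tolerance in parts per million (default 10, typical for
#'   an Orbitrap survey scan).
#' @return data.frame of matches: observed mz/z, pep_a, pep_b,
#'   predicted_mz, ppm_error.
#' @export
match_observed_peaks <- function(species, observed, tol_ppm = 10) {
  stopifnot(tol_ppm > 0, all(c("mz", "z") %in% names(observed)))
  out <- list()
  for (k in seq_len(nrow(observed))) {
    z <- observed$z[k]
    col <- paste0("mz_z", z)
    if (!col %in% names(species)) next
    pred <- species[[col]]
    ppm <- (observed$mz[k] - pred) / pred * 1e6
    hit <- which(abs(ppm) <= tol_ppm)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        mz = observed$mz[k], z = z,
        pep_a = species$pep_a[hit], pep_b = species$pep_b[hit],
        predicted_mz = pred[hit], ppm_error = ppm[hit],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mz = numeric(), z = integer(), pep_a = character(),
                      pep_b = character(), predicted_mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
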