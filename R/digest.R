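#' Protease cleavage rules
#'
#' A `protease_rule` describes a site-specific endoproteinase by either a
#' C-terminal rule (`cleave_after`: cut after any residue in the set,
#' unless the next residue is in `blocked_by_next`) or an N-terminal rule
#' (`cleave_before`: cut before any residue in the set). Exactly one of
#' the two must be given.
#'
#' `protease()` returns a named preset:
#' \describe{
#'   \item{`trypsin`}{cuts after K or R, blocked by a following proline
#'     (the Keil rule; pass `proline_rule = FALSE` to disable).}
#'   \item{`aspn_d`}{endoproteinase Asp-N, vendor definition: cuts before D.}
#'   \item{`aspn_de`}{Asp-N with the broadened specificity some
#'     preparations show: cuts before D or E.}
#' }
#'
#' @param name rule name.
#' @param cleave_after,cleave_before character vectors of one-letter codes.
#' @param blocked_by_next residues that suppress a C-terminal cut when they
#'   follow the site (only meaningful with `cleave_after`).
#' @export
protease_rule <- function(name, cleave_after = NULL, cleave_before = NULL,
                          blocked_by_next = character()) {
  if (is.null(cleave_after) == is.null(cleave_before)) {
    stop("exactly one of cleave_after / cleave_before must be given", call. = FALSE)
  }
  structure(list(name = name, cleave_after = cleave_after,
                 cleave_before = cleave_before,
                 blocked_by_next = blocked_by_next),
            class = "ProteaseRule")
}

#' @rdname protease_rule
#' @param preset one of `"trypsin"`, `"aspn_d"`, `"aspn_de"`.
#' @param proline_rule for trypsin: suppress cleavage before proline.
#' @export
protease <- function(preset, proline_rule = TRUE) {
  switch(tolower(preset),
    trypsin = protease_rule("trypsin", cleave_after = c("K", "R"),
                            blocked_by_next = if (proline_rule) "P" else character()),
    aspn_d = protease_rule("aspn_d", cleave_before = "D"),
    aspn_de = protease_rule("aspn_de", cleave_before = c("D", "E")),
    stop("unknown protease preset: ", preset, call. = FALSE)
  )
}

#' Cleavage sites of a rule on a sequence
#'
#' Returns the cut points as integer positions i meaning "cut between
#' residue i and residue i+1" (so sites lie in 1..n-1; sequence ends are
#' never sites).
#'
#' @param sequence one-letter amino-acid string.
#' @param rule a [protease_rule()] or a list of them (site union).
#' @export
cleavage_sites <- function(sequence, rule) {
  res <- check_peptide_sequence(sequence)
  n <- length(res)
  if (n < 2L) return(integer())
  rules <- if (inherits(rule, "ProteaseRule")) list(rule) else rule
  sites <- integer()
  for (r in rules) {
    stopifnot(inherits(r, "ProteaseRule"))
    if (!is.null(r$cleave_after)) {
      s <- which(res[-n] %in% r$cleave_after)
      if (length(r$blocked_by_next)) s <- s[!(res[s + 1L] %in% r$blocked_by_next)]
    } else {
      s <- which(res[-1L] %in% r$cleave_before)  # cut before position s+1
    }
    sites <- union(sites, s)
  }
  sort(sites)
}

fragments_from_sites <- function(sequence, sites, max_missed) {
  n <- nchar(sequence)
  bounds <- c(0L, sites, n)
  k <- length(bounds)
  out <- list()
  for (i in seq_len(k - 1L)) {
    jmax <- min(k, i + 1L + max_missed)
    for (j in (i + 1L):jmax) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      out[[length(out) + 1L]] <- c(start, end, j - i - 1L)
    }
  }
  m <- do.call(rbind, out)
  seqs <- substring(sequence, m[, 1], m[, 2])
  data.frame(
    sequence = seqs, start = m[, 1], end = m[, 2], missed = m[, 3],
    mass = vapply(seqs, peptide_monoisotopic_mass, numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' In-silico proteolytic digestion
#'
#' Enumerates the peptides produced by digesting `sequence` with one
#' protease (`digest()`) or with several applied jointly
#' (`sequential_digest()`: the cut-site union, modelling a sequential
#' trypsin-then-Asp-N workflow where every site of either enzyme ends up
#' cut). Fragments are enumerated for 0..`max_missed` missed cleavages;
#' each carries its 1-based inclusive span on the parent sequence, its
#' missed-cleavage count and its neutral monoisotopic mass.
#'
#' @param sequence one-letter amino-acid string.
#' @param rule a [protease_rule()].
#' @param rules list of `protease_rule` objects applied jointly.
#' @param max_missed maximum missed cleavages (default 2, a common
#'   database-search setting).
#' @return data.frame with columns sequence, start, end, missed, mass,
#'   ordered by (start, end).
#' @export
digest <- function(sequence, rule, max_missed = 2) {
  stopifnot(max_missed >= 0)
  sites <- cleavage_sites(sequence, rule)
  f <- fragments_from_sites(sequence, sites, max_missed)
  f[order(f$start, f$end), , drop = FALSE]
}

#' @rdname digest
#' @export
sequential_digest <- function(sequence, rules, max_missed = 2) {
  stopifnot(length(rules) >= 1L)
  if (inherits(rules, "ProteaseRule")) rules <- list(rules)
  sites <- cleavage_sites(sequence, rules)
  f <- fragments_from_sites(sequence, sites, max_missed)
  f[order(f$start, f$end), , drop = FALSE]
}

#' Point mutations in from/position/to notation
#'
#' `parse_mutation()` reads the conventional one-letter notation
#' (`"K321C"`, optionally chain-qualified as `"A:K321C"`) into its parts;
#' `apply_mutations()` applies a set of such mutations to a sequence in
#' construct numbering, refusing to proceed when the stated reference
#' residue does not match the sequence (the standard guard against
#' numbering-offset mistakes).
#'
#' @param spec mutation string, e.g. `"K321C"` or `"B:R360C"`.
#' @return `parse_mutation()`: list with `chain` (may be `NA`), `pos`,
#'   `from`, `to`.
#' @export
parse_mutation <- function(spec) {
  m <- regmatches(spec, regexec("^(?:([^:]+):)?([A-Z])([0-9]+)([A-Z])$", spec))[[1]]
  if (length(m) == 0L) stop("cannot parse mutation spec: ", spec, call. = FALSE)
  list(chain = if (nzchar(m[2])) m[2] else NA_character_,
       pos = as.integer(m[4]), from = m[3], to = m[5])
}

#' @rdname parse_mutation
#' @param sequence one-letter amino-acid string (construct numbering,
#'   position 1 = first residue).
#' @param mutations character vector of mutation specs, or a list of
#'   parsed mutations.
#' @param offset added to each mutation position before indexing into
#'   `sequence` (use when the sequence starts downstream of construct
#'   position 1).
#' @return `apply_mutations()`: the mutated sequence (same length).
#' @export
apply_mutations <- function(sequence, mutations, offset = 0) {
  res <- check_peptide_sequence(sequence)
  muts <- lapply(mutations, function(m) if (is.character(m)) parse_mutation(m) else m)
  for (m in muts) {
    i <- m$pos + offset
    if (i < 1L || i > length(res)) {
      stop(sprintf("mutation %s%d%s: position outside sequence (length %d)",
                   m$from, m$pos, m$to, length(res)), call. = FALSE)
    }
    if (res[i] != m$from) {
      stop(sprintf("mutation %s%d%s: expected %s at position %d but sequence has %s",
                   m$from, m$pos, m$to, m$from, m$pos, res[i]), call. = FALSE)
    }
    if (m$from == m$to) stop("mutation with identical from/to residue", call. = FALSE)
    res[i] <- m$to
  }
  paste(res, collapse = "")
}
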