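# Independent oracles, deliberately implemented differently from the package.

# Brute-force digestion oracle: decide cut points by direct per-position rule
# evaluation, then enumerate every substring whose ends are boundaries and
# whose interior contains at most max_missed cut points.
oracle_digest <- function(sequence, rules, max_missed) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  if (!is.list(rules)) rules <- list(rules)
  is_cut <- function(i) {   # cut between i and i+1?
    if (i < 1 || i >= n) return(FALSE)
    for (r in rules) {
      if (!is.null(r$cleave_after)) {
        if (res[i] %in% r$cleave_after && !(res[i + 1] %in% r$blocked_by_next)) {
          return(TRUE)
        }
      } else {
        if (res[i + 1] %in% r$cleave_before) return(TRUE)
      }
    }
    FALSE
  }
  cuts <- vapply(seq_len(max(0, n - 1)), is_cut, logical(1))
  out <- list()
  for (start in seq_len(n)) {
    if (!(start == 1 || cuts[start - 1])) next
    for (end in start:n) {
      if (!(end == n || cuts[end])) next
      interior <- if (end > start) sum(cuts[start:(end - 1)]) else 0L
      if (interior <= max_missed) {
        out[[length(out) + 1L]] <- data.frame(
          sequence = paste(res[start:end], collapse = ""),
          start = start, end = end, missed = interior,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Brute-force screen oracle: double loop over residues, get_cb per residue.
oracle_screen <- function(closed, open, chain_i, chain_j, closed_max, open_min) {
  ri <- residues(closed, chain_i)
  rj <- residues(closed, chain_j)
  out <- list()
  for (a in seq_len(nrow(ri))) for (b in seq_len(nrow(rj))) {
    d_cl <- tryCatch(cb_distance(closed, chain_i, ri$resnum[a], chain_j, rj$resnum[b]),
                     error = function(e) NA_real_)
    d_op <- tryCatch(cb_distance(open, chain_i, ri$resnum[a], chain_j, rj$resnum[b]),
                     error = function(e) NA_real_)
    if (is.na(d_cl) || is.na(d_op)) next
    out[[length(out) + 1L]] <- data.frame(
      res_i = ri$resnum[a], res_j = rj$resnum[b],
      d_closed = d_cl, d_open = d_op,
      candidate = d_cl <= closed_max && d_op >= open_min
    )
  }
  do.call(rbind, out)
}

# random peptide sequence (uniform over the 20 standard residues)
random_peptide <- function(n) {
  paste(sample(names(sslock::aa_monoisotopic), n, replace = TRUE), collapse = "")
}

# hand-built single-residue PDB lines for parser tests
pdb_atom_line <- function(serial, atom, resname, chain, resnum, x, y, z,
                          altloc = " ", occ = 1, icode = " ", element = NULL) {
  if (is.null(element)) element <- substr(atom, 1, 1)
  pad <- if (nchar(atom) >= 4) substr(atom, 1, 4) else sprintf(" %-3s", atom)
  sprintf("ATOM  %5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, pad, altloc, resname, chain, resnum, icode, x, y, z, occ, 0,
          element)
}
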