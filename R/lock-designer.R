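#' C-beta/C-beta distance between two residues
#'
#' Euclidean distance in angstrom between the C-beta atoms of two residues
#' of one conformational state. This is the screening metric for disulfide
#' engineering: residue pairs whose C-beta atoms sit within bonding range
#' in one state but far apart in the other are candidates for a
#' conformation-locking S-S bond. Symmetric in its arguments; full
#' precision is returned (round for display).
#'
#' @param model a [StructureModel][parse_pdb] for one state.
#' @param chain_i,resnum_i,chain_j,resnum_j residue identities.
#' @param icode_i,icode_j insertion codes ("" for none).
#' @param use_virtual_cb construct virtual C-beta for glycine (see [get_cb()]).
#' @return distance in angstrom.
#' @export
cb_distance <- function(model, chain_i, resnum_i, chain_j, resnum_j,
                        icode_i = "", icode_j = "", use_virtual_cb = FALSE) {
  a <- get_cb(model, chain_i, resnum_i, icode_i, use_virtual_cb)
  b <- get_cb(model, chain_j, resnum_j, icode_j, use_virtual_cb)
  sqrt(sum((a - b)^2))
}

#' Two-state conformer pair
#'
#' Bundles the two endpoint structures of a conformational transition with
#' a chain correspondence (closed-state chain id -> open-state chain id;
#' identity by default).
#'
#' @param closed,open `StructureModel` objects for the two states.
#' @param chain_map named character vector mapping closed chain ids to open
#'   chain ids; defaults to identity over the closed model's chains.
#' @export
conformer_pair <- function(closed, open, chain_map = NULL) {
  stopifnot(inherits(closed, "StructureModel"), inherits(open, "StructureModel"))
  if (is.null(chain_map)) {
    ch <- chains(closed)
    chain_map <- stats::setNames(ch, ch)
  }
  structure(list(closed = closed, open = open, chain_map = chain_map),
            class = "ConformerPair")
}

#' Screening configuration
#'
#' Thresholds for the two-state C-beta screen. Defaults (12 angstrom
#' maximum in the closed state, 20 angstrom minimum in the open state)
#' bracket the distances of known conformation-locking pairs in the
#' integrin alphaIIb-beta3 headpiece (7.7 and 11.7 angstrom closed, 32.6
#' and 38.7 angstrom open).
#'
#' @param closed_max candidate pairs must be at most this far apart in the
#'   closed state (angstrom).
#' @param open_min and at least this far apart in the open state (angstrom).
#' @param use_virtual_cb pass-through to [get_cb()] for glycines.
#' @param include_intra also scan residue pairs within one chain (off by
#'   default: conformation locks are usually engineered across subunits).
#' @export
screen_config <- function(closed_max = 12, open_min = 20,
                          use_virtual_cb = FALSE, include_intra = FALSE) {
  stopifnot(closed_max > 0, open_min > closed_max)
  structure(list(closed_max = closed_max, open_min = open_min,
                 use_virtual_cb = use_virtual_cb, include_intra = include_intra),
            class = "ScreenConfig")
}

# C-beta coordinates for every residue of one chain, NA rows when missing
chain_cb_table <- function(model, chain, use_virtual_cb) {
  r <- residues(model, chain)
  if (nrow(r) == 0L) {
    r$x <- numeric(0); r$y <- numeric(0); r$z <- numeric(0)
    return(r)
  }
  xyz <- t(vapply(seq_len(nrow(r)), function(i) {
    tryCatch(get_cb(model, r$chain[i], r$resnum[i], r$icode[i], use_virtual_cb),
             error = function(e) c(NA_real_, NA_real_, NA_real_))
  }, numeric(3)))
  r$x <- xyz[, 1]; r$y <- xyz[, 2]; r$z <- xyz[, 3]
  r
}

#' Screen residue pairs across two conformational states
#'
#' Scans residue pairs between the named chains, measures the
#' C-beta/C-beta distance of each pair in both states, and flags as
#' candidates the pairs that are bondable in the closed state
#' (`d_closed <= closed_max`) and widely separated in the open state
#' (`d_open >= open_min`). Only residues present (with a resolvable
#' C-beta) in both states are scanned; the rest are skipped and counted in
#' the `skipped` attribute, because crystal structures routinely have
#' unmodeled loops. The result is ranked by `delta = d_open - d_closed`
#' descending (the paper-of-record selection logic: maximize the
#' closed/open contrast), ties by `d_closed` ascending, then by residue
#' identity.
#'
#' @param pair a [conformer_pair()].
#' @param chain_pairs list of length-2 character vectors of closed-state
#'   chain ids to scan against each other, e.g. `list(c("A", "B"))`.
#' @param config a [screen_config()].
#' @return data.frame with columns chain_i, res_i, name_i, chain_j, res_j,
#'   name_j, d_closed, d_open, delta, candidate; attribute `skipped` counts
#'   residues absent from one state.
#' @export
screen_interface_pairs <- function(pair, chain_pairs, config = screen_config()) {
  stopifnot(inherits(pair, "ConformerPair"), inherits(config, "ScreenConfig"))
  if (length(chain_pairs) == 0L) stop("chain_pairs must be non-empty", call. = FALSE)
  if (!is.list(chain_pairs)) chain_pairs <- list(chain_pairs)

  res <- list()
  skipped <- 0L
  for (cp in chain_pairs) {
    ci <- cp[[1]]; cj <- cp[[2]]
    if (!config$include_intra && ci == cj) {
      stop("intra-chain scan requested without include_intra", call. = FALSE)
    }
    tabs <- lapply(c(ci, cj), function(ch) {
      cl <- chain_cb_table(pair$closed, ch, config$use_virtual_cb)
      if (!ch %in% names(pair$chain_map)) {
        stop("chain '", ch, "' missing from chain correspondence", call. = FALSE)
      }
      op <- chain_cb_table(pair$open, pair$chain_map[[ch]], config$use_virtual_cb)
      key_cl <- paste(cl$resnum, cl$icode)
      key_op <- paste(op$resnum, op$icode)
      common <- key_cl %in% key_op
      ok <- common & !is.na(cl$x)
      m <- merge(cl[ok, ], op[!is.na(op$x), c("resnum", "icode", "x", "y", "z")],
                 by = c("resnum", "icode"), suffixes = c("_cl", "_op"))
      skipped <<- skipped + (nrow(cl) - nrow(m))
      m[order(m$resnum, m$icode), , drop = FALSE]
    })
    ti <- tabs[[1]]; tj <- tabs[[2]]
    if (nrow(ti) == 0L || nrow(tj) == 0L) {
      stop("no common residues with C-beta between states for chains ",
           ci, "/", cj, call. = FALSE)
    }
    idx <- expand.grid(i = seq_len(nrow(ti)), j = seq_len(nrow(tj)))
    if (ci == cj) idx <- idx[idx$i < idx$j, , drop = FALSE]
    d_cl <- sqrt((ti$x_cl[idx$i] - tj$x_cl[idx$j])^2 +
                 (ti$y_cl[idx$i] - tj$y_cl[idx$j])^2 +
                 (ti$z_cl[idx$i] - tj$z_cl[idx$j])^2)
    d_op <- sqrt((ti$x_op[idx$i] - tj$x_op[idx$j])^2 +
                 (ti$y_op[idx$i] - tj$y_op[idx$j])^2 +
                 (ti$z_op[idx$i] - tj$z_op[idx$j])^2)
    res[[length(res) + 1L]] <- data.frame(
      chain_i = ci, res_i = ti$resnum[idx$i], icode_i = ti$icode[idx$i],
      name_i = ti$resname[idx$i],
      chain_j = cj, res_j = tj$resnum[idx$j], icode_j = tj$icode[idx$j],
      name_j = tj$resname[idx$j],
      d_closed = d_cl, d_open = d_op, delta = d_op - d_cl,
      candidate = d_cl <= config$closed_max & d_op >= config$open_min,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  out <- out[order(-out$delta, out$d_closed, out$chain_i, out$res_i,
                   out$chain_j, out$res_j, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "config") <- config
  out
}

# backbone atoms never count as side-chain polar atoms
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Detect polar side-chain contacts between two residues
#'
#' Lists all side-chain nitrogen/oxygen atom pairs of two residues within
#' a distance cutoff. A contact is typed `salt-bridge` when one residue is
#' basic (Lys/Arg, contributing a side-chain N) and the other acidic
#' (Asp/Glu, contributing a side-chain O); every other polar pair is an
#' `h-bond-candidate`. Useful for confirming that a screened pair sits on
#' an existing polar interaction (e.g. an interface salt bridge) in the
#' closed state.
#'
#' @param model a `StructureModel`.
#' @param chain_i,resnum_i,chain_j,resnum_j residue identities.
#' @param cutoff maximum heavy-atom distance, angstrom.
#' @param icode_i,icode_j insertion codes.
#' @return data.frame (possibly 0-row) with atom_i, atom_j, distance,
#'   contact_type.
#' @export
detect_polar_contacts <- function(model, chain_i, resnum_i, chain_j, resnum_j,
                                  cutoff = 4.0, icode_i = "", icode_j = "") {
  ra <- residue_atoms(model, chain_i, resnum_i, icode_i)
  rb <- residue_atoms(model, chain_j, resnum_j, icode_j)
  if (nrow(ra) == 0L || nrow(rb) == 0L) {
    stop("residue not found for polar-contact detection", call. = FALSE)
  }
  side_no <- function(r) r[r$element %in% c("N", "O") & !(r$atom %in% BACKBONE_ATOMS), ,
                           drop = FALSE]
  sa <- side_no(ra); sb <- side_no(rb)
  out <- data.frame(atom_i = character(), atom_j = character(),
                    distance = numeric(), contact_type = character(),
                    stringsAsFactors = FALSE)
  if (nrow(sa) == 0L || nrow(sb) == 0L) return(out)
  basic <- c("LYS", "ARG"); acidic <- c("ASP", "GLU")
  sb_pair <- (ra$resname[1] %in% basic && rb$resname[1] %in% acidic) ||
    (ra$resname[1] %in% acidic && rb$resname[1] %in% basic)
  for (i in seq_len(nrow(sa))) {
    d <- sqrt((sa$x[i] - sb$x)^2 + (sa$y[i] - sb$y)^2 + (sa$z[i] - sb$z)^2)
    hit <- which(d <= cutoff)
    if (length(hit)) {
      ion_pair <- sb_pair &
        ((sa$element[i] == "N" & sb$element[hit] == "O") |
         (sa$element[i] == "O" & sb$element[hit] == "N"))
      out <- rbind(out, data.frame(
        atom_i = sa$atom[i], atom_j = sb$atom[hit], distance = d[hit],
        contact_type = ifelse(ion_pair, "salt-bridge", "h-bond-candidate"),
        stringsAsFactors = FALSE
      ))
    }
  }
  rownames(out) <- NULL
  out[order(out$distance), , drop = FALSE]
}
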