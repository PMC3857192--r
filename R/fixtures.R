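#' Synthetic two-state hinge structure pair
#'
#' Generates a toy two-chain complex in PDB text form in two
#' conformational states: chain A is fixed and chain B is rigidly rotated
#' about a hinge axis (the z axis through the origin) by
#' `hinge_angle_deg`, emulating a domain swing-out. Residues are
#' poly-alanine-like (N, CA, C, O, CB), laid out so that exactly one
#' inter-chain pair — residue 1 of chain A against residue 1 of chain B,
#' 8 angstrom apart in the closed state — can pass the default screen
#' thresholds; all other pairs are at least 15 angstrom apart in the
#' closed state. For hinge angles of at least 30 degrees the engineered
#' pair's open-state separation exceeds the default 20 angstrom minimum,
#' so the screen reports exactly that one candidate. The stored
#' `true_d_open` is the analytic rotated distance
#' `sqrt(1250 (1 - cos t) + 400 sin t + 64)`.
#'
#' Small per-residue z jitter (drawn from the seeded generator) decorates
#' the non-engineered residues so repeated seeds give distinct but
#' deterministic fixtures; the engineered pair is jitter-free. The seed is
#' recorded in a REMARK header of the emitted PDB text.
#'
#' @param n_res_per_chain residues per chain (>= 5).
#' @param hinge_angle_deg hinge rotation in degrees, in (0, 180).
#' @param seed integer seed.
#' @return list of class `ToyTwoState`: `closed_pdb_text`,
#'   `open_pdb_text` (character vectors of PDB lines), `engineered_pair`
#'   (chain/resnum for both residues), `true_d_closed`, `true_d_open`,
#'   `seed`.
#' @export
make_two_state_toy <- function(n_res_per_chain = 8, hinge_angle_deg = 60, seed = 1) {
  if (n_res_per_chain < 5) stop("n_res_per_chain must be >= 5", call. = FALSE)
  # 0 is allowed as the degenerate no-motion case (states identical)
  if (hinge_angle_deg < 0 || hinge_angle_deg >= 180) {
    stop("hinge_angle_deg must be in [0, 180)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- n_res_per_chain
  spacing <- 13
  # CB anchor points; chain A runs away from the interface along -y,
  # chain B along +x from the hinge at the origin
  cb_a <- cbind(25, -8 - spacing * (seq_len(n) - 1), 0)
  cb_b <- cbind(25 + spacing * (seq_len(n) - 1), 0, 0)
  jitter_a <- c(0, stats::runif(n - 1, -0.3, 0.3))
  jitter_b <- c(0, stats::runif(n - 1, -0.3, 0.3))
  cb_a[, 3] <- cb_a[, 3] + jitter_a
  cb_b[, 3] <- cb_b[, 3] + jitter_b

  theta <- hinge_angle_deg * pi / 180
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)

  atoms_for_chain <- function(cb, chain) {
    # fixed offsets from CB giving plausible bond lengths; rigid per residue
    offs <- list(
      N = c(-0.575, 2.135, 0.885), CA = c(0.885, 0.885, 0.885),
      C = c(1.645, 2.205, 0.885), O = c(2.245, 3.265, 0.885),
      CB = c(0, 0, 0)
    )
    out <- list()
    for (i in seq_len(nrow(cb))) {
      for (nm in names(offs)) {
        out[[length(out) + 1L]] <- data.frame(
          chain = chain, resnum = i, icode = "", resname = "ALA", atom = nm,
          x = cb[i, 1] + offs[[nm]][1], y = cb[i, 2] + offs[[nm]][2],
          z = cb[i, 3] + offs[[nm]][3],
          occupancy = 1, element = substr(nm, 1, 1), stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, out)
  }

  a_atoms <- atoms_for_chain(cb_a, "A")
  b_atoms_closed <- atoms_for_chain(cb_b, "B")
  b_atoms_open <- b_atoms_closed
  xyz <- as.matrix(b_atoms_open[, c("x", "y", "z")]) %*% t(rot)
  b_atoms_open$x <- xyz[, 1]; b_atoms_open$y <- xyz[, 2]; b_atoms_open$z <- xyz[, 3]

  as_model <- function(atoms, label) {
    structure(list(label = label, source = "synthetic", atoms = atoms,
                   counts = c(seen = nrow(atoms), kept = nrow(atoms),
                              malformed = 0L, nonstandard = 0L)),
              class = "StructureModel")
  }
  hdr <- sprintf("REMARK 999 SYNTHETIC TWO-STATE TOY SEED %d HINGE %g", seed,
                 hinge_angle_deg)
  closed_txt <- c(hdr, write_pdb(as_model(rbind(a_atoms, b_atoms_closed), "closed")))
  open_txt <- c(hdr, write_pdb(as_model(rbind(a_atoms, b_atoms_open), "open")))

  true_d_open <- sqrt(1250 * (1 - cos(theta)) + 400 * sin(theta) + 64)
  structure(list(
    closed_pdb_text = closed_txt, open_pdb_text = open_txt,
    engineered_pair = list(chain_i = "A", res_i = 1L, chain_j = "B", res_j = 1L),
    true_d_closed = 8, true_d_open = true_d_open, seed = as.integer(seed)
  ), class = "ToyTwoState")
}

#' Synthetic stand-in for the closed/open integrin headpiece pair
#'
#' A SYNTHETIC two-state structure pair that mimics the geometry of the
#' integrin alphaIIb-beta3 headpiece around the conformation-locking
#' sites: chain A carries a lysine at position 321 (with its side-chain
#' NZ), chain B a glutamate at 358 (OE1/OE2) and an arginine at 360
#' (NH1), plus alanine flankers. Coordinates are constructed so the
#' C-beta/C-beta distances reproduce the published values measured on the
#' crystallographic pair 3FCS/3FCU — 7.7 and 11.7 angstrom closed, 32.6
#' and 38.7 angstrom open — and so the K321 NZ sits 2.9 angstrom from the
#' E358 OE1 (an interface salt bridge) in the closed state. These are NOT
#' crystallographic coordinates: the object exists so the full
#' parse/screen/contact pipeline can be exercised offline; distance
#' "reproduction" on it only demonstrates the machinery, since the
#' distances are construction inputs.
#'
#' @return list with `closed_pdb_text`, `open_pdb_text` (PDB lines) and
#'   `expected`: the construction-target distances.
#' @export
make_integrin_standin <- function() {
  # chain B (beta3-like) fixed in both states; CB(358) at origin, CB(360) at x=6.5
  b_res <- data.frame(
    resnum = 356:362,
    resname = c("ALA", "ALA", "GLU", "ALA", "ARG", "ALA", "ALA"),
    stringsAsFactors = FALSE
  )
  b_res$cbx <- (b_res$resnum - 358) * 3.25
  b_res$cby <- 0

  # chain A (alphaIIb-like): CB(321) placed to satisfy all four distances
  cb321_closed <- c(-2.719, 7.204, 0)
  cb321_open <- c(-30.206, 12.262, 0)
  a_res <- data.frame(
    resnum = 319:323,
    resname = c("ALA", "ALA", "LYS", "ALA", "ALA"),
    stringsAsFactors = FALSE
  )
  a_off <- rbind(c(-12.4, 0), c(-6.2, 0), c(0, 0), c(0, 6.2), c(0, 12.4))
  a_res$cbx <- cb321_closed[1] + a_off[, 1]
  a_res$cby <- cb321_closed[2] + a_off[, 2]

  build_atoms <- function(res, chain, shift = c(0, 0)) {
    offs <- list(N = c(-0.575, 2.135, 0.885), CA = c(0.885, 0.885, 0.885),
                 C = c(1.645, 2.205, 0.885), O = c(2.245, 3.265, 0.885),
                 CB = c(0, 0, 0))
    out <- list()
    for (i in seq_len(nrow(res))) {
      cb <- c(res$cbx[i] + shift[1], res$cby[i] + shift[2], 0)
      for (nm in names(offs)) {
        out[[length(out) + 1L]] <- data.frame(
          chain = chain, resnum = res$resnum[i], icode = "",
          resname = res$resname[i], atom = nm,
          x = cb[1] + offs[[nm]][1], y = cb[2] + offs[[nm]][2],
          z = cb[3] + offs[[nm]][3],
          occupancy = 1, element = substr(nm, 1, 1), stringsAsFactors = FALSE
        )
      }
      extra <- switch(res$resname[i],
        LYS = data.frame(atom = "NZ", dx = 0.764, dy = -2.021, el = "N"),
        GLU = data.frame(atom = c("OE1", "OE2"), dx = c(-0.93, -2.2),
                         dy = c(2.47, 1.9), el = c("O", "O")),
        ARG = data.frame(atom = "NH1", dx = 0.5, dy = -3.0, el = "N"),
        NULL)
      # LYS NZ offset points from CB(321) toward E358 OE1: 2.9 A contact
      if (res$resname[i] == "LYS") { extra$dx <- -1.955 - res$cbx[i]; extra$dy <- 5.183 - res$cby[i] }
      if (!is.null(extra)) {
        for (k in seq_len(nrow(extra))) {
          out[[length(out) + 1L]] <- data.frame(
            chain = chain, resnum = res$resnum[i], icode = "",
            resname = res$resname[i], atom = extra$atom[k],
            x = cb[1] + extra$dx[k], y = cb[2] + extra$dy[k], z = cb[3],
            occupancy = 1, element = extra$el[k], stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, out)
  }

  shift_open <- cb321_open[1:2] - cb321_closed[1:2]
  b_atoms <- build_atoms(b_res, "B")
  closed_atoms <- rbind(build_atoms(a_res, "A"), b_atoms)
  open_atoms <- rbind(build_atoms(a_res, "A", shift = shift_open), b_atoms)

  as_model <- function(atoms, label) {
    structure(list(label = label, source = "synthetic-standin", atoms = atoms,
                   counts = c(seen = nrow(atoms), kept = nrow(atoms),
                              malformed = 0L, nonstandard = 0L)),
              class = "StructureModel")
  }
  hdr <- "REMARK 999 SYNTHETIC STAND-IN (NOT CRYSTALLOGRAPHIC COORDINATES)"
  list(
    closed_pdb_text = c(hdr, write_pdb(as_model(closed_atoms, "closed"))),
    open_pdb_text = c(hdr, write_pdb(as_model(open_atoms, "open"))),
    expected = data.frame(
      res_i = 321L, res_j = c(358L, 360L),
      d_closed = c(7.7, 11.7), d_open = c(32.6, 38.7)
    )
  )
}

#' Synthetic wild-type / cysteine-mutant sequence pair
#'
#' Draws a random protein-like sequence guaranteed to contain tryptic
#' (K/R) and Asp-N (D) sites, then substitutes cysteines at the requested
#' positions to form the mutant. Positions that already hold a cysteine in
#' the wild type are re-drawn deterministically so the mutant differs from
#' the wild type at every requested position.
#'
#' @param template_length sequence length.
#' @param cys_positions positions mutated to C in the mutant.
#' @param seed integer seed.
#' @return list: `wildtype`, `mutant` (sequences), `mutations` (specs like
#'   `"K321C"`), `fasta` (character lines, two records: wt and mut), `seed`.
#' @export
make_mutant_sequences <- function(template_length = 60, cys_positions, seed = 1) {
  stopifnot(template_length >= 10, length(cys_positions) >= 1)
  if (any(cys_positions < 1 | cys_positions > template_length)) {
    stop("cys_positions outside template", call. = FALSE)
  }
  set.seed(as.integer(seed))
  aa <- names(aa_monoisotopic)
  # enrich cleavable residues so both enzymes always find sites
  w <- rep(1, length(aa)); names(w) <- aa
  w[c("K", "R", "D")] <- 3
  repeat {
    res <- sample(aa, template_length, replace = TRUE, prob = w)
    if (!any(res[cys_positions] == "C") &&
        any(res %in% c("K", "R")) && any(res == "D")) break
  }
  wt <- paste(res, collapse = "")
  mres <- res
  mres[cys_positions] <- "C"
  mut <- paste(mres, collapse = "")
  specs <- sprintf("%s%dC", res[cys_positions], cys_positions)
  fasta <- c(sprintf(">wildtype seed=%d", seed), wt,
             sprintf(">mutant seed=%d %s", seed, paste(specs, collapse = ",")), mut)
  list(wildtype = wt, mutant = mut, mutations = specs, fasta = fasta,
       seed = as.integer(seed))
}

#' Synthetic flow-cytometry events
#'
#' Log-normal fluorescence events with a known geometric mean
#' `exp(log_mean)`, for exercising the GMFI/NNFI path.
#'
#' @param n number of events (>= 1).
#' @param log_mean,log_sd log-scale location and spread.
#' @param seed integer seed.
#' @export
make_flow_events <- function(n, log_mean, log_sd, seed = 1) {
  stopifnot(n >= 1, log_sd >= 0)
  set.seed(as.integer(seed))
  stats::rlnorm(n, meanlog = log_mean, sdlog = log_sd)
}

#' Synthetic filled-ellipse mask
#'
#' Rasterizes a filled ellipse with semi-axes `a_px` (minor) and `b_px`
#' (major), rotated by `angle_deg`, centred in a `size` x `size` logical
#' matrix. Ground truth for the moments-based ellipse fit: the fitted
#' form factor should recover `b_px / a_px`.
#'
#' @param a_px,b_px semi-axis lengths in pixels (>= 3).
#' @param angle_deg rotation of the b axis against the row axis.
#' @param size matrix edge length; defaults to fit the ellipse with margin.
#' @export
make_ellipse_mask <- function(a_px, b_px, angle_deg = 0,
                              size = 2 * ceiling(max(a_px, b_px)) + 11) {
  stopifnot(a_px >= 3, b_px >= 3)
  ctr <- (size + 1) / 2
  rc <- expand.grid(r = seq_len(size), c = seq_len(size))
  th <- angle_deg * pi / 180
  u <- (rc$r - ctr) * cos(th) + (rc$c - ctr) * sin(th)
  v <- -(rc$r - ctr) * sin(th) + (rc$c - ctr) * cos(th)
  inside <- (u / b_px)^2 + (v / a_px)^2 <= 1
  matrix(inside, size, size)
}
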