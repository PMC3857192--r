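#' Parse fixed-column PDB text into a structure model
#'
#' Reads wwPDB v3.3 fixed-column `ATOM` records into a queryable model of
#' one conformational state. Only the first `MODEL` block is used (a
#' warning is issued when more exist), only `ATOM` records of the 20
#' standard amino acids are retained (`HETATM`, waters and non-standard
#' residues are dropped), and alternate locations are resolved
#' deterministically: for each (residue, atom name) the conformer with the
#' highest occupancy wins, ties broken by the lexicographically smallest
#' altloc identifier. Occupancies outside \[0, 1\] are clamped with a
#' warning. Malformed fixed-column lines are skipped, counted and warned
#' about, never fatal.
#'
#' @param text PDB-format content: a single string or a character vector of
#'   lines.
#' @param label free-text label for the state, e.g. `"closed"` or `"open"`.
#' @param source optional provenance string (file path or accession).
#' @return an object of class `StructureModel`: a list with `label`,
#'   `source`, `atoms` (a data.frame with columns chain, resnum, icode,
#'   resname, atom, x, y, z, occupancy, element) and `counts` (records
#'   seen/kept/skipped).
#' @seealso [read_pdb()], [get_cb()], [write_pdb()]
#' @export
parse_pdb <- function(text, label = "", source = "") {
  stopifnot(is.character(text))
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    text
  }
  if (length(lines) == 0L) stop("empty PDB input", call. = FALSE)

  rec <- substr(lines, 1, 6)
  # first MODEL block only
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1L) {
    warning(sprintf("input %s has %d MODEL blocks; using the first only",
                    if (nzchar(source)) source else "<text>", length(model_starts)))
    endmdl <- which(trimws(rec) == "ENDMDL")
    end1 <- endmdl[endmdl > model_starts[1]][1]
    if (!is.na(end1)) lines <- lines[seq_len(end1)]
    rec <- substr(lines, 1, 6)
  }

  is_atom <- rec == "ATOM  "
  n_seen <- sum(is_atom)
  if (n_seen == 0L) {
    stop("no ATOM records in PDB input",
         if (nzchar(source)) paste0(" (", source, ")") else "", call. = FALSE)
  }
  al <- lines[is_atom]

  field <- function(from, to) substr(al, from, to)
  atom <- trimws(field(13, 16))
  altloc <- field(17, 17)
  resname <- trimws(field(18, 20))
  chain <- field(22, 22)
  resnum <- suppressWarnings(as.integer(field(23, 26)))
  icode <- trimws(field(27, 27))
  x <- suppressWarnings(as.numeric(field(31, 38)))
  y <- suppressWarnings(as.numeric(field(39, 46)))
  z <- suppressWarnings(as.numeric(field(47, 54)))
  occupancy <- suppressWarnings(as.numeric(field(55, 60)))
  occupancy[is.na(occupancy)] <- 1
  element <- trimws(field(77, 78))
  no_el <- !nzchar(element)
  element[no_el] <- substr(gsub("[^A-Za-z].*$", "", atom[no_el]), 1, 1)

  malformed <- is.na(resnum) | is.na(x) | is.na(y) | is.na(z) |
    !is.finite(x) | !is.finite(y) | !is.finite(z) | !nzchar(atom)
  if (any(malformed)) {
    warning(sprintf("skipped %d malformed ATOM line(s)", sum(malformed)))
  }
  keep <- !malformed & is_standard_resname(resname)
  n_nonstd <- sum(!malformed & !is_standard_resname(resname))

  df <- data.frame(
    chain = chain[keep], resnum = resnum[keep], icode = icode[keep],
    resname = resname[keep], atom = atom[keep], altloc = altloc[keep],
    x = x[keep], y = y[keep], z = z[keep], occupancy = occupancy[keep],
    element = element[keep], stringsAsFactors = FALSE
  )
  if (nrow(df) == 0L) {
    stop("no ATOM records of standard residues in PDB input",
         if (nzchar(source)) paste0(" (", source, ")") else "", call. = FALSE)
  }

  oob <- df$occupancy < 0 | df$occupancy > 1
  if (any(oob)) {
    warning(sprintf("clamped %d occupancy value(s) outside [0,1]", sum(oob)))
    df$occupancy <- pmin(pmax(df$occupancy, 0), 1)
  }

  # altloc resolution: highest occupancy, tie -> smallest altloc id
  key <- paste(df$chain, df$resnum, df$icode, df$atom, sep = "\r")
  ord <- order(key, -df$occupancy, df$altloc, method = "radix")
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df$altloc <- NULL

  # stable residue ordering: chain, then (resnum, icode)
  df <- df[order(df$chain, df$resnum, df$icode, df$atom, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL

  structure(
    list(label = label, source = source, atoms = df,
         counts = c(seen = n_seen, kept = nrow(df),
                    malformed = sum(malformed), nonstandard = n_nonstd)),
    class = "StructureModel"
  )
}

#' Read a PDB file from disk
#'
#' @param path path to a PDB-format file.
#' @param label state label passed to [parse_pdb()].
#' @return a `StructureModel`.
#' @export
read_pdb <- function(path, label = "") {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  parse_pdb(readLines(path, warn = FALSE), label = label, source = path)
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- chains(x)
  cat(sprintf("StructureModel '%s' (%s): %d chain(s), %d residue(s), %d atom(s)\n",
              x$label, if (nzchar(x$source)) x$source else "in-memory",
              length(ch), nrow(residues(x)), nrow(x$atoms)))
  for (c1 in ch) {
    r <- residues(x, c1)
    cat(sprintf("  chain %s: %d residues (%d..%d)\n", c1, nrow(r),
                min(r$resnum), max(r$resnum)))
  }
  invisible(x)
}

#' Chain and residue inventories of a structure model
#'
#' `chains()` returns the chain identifiers in file order; `residues()` the
#' residue table (chain, resnum, icode, resname) of one chain or of the
#' whole model, ordered by (resnum, insertion code).
#'
#' @param model a `StructureModel`.
#' @param chain optional chain id to restrict to.
#' @export
chains <- function(model) unique(model$atoms$chain)

#' @rdname chains
#' @export
residues <- function(model, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain == chain, , drop = FALSE]
  r <- unique(a[, c("chain", "resnum", "icode", "resname")])
  rownames(r) <- NULL
  r
}

# atoms of one residue (icode part of the key)
residue_atoms <- function(model, chain, resnum, icode = "") {
  a <- model$atoms
  a[a$chain == chain & a$resnum == resnum & a$icode == icode, , drop = FALSE]
}

get_atom_xyz <- function(model, chain, resnum, atom, icode = "") {
  ra <- residue_atoms(model, chain, resnum, icode)
  hit <- ra[ra$atom == atom, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  c(hit$x[1], hit$y[1], hit$z[1])
}

#' Virtual C-beta construction from backbone atoms
#'
#' Places an idealized C-beta given the N, CA and C coordinates of a
#' residue, using a 1.532 angstrom CA-CB bond, equal N-CA-CB and C-CA-CB
#' angles of 110.4 degrees, and L-amino-acid chirality. Used for glycine,
#' which has no real C-beta.
#'
#' @param n,ca,c numeric xyz coordinates (angstrom) of the backbone N, CA
#'   and C atoms.
#' @param bond_length CA-CB distance, angstrom.
#' @param angle_deg N-CA-CB (= C-CA-CB) angle, degrees.
#' @return numeric xyz of the virtual C-beta.
#' @export
virtual_cb <- function(n, ca, c, bond_length = 1.532, angle_deg = 110.4) {
  b1 <- n - ca; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c - ca; b2 <- b2 / sqrt(sum(b2^2))
  bis <- b1 + b2
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) stop("degenerate backbone geometry (N, CA, C collinear)", call. = FALSE)
  bis <- bis / nb
  nrm <- c(b1[2] * b2[3] - b1[3] * b2[2],
           b1[3] * b2[1] - b1[1] * b2[3],
           b1[1] * b2[2] - b1[2] * b2[1])
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-8) stop("degenerate backbone geometry (N, CA, C collinear)", call. = FALSE)
  nrm <- nrm / nn
  alpha <- cos(angle_deg * pi / 180) / sum(bis * b1)
  beta <- sqrt(max(0, 1 - alpha^2))
  dir <- alpha * bis + beta * nrm
  # renormalize: keeps |CA-CB| exact even for backbones so distorted that the
  # target angle is geometrically infeasible (then both angles fall short
  # equally); a no-op for realistic N-CA-C angles
  dir <- dir / sqrt(sum(dir^2))
  ca + bond_length * dir
}

#' C-beta coordinate of a residue
#'
#' Returns the C-beta coordinate of a residue. For glycine (no C-beta) a
#' virtual C-beta is constructed from the backbone via [virtual_cb()] when
#' `use_virtual_cb = TRUE`; otherwise a missing C-beta is an error. The
#' virtual option is off by default because the residues this screen was
#' built around (Lys, Glu, Arg) all carry real C-beta atoms.
#'
#' @param model a `StructureModel`.
#' @param chain chain id.
#' @param resnum author residue number.
#' @param icode insertion code ("" for none); part of the residue key.
#' @param use_virtual_cb build a virtual C-beta for residues lacking one.
#' @return numeric xyz (angstrom).
#' @export
get_cb <- function(model, chain, resnum, icode = "", use_virtual_cb = FALSE) {
  ra <- residue_atoms(model, chain, resnum, icode)
  if (nrow(ra) == 0L) {
    stop(sprintf("residue %s:%d%s not found in model '%s'",
                 chain, resnum, icode, model$label), call. = FALSE)
  }
  cb <- ra[ra$atom == "CB", , drop = FALSE]
  if (nrow(cb) >= 1L) return(c(cb$x[1], cb$y[1], cb$z[1]))
  if (!use_virtual_cb) {
    stop(sprintf("residue %s %s:%d%s has no CB atom (enable use_virtual_cb for glycine)",
                 ra$resname[1], chain, resnum, icode), call. = FALSE)
  }
  bb <- lapply(c("N", "CA", "C"), function(a) {
    h <- ra[ra$atom == a, , drop = FALSE]
    if (nrow(h) == 0L) {
      stop(sprintf("residue %s:%d%s lacks backbone atom %s needed for virtual CB",
                   chain, resnum, icode, a), call. = FALSE)
    }
    c(h$x[1], h$y[1], h$z[1])
  })
  virtual_cb(bb[[1]], bb[[2]], bb[[3]])
}

#' Numbering map between construct and file (author) numbering
#'
#' Crystal-structure author numbering and mature-protein construct
#' numbering can differ by a per-chain offset (leader sequences, tags).
#' `numbering_map()` stores one integer offset per chain with
#' author = construct + offset; `map_residue()` applies it and
#' `unmap_residue()` inverts it, so the pair round-trips exactly.
#'
#' @param offsets named integer vector, names are chain ids.
#' @export
numbering_map <- function(offsets) {
  stopifnot(is.numeric(offsets), !is.null(names(offsets)), all(nzchar(names(offsets))))
  structure(list(offsets = stats::setNames(as.integer(offsets), names(offsets))),
            class = "NumberingMap")
}

map_offset <- function(map, chain) {
  stopifnot(inherits(map, "NumberingMap"))
  if (!chain %in% names(map$offsets)) {
    stop("chain '", chain, "' has no offset in the numbering map", call. = FALSE)
  }
  map$offsets[[chain]]
}

#' @rdname numbering_map
#' @param map a `NumberingMap`.
#' @param chain chain id.
#' @param construct_number residue number in construct (mature-protein) numbering.
#' @export
map_residue <- function(map, chain, construct_number) {
  as.integer(construct_number + map_offset(map, chain))
}

#' @rdname numbering_map
#' @param author_number residue number in file (author) numbering.
#' @export
unmap_residue <- function(map, chain, author_number) {
  as.integer(author_number - map_offset(map, chain))
}

#' Serialize a structure model
#'
#' `atom_table()` returns the flat atom table (chain, resnum, icode,
#' resname, atom, x, y, z) for debugging or TSV export; `write_pdb()`
#' renders the model back to strictly valid fixed-column PDB text, so a
#' parse/write/parse round trip preserves the residue and atom inventory
#' and coordinates to 3 decimals.
#'
#' @param model a `StructureModel`.
#' @export
atom_table <- function(model) {
  model$atoms[, c("chain", "resnum", "icode", "resname", "atom", "x", "y", "z")]
}

#' @rdname atom_table
#' @param path optional path; when given, lines are written there.
#' @return `write_pdb()` returns the PDB lines invisibly (or visibly when
#'   `path` is NULL).
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  pad_atom <- function(nm) {
    # atom names of 1-3 chars start in column 14; 4-char names in column 13
    ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  lines <- sprintf(
    "ATOM  %5d %s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), pad_atom(a$atom), " ", a$resname, a$chain, a$resnum,
    ifelse(nzchar(a$icode), a$icode, " "),
    a$x, a$y, a$z, a$occupancy, 0, a$element
  )
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
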