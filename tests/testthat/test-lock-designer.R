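make_cb_model <- function(coords, chain = "A", resname = "ALA") {
  # coords: list of xyz per residue, residue numbers 1..n
  lines <- unlist(lapply(seq_along(coords), function(i) {
    pdb_atom_line(i, "CB", resname, chain, i,
                  coords[[i]][1], coords[[i]][2], coords[[i]][3])
  }))
  parse_pdb(lines)
}

test_that("cb_distance is Euclidean, symmetric and zero on identity", {
  lines <- c(pdb_atom_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "CB", "ALA", "B", 1, 3, 4, 0))
  m <- parse_pdb(lines)
  expect_equal(cb_distance(m, "A", 1, "B", 1), 5)
  expect_identical(cb_distance(m, "A", 1, "B", 1), cb_distance(m, "B", 1, "A", 1))
  expect_equal(cb_distance(m, "A", 1, "A", 1), 0)
})

test_that("screen on toy fixtures equals brute-force enumeration and ranks the engineered pair first", {
  for (seed in c(3, 17, 91)) {
    toy <- make_two_state_toy(n_res_per_chain = 7, hinge_angle_deg = 60, seed = seed)
    cl <- parse_pdb(toy$closed_pdb_text, "closed")
    op <- parse_pdb(toy$open_pdb_text, "open")
    got <- screen_interface_pairs(conformer_pair(cl, op), list(c("A", "B")))
    exp <- oracle_screen(cl, op, "A", "B", 12, 20)

    key <- function(d) paste(d$res_i, d$res_j)
    expect_setequal(key(got), key(exp))
    mexp <- exp[match(key(got), key(exp)), ]
    expect_equal(got$d_closed, mexp$d_closed, tolerance = 1e-9)
    expect_equal(got$d_open, mexp$d_open, tolerance = 1e-9)
    expect_identical(got$candidate, mexp$candidate)
    expect_equal(got$delta, got$d_open - got$d_closed)

    cand <- got[got$candidate, ]
    expect_identical(nrow(cand), 1L)
    expect_identical(cand$res_i, toy$engineered_pair$res_i)
    expect_identical(cand$res_j, toy$engineered_pair$res_j)
    # ranked by delta: the engineered pair tops the whole list on these fixtures
    expect_true(all(diff(got$delta) <= 1e-12))
  }
})

test_that("identical models as both states yield zero candidates", {
  toy <- make_two_state_toy(n_res_per_chain = 6, hinge_angle_deg = 60, seed = 5)
  cl <- parse_pdb(toy$closed_pdb_text)
  got <- screen_interface_pairs(conformer_pair(cl, cl), list(c("A", "B")))
  expect_false(any(got$candidate))
})

test_that("screen metrics are invariant under rigid motion of a whole state", {
  toy <- make_two_state_toy(n_res_per_chain = 6, hinge_angle_deg = 50, seed = 8)
  cl <- parse_pdb(toy$closed_pdb_text)
  op <- parse_pdb(toy$open_pdb_text)
  base <- screen_interface_pairs(conformer_pair(cl, op), list(c("A", "B")))

  set.seed(1)
  ang <- stats::runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3)
  rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
  rot <- rx %*% rz
  shift <- c(12.3, -45.6, 7.89)
  op2 <- op
  xyz <- as.matrix(op$atoms[, c("x", "y", "z")]) %*% t(rot)
  op2$atoms$x <- xyz[, 1] + shift[1]
  op2$atoms$y <- xyz[, 2] + shift[2]
  op2$atoms$z <- xyz[, 3] + shift[3]

  moved <- screen_interface_pairs(conformer_pair(cl, op2), list(c("A", "B")))
  expect_equal(moved$d_open, base$d_open, tolerance = 1e-6)
  expect_equal(moved$d_closed, base$d_closed, tolerance = 1e-6)
  expect_identical(moved$candidate, base$candidate)
})

test_that("threshold monotonicity: looser closed_max / open_min grow the candidate set", {
  toy <- make_two_state_toy(n_res_per_chain = 7, hinge_angle_deg = 70, seed = 21)
  pair <- conformer_pair(parse_pdb(toy$closed_pdb_text), parse_pdb(toy$open_pdb_text))
  key <- function(d) paste(d$res_i, d$res_j)[d$candidate]
  tight <- screen_interface_pairs(pair, list(c("A", "B")), screen_config(12, 20))
  loose_closed <- screen_interface_pairs(pair, list(c("A", "B")), screen_config(18, 20))
  loose_open <- screen_interface_pairs(pair, list(c("A", "B")), screen_config(12, 15))
  expect_true(all(key(tight) %in% key(loose_closed)))
  expect_true(all(key(tight) %in% key(loose_open)))
})

test_that("residues missing from one state are skipped, not fatal", {
  toy <- make_two_state_toy(n_res_per_chain = 6, hinge_angle_deg = 60, seed = 2)
  cl <- parse_pdb(toy$closed_pdb_text)
  op <- parse_pdb(toy$open_pdb_text)
  # unmodeled loop: drop residue 3 of chain B from the open state
  op$atoms <- op$atoms[!(op$atoms$chain == "B" & op$atoms$resnum == 3), ]
  got <- screen_interface_pairs(conformer_pair(cl, op), list(c("A", "B")))
  expect_false(any(got$chain_j == "B" & got$res_j == 3))
  expect_gte(attr(got, "skipped"), 1L)
  # but chains with no overlap at all are an error
  op2 <- op
  op2$atoms <- op2$atoms[op2$atoms$chain == "A", ]
  expect_error(screen_interface_pairs(conformer_pair(cl, op2), list(c("A", "B"))),
               "no common residues")
})

test_that("polar contacts: salt bridges typed and cutoff respected", {
  lines <- c(
    pdb_atom_line(1, "CB", "LYS", "A", 321, 0, 0, 0),
    pdb_atom_line(2, "NZ", "LYS", "A", 321, 0, 3.9, 0),
    pdb_atom_line(3, "CB", "GLU", "B", 358, 0, 8, 0),
    pdb_atom_line(4, "OE1", "GLU", "B", 358, 0, 7.1, 0)
  )
  m <- parse_pdb(lines)
  got <- detect_polar_contacts(m, "A", 321, "B", 358)
  expect_identical(nrow(got), 1L)
  expect_equal(got$distance, 3.2)
  expect_identical(got$contact_type, "salt-bridge")
  expect_identical(got$atom_i, "NZ")

  # all side-chain atoms far apart -> empty, not an error
  far <- c(pdb_atom_line(1, "NZ", "LYS", "A", 1, 0, 0, 0),
           pdb_atom_line(2, "OE1", "GLU", "B", 2, 50, 0, 0))
  expect_identical(nrow(detect_polar_contacts(parse_pdb(far), "A", 1, "B", 2)), 0L)

  # backbone O/N never counts
  bb <- c(pdb_atom_line(1, "O", "ALA", "A", 1, 0, 0, 0),
          pdb_atom_line(2, "N", "ALA", "B", 2, 0, 2.9, 0))
  expect_identical(nrow(detect_polar_contacts(parse_pdb(bb), "A", 1, "B", 2)), 0L)
})

test_that("synthetic integrin stand-in reproduces its construction targets end to end", {
  st <- make_integrin_standin()
  cl <- parse_pdb(st$closed_pdb_text, "closed")
  op <- parse_pdb(st$open_pdb_text, "open")
  got <- screen_interface_pairs(conformer_pair(cl, op), list(c("A", "B")))
  for (k in seq_len(nrow(st$expected))) {
    row <- got[got$res_i == st$expected$res_i[k] & got$res_j == st$expected$res_j[k], ]
    expect_identical(nrow(row), 1L)
    expect_equal(round(row$d_closed, 1), st$expected$d_closed[k])
    expect_equal(round(row$d_open, 1), st$expected$d_open[k])
    expect_true(row$candidate)
  }
  pc <- detect_polar_contacts(cl, "A", 321, "B", 358)
  expect_true(any(pc$contact_type == "salt-bridge"))
})
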