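# residue geometries here are synthetic: coordinates constructed to give
# known charged-atom distances, not taken from any deposited structure

test_that("a minimal synthetic file loads with correct coordinates", {
  atoms <- data.frame(elety = c("NZ", "OE1"), resid = c("LYS", "GLU"),
                      chain = "A", resno = c(1, 2),
                      x = c(0, 3), y = c(0, 0), z = c(0, 0))
  path <- write_synthetic_pdb(atoms)
  mod <- load_structure(path)
  expect_equal(nrow(mod$atoms), 2L)
  expect_equal(mod$atoms$x, c(0, 3))
  expect_equal(mod$atoms$resid, c("LYS", "GLU"))
})

test_that("HETATM-only input without include_het loads nothing, with warning", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "END"), path)
  expect_warning(mod <- load_structure(path), "no atoms")
  expect_equal(nrow(mod$atoms), 0L)
  mod2 <- suppressWarnings(load_structure(path, include_het = TRUE))
  expect_equal(nrow(mod2$atoms), 1L)
})

test_that("coordinates round-trip through the fixed-width format", {
  set.seed(12)
  atoms <- data.frame(elety = "NZ", resid = "LYS", chain = "A",
                      resno = 1:10,
                      x = round(runif(10, -50, 50), 3),
                      y = round(runif(10, -50, 50), 3),
                      z = round(runif(10, -50, 50), 3))
  path <- write_synthetic_pdb(atoms)
  mod <- load_structure(path)
  expect_equal(mod$atoms$x, atoms$x, tolerance = 1e-9)
  expect_equal(mod$atoms$y, atoms$y, tolerance = 1e-9)
  expect_equal(mod$atoms$z, atoms$z, tolerance = 1e-9)
})

test_that("charged-atom minimum distance matches constructed geometry", {
  atoms <- data.frame(
    elety = c("NZ", "OE1", "OE2"), resid = c("LYS", "GLU", "GLU"),
    chain = "A", resno = c(1, 2, 2),
    x = c(0, 3.0, 6.0), y = 0, z = 0)
  mod <- load_structure(write_synthetic_pdb(atoms))
  expect_equal(min_charged_distance(mod, "A:1", "A:2"), 3.0)
  # symmetry in the arguments
  expect_equal(min_charged_distance(mod, "A:2", "A:1"), 3.0)
  expect_error(min_charged_distance(mod, "A:1", "A:9"), "not found")
})

test_that("distance equals the brute-force all-pair minimum on random residues", {
  set.seed(77)
  for (i in 1:10) {
    na <- sample(1:3, 1); nb <- sample(1:2, 1)
    atoms <- data.frame(
      elety = c(c("NE", "NH1", "NH2")[1:na], c("OD1", "OD2")[1:nb]),
      resid = c(rep("ARG", na), rep("ASP", nb)),
      chain = "A", resno = c(rep(1, na), rep(2, nb)),
      x = round(runif(na + nb, -10, 10), 3),
      y = round(runif(na + nb, -10, 10), 3),
      z = round(runif(na + nb, -10, 10), 3))
    mod <- load_structure(write_synthetic_pdb(atoms))
    d <- min_charged_distance(mod, "A:1", "A:2")
    brute <- min(as.matrix(stats::dist(atoms[c("x", "y", "z")]))[1:na,
                 (na + 1):(na + nb)])
    expect_equal(d, brute, tolerance = 1e-9)
  }
})

test_that("distance is invariant under rigid rotation and translation", {
  base <- data.frame(
    elety = c("NZ", "OE1", "OE2"), resid = c("LYS", "GLU", "GLU"),
    chain = "A", resno = c(1, 2, 2),
    x = c(0.512, 3.117, 5.221), y = c(1.2, -0.8, 2.0), z = c(0, 1, -1))
  mod0 <- load_structure(write_synthetic_pdb(base))
  d0 <- min_charged_distance(mod0, "A:1", "A:2")
  set.seed(4)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                   0, -sin(th[1]), cos(th[1])), 3)
    Rz <- matrix(c(cos(th[2]), sin(th[2]), 0, -sin(th[2]), cos(th[2]), 0,
                   0, 0, 1), 3)
    xyz <- as.matrix(base[c("x", "y", "z")]) %*% (Rx %*% Rz) +
      matrix(runif(3, -20, 20), nrow(base), 3, byrow = TRUE)
    rot <- base; rot$x <- round(xyz[, 1], 3); rot$y <- round(xyz[, 2], 3)
    rot$z <- round(xyz[, 3], 3)
    modr <- load_structure(write_synthetic_pdb(rot))
    # PDB coordinates carry 3 decimals, so equality holds to ~2e-3 A
    expect_equal(min_charged_distance(modr, "A:1", "A:2"), d0,
                 tolerance = 2e-3)
  }
})

test_that("salt-bridge classification follows charge and cutoff semantics", {
  mk_pair <- function(d, resb = "GLU", eletyb = "OE1") {
    atoms <- data.frame(
      elety = c("NH1", eletyb), resid = c("ARG", resb), chain = "A",
      resno = c(146, 774), x = c(0, d), y = 0, z = 0)
    load_structure(write_synthetic_pdb(atoms))
  }
  pairs <- list(c("A:146", "A:774"))
  # a 3.0 or 3.2 A Arg-Glu contact is a bridge at the 4.0 A cutoff
  expect_true(classify_salt_bridges(mk_pair(3.0), pairs)$is_salt_bridge)
  expect_true(classify_salt_bridges(mk_pair(3.2), pairs)$is_salt_bridge)
  # broken contacts at 4.5 and 5.7 A are not
  expect_false(classify_salt_bridges(mk_pair(4.5), pairs)$is_salt_bridge)
  expect_false(classify_salt_bridges(mk_pair(5.7), pairs)$is_salt_bridge)
  # like charges never bridge, whatever the distance
  atoms <- data.frame(elety = c("NH1", "NZ"), resid = c("ARG", "LYS"),
                      chain = "A", resno = c(1, 2), x = c(0, 2.8), y = 0,
                      z = 0)
  like <- load_structure(write_synthetic_pdb(atoms))
  r <- classify_salt_bridges(like, list(c("A:1", "A:2")))
  expect_false(r$is_salt_bridge)
  expect_false(r$opposite_charge)
  # uncharged asparagine measures over polar atoms but never bridges
  atoms2 <- data.frame(elety = c("NH1", "OD1"), resid = c("ARG", "ASN"),
                       chain = "A", resno = c(1, 2), x = c(0, 3.0), y = 0,
                       z = 0)
  asn <- load_structure(write_synthetic_pdb(atoms2))
  r2 <- classify_salt_bridges(asn, list(c("A:1", "A:2")))
  expect_equal(r2$min_charged_distance, 3.0)
  expect_false(r2$is_salt_bridge)
})

test_that("lowering the cutoff never creates a bridge", {
  set.seed(9)
  dists <- runif(12, 2.5, 6.5)
  for (d in dists) {
    atoms <- data.frame(elety = c("NZ", "OE1"), resid = c("LYS", "GLU"),
                        chain = "A", resno = c(1, 2),
                        x = c(0, round(d, 3)), y = 0, z = 0)
    mod <- load_structure(write_synthetic_pdb(atoms))
    wide <- classify_salt_bridges(mod, list(c("A:1", "A:2")), cutoff = 4.5)
    tight <- classify_salt_bridges(mod, list(c("A:1", "A:2")), cutoff = 3.5)
    expect_true(wide$is_salt_bridge >= tight$is_salt_bridge)
  }
})
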