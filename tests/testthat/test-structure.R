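test_that("toy structures parse into complete residue records", {
  pdb <- make_toy_structure(3, "ideal_helix", seed = 1)
  atoms <- read_structure(pdb)
  res <- dplyr::count(atoms, chain, resno)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$n >= 4L))  # N, CA, C, O at least
  expect_true(all(atoms$aa %in% severin:::AA_ALPHABET))
})

test_that("waters alone are an empty structure; junk input errors", {
  waters <- paste(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END", sep = "\n")
  expect_error(read_structure(waters), "no standard amino-acid")
  expect_error(read_structure("not a pdb at all\nreally not"),
               "no standard|unparseable")
})

test_that("selenomethionine maps to MET and nonstandard residues warn", {
  base <- make_toy_structure(4, "ideal_helix", seed = 2, aa_seq = "MAMA")
  lines <- strsplit(base, "\n")[[1]]
  lines <- sub("^(ATOM  .{6}.{4} )MET", "\\1MSE", lines)
  lines[grepl("MSE", lines)] <- sub("^ATOM  ", "HETATM",
                                    lines[grepl("MSE", lines)])
  atoms <- read_structure(paste(lines, collapse = "\n"))
  expect_true(all(atoms$resid != "MSE"))
  expect_equal(sort(unique(atoms$aa)), c("A", "M"))

  odd <- sub("ALA", "XYZ", base)
  expect_warning(read_structure(odd), "non-standard")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60 11.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00 10.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.400   0.000  1.00 10.00           C",
    "END")
  atoms <- read_structure(paste(lines, collapse = "\n"))
  n_rows <- atoms[atoms$elety == "N", ]
  expect_equal(nrow(n_rows), 1L)
  expect_equal(n_rows$x, 5.0)
})

test_that("isolated-atom SASA matches the analytic sphere area", {
  a <- single_atom("C")  # r = 1.7
  got <- atom_sasa(a, probe_radius = 1.4, n_points = 960)$sasa
  expect_equal(got, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02)
})

test_that("far-apart atoms do not occlude each other and area grows with probe", {
  two <- dplyr::bind_rows(single_atom("C"), single_atom("C", x = 10))
  got <- atom_sasa(two, probe_radius = 1.4, n_points = 480)$sasa
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(got, c(iso, iso), tolerance = 1e-9)

  a <- single_atom("C")
  s1 <- atom_sasa(a, probe_radius = 1.4, n_points = 480)$sasa
  s2 <- atom_sasa(a, probe_radius = 2.0, n_points = 480)$sasa
  expect_gt(s2, s1)
})

test_that("SASA is invariant to input order and rigid-body motion", {
  b <- toy_bundle(12, seed = 3)
  atoms <- b$atoms
  ref <- atom_sasa(atoms, n_points = 240)$sasa

  perm <- sample(nrow(atoms))
  shuffled <- atom_sasa(atoms[perm, ], n_points = 240)$sasa
  expect_equal(shuffled, ref[perm], tolerance = 1e-6)

  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% R
  moved <- atoms
  moved$x <- xyz[, 1] + 11.3
  moved$y <- xyz[, 2] - 4.2
  moved$z <- xyz[, 3] + 0.5
  expect_equal(atom_sasa(moved, n_points = 240)$sasa, ref,
               tolerance = 1e-6)
})

test_that("residue areas sum to the whole-structure atomic SASA", {
  b <- toy_bundle(12, seed = 3)
  per_res <- compute_surfaces(b$atoms, n_points = 240, ses = "none")
  per_atom <- atom_sasa(b$atoms, n_points = 240)
  expect_equal(sum(per_res$areaSAS), sum(per_atom$sasa), tolerance = 1e-9)
})

test_that("unknown element without a radius override is a configuration error", {
  odd <- single_atom("ZZ")
  expect_error(atom_sasa(odd), "radius")
  expect_silent(atom_sasa(odd, radii = c(ZZ = 2.0), n_points = 96))
})

test_that("planar dihedrals give 0 (cis) and 180 (trans), and mirror negates", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(p1, p2, p3, c(1, 1, 0)), 0)

  set.seed(5)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    a <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    m <- p
    m[, 3] <- -m[, 3]  # mirror through z = 0
    am <- dihedral_angle(m[1, ], m[2, ], m[3, ], m[4, ])
    if (abs(abs(a) - 180) > 1e-8) expect_equal(am, -a, tolerance = 1e-9)
  }
})

test_that("torsions are missing exactly at chain termini", {
  b <- toy_bundle(12, seed = 3)
  tors <- compute_torsions(b$atoms)
  expect_true(is.na(tors$phi[1]))
  expect_true(is.na(tors$psi[nrow(tors)]))
  expect_true(all(!is.na(tors$phi[-1])))
  expect_true(all(!is.na(tors$psi[-nrow(tors)])))
})

test_that("feature records carry hydropathy by residue type and flag join misses", {
  pdb <- make_toy_structure(5, "ideal_helix", seed = 4, aa_seq = "IRAGW")
  atoms <- read_structure(pdb)
  cons <- tibble::tibble(resno = c(1L, 2L, 3L, 4L), conservation = 1:4 / 10)
  feats <- residue_features(atoms, cons, n_points = 96)
  expect_equal(feats$kdHydrophobicity[feats$aa == "I"], 4.5)
  expect_equal(feats$kdHydrophobicity[feats$aa == "R"], -4.5)
  expect_true(is.na(feats$conservation[feats$resno == 5]))

  orphan <- tibble::tibble(resno = c(1L, 99L), conservation = c(0.1, 0.2))
  expect_warning(residue_features(atoms, orphan, n_points = 96),
                 "absent from the structure")
  dup <- tibble::tibble(resno = c(1L, 1L), conservation = c(0.1, 0.2))
  expect_error(residue_features(atoms, dup, n_points = 96), "duplicate")
})

test_that("feature table is sorted and free of NaN leaks", {
  b <- toy_bundle(12, seed = 3)
  f <- b$features
  expect_equal(order(f$chain, f$resno, f$insert), seq_len(nrow(f)))
  num <- vapply(f[, c("areaSAS", "areaSES", "kdHydrophobicity", "PHI",
                      "PSI", "bFactor", "conservation")],
                function(x) all(is.finite(x) | is.na(x)), logical(1))
  expect_true(all(num))
  expect_false(any(vapply(f, function(x) any(is.nan(x)), logical(1))))
  expect_true(all(f$areaSAS >= 0))
})
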