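test_that("generators are pure functions of spec and seed", {
  expect_identical(make_toy_structure(10, "ideal_helix", seed = 4),
                   make_toy_structure(10, "ideal_helix", seed = 4))
  expect_false(identical(make_toy_structure(10, "ideal_helix", seed = 4),
                         make_toy_structure(10, "ideal_helix", seed = 5)))
  expect_identical(make_toy_property_table(12, rank = 3, seed = 2),
                   make_toy_property_table(12, rank = 3, seed = 2))
  expect_identical(make_toy_conservation(15, seed = 3),
                   make_toy_conservation(15, seed = 3))
})

test_that("ideal helix interior torsions hit the canonical angles", {
  atoms <- read_structure(make_toy_structure(20, "ideal_helix", seed = 1))
  tors <- compute_torsions(atoms)
  interior <- tors[2:19, ]
  expect_true(all(abs(interior$phi - (-57)) < 2))
  expect_true(all(abs(interior$psi - (-47)) < 2))
})

test_that("extended chains have no long-range contacts", {
  atoms <- read_structure(make_toy_structure(15, "extended", seed = 2))
  # CA trace: consecutive ~3.8 A, second neighbours far beyond 5 A
  ca <- atoms[atoms$elety == "CA", ]
  d12 <- sqrt(sum((ca[1, c("x", "y", "z")] - ca[2, c("x", "y", "z")])^2))
  d13 <- sqrt(sum((ca[1, c("x", "y", "z")] - ca[3, c("x", "y", "z")])^2))
  expect_equal(d12, 3.8, tolerance = 0.02)
  expect_gt(d13, 5)
  # the full heavy-atom graph keeps only near-neighbour peptide contacts
  rin <- build_rin(atoms)
  el <- igraph::as_edgelist(rin$graph)
  sep <- abs(as.integer(sub("^A:(\\d+):.*", "\\1", paste0(el[, 1], ":"))) -
               as.integer(sub("^A:(\\d+):.*", "\\1", paste0(el[, 2], ":"))))
  expect_true(all(sep <= 2))
})

test_that("structures below 3 residues are refused", {
  expect_error(make_toy_structure(2), "at least 3")
})

test_that("planted low-rank property tables recover their rank", {
  for (r in c(1, 2, 4)) {
    tab <- make_toy_property_table(20, rank = r, seed = r + 10)
    expect_equal(reduce_properties(tab, 0.99)$n_components, r)
  }
})

test_that("duplicated columns do not change standardized distances", {
  tab <- make_toy_property_table(10, seed = 6)
  dup <- tab
  dup$dupcol <- dup[[2]]
  d1 <- aa_distance_index(tab, variance_target = 1.0)
  # with standardization, a duplicated column doubles that axis's
  # weight; distances change deterministically but the metric axioms
  # and ordering of identical pairs are preserved
  d2 <- aa_distance_index(dup, variance_target = 1.0)
  expect_equal(diag(unclass(d2)), rep(0, 20), ignore_attr = TRUE)
  expect_equal(unclass(d2), t(unclass(d2)), ignore_attr = TRUE)
  # the duplicated axis contributes twice the squared coordinate gap
  z <- scale(as.matrix(tab[, -1]))
  gap2 <- outer(z[, 1], z[, 1], "-")^2
  expect_equal(unclass(d2)^2, unclass(d1)^2 + gap2, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("noise-free labels are recoverable by a linear threshold", {
  b <- toy_bundle(50, seed = 21)
  muts <- make_synthetic_mutations(b$features, b$centralities, b$dmat,
                                   n = 200, noise_sd = 0,
                                   severe_fraction = 0.4, seed = 21)
  co <- attr(muts, "coefficients")
  feats <- dplyr::inner_join(
    muts,
    dplyr::inner_join(b$features,
                      dplyr::select(b$centralities, chain, resno, insert,
                                    degree),
                      by = c("chain", "resno", "insert")),
    by = c("position" = "resno")
  )
  eta <- co[["degree"]] * scale(feats$degree)[, 1] +
    co[["conservation"]] * scale(feats$conservation)[, 1] +
    co[["aa_distance"]] * scale(aa_distance(b$dmat, feats$wt_aa,
                                            feats$mut_aa))[, 1]
  # perfect separation by the generating score
  cut <- sort(eta[feats$label == "severe"])[1]
  expect_true(all(eta[feats$label == "mild_moderate"] < cut))
})

test_that("class imbalance matches the requested fraction within rounding", {
  b <- toy_bundle(50, seed = 21)
  muts <- make_synthetic_mutations(b$features, b$centralities, b$dmat,
                                   n = 300, severe_fraction = 1 / 3,
                                   seed = 4)
  expect_equal(sum(muts$label == "severe"), 100L)
  # activities are consistent with the labels
  expect_true(all(muts$activity[muts$label == "severe"] < 1))
  expect_true(all(muts$activity[muts$label == "mild_moderate"] >= 1))
  expect_equal(muts$severity, label_severity(muts$activity))
})

test_that("a different seed changes labels but not the structure tables", {
  b <- toy_bundle(50, seed = 21)
  m1 <- make_synthetic_mutations(b$features, b$centralities, b$dmat,
                                 n = 150, seed = 1)
  m2 <- make_synthetic_mutations(b$features, b$centralities, b$dmat,
                                 n = 150, seed = 2)
  expect_false(identical(m1$label, m2$label))
  expect_identical(b$features, toy_bundle(50, seed = 21)$features)
})

test_that("the demo workspace is complete and internally consistent", {
  dir <- tempfile("demo")
  paths <- make_demo_workspace(dir, n_residues = 30, n_mutations = 80,
                               seed = 2)
  expect_true(all(file.exists(unlist(paths))))
  atoms <- read_structure(paths$structure)
  expect_equal(max(atoms$resno), 30L)
  cons <- read_conservation(paths$conservation)
  expect_equal(nrow(cons), 30L)
  props <- read_property_csv(paths$properties)
  expect_equal(nrow(props), 20L)
  muts <- utils::read.csv(paths$mutations)
  expect_equal(nrow(muts), 80L)
  expect_true(all(muts$position %in% atoms$resno))
})
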