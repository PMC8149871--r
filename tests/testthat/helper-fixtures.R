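# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) {
    assign(key, builder(), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# A small coil structure with features, network and distance index.
toy_bundle <- function(n_residues = 40, seed = 7) {
  key <- sprintf("bundle_%d_%d", n_residues, seed)
  cached(key, function() {
    pdb <- make_toy_structure(n_residues, "random_coil", seed = seed)
    atoms <- read_structure(pdb)
    cons <- make_toy_conservation(n_residues, seed)
    feats <- residue_features(atoms, cons, n_points = 120)
    rin <- build_rin(atoms)
    cent <- rin_centralities(rin)
    dmat <- aa_distance_index(make_toy_property_table(30, seed = seed))
    list(pdb = pdb, atoms = atoms, cons = cons, features = feats,
         rin = rin, centralities = cent, dmat = dmat)
  })
}

# A trained fast-suite ensemble on a strongly separable fixture.
trained_bundle <- function() {
  cached("trained", function() {
    b <- toy_bundle(60, seed = 11)
    muts <- make_synthetic_mutations(b$features, b$centralities, b$dmat,
                                     n = 350, noise_sd = 0.3, seed = 11)
    design <- build_design_matrix(muts, b$features, b$centralities, b$dmat)
    ens <- severity_train(design, model_suite("fast"), folds = 10,
                          seed = 11)
    c(b, list(mutations = muts, design = design, ensemble = ens))
  })
}

single_atom <- function(element = "C", x = 0, y = 0, z = 0) {
  tibble::tibble(chain = "A", resno = 1L, insert = "", resid = "ALA",
                 aa = "A", eleno = 1L, elety = element, element = element,
                 x = x, y = y, z = z, occupancy = 1, b = 0)
}
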