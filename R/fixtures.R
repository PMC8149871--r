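# Seeded generators of toy structures, property tables and labeled
# mutation sets. Everything is a pure function of (spec, seed).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension reference frame: place atom D bonded to C with the
# given internal coordinates relative to the chain A-B-C.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone internal coordinates (Engh-Huber-like averages).
BB_GEOM <- list(
  b_CN = 1.329, b_NCA = 1.458, b_CAC = 1.525, b_CO = 1.231, b_CACB = 1.530,
  a_CACN = 116.2, a_CNCA = 121.7, a_NCAC = 111.2, a_CACO = 120.8
)

toy_torsions <- function(n, geometry, seed) {
  switch(geometry,
    ideal_helix = list(phi = rep(-57, n), psi = rep(-47, n)),
    extended = list(phi = rep(180, n), psi = rep(180, n)),
    random_coil = {
      old_seed <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      on.exit({
        if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      }, add = TRUE)
      set.seed(seed + 7L)
      list(phi = stats::runif(n, -150, -50), psi = stats::runif(n, -60, 160))
    },
    stop("unknown geometry: ", geometry, call. = FALSE)
  )
}

#' Generate a toy protein structure
#'
#' Builds an ideal-geometry backbone (N, CA, C, O, and CB for
#' non-glycine residues) from standard bond lengths and angles with the
#' backbone torsions of the requested conformation: `ideal_helix`
#' (phi = -57, psi = -47), `extended` (phi = psi = 180), or
#' `random_coil` (seeded torsions from the broad allowed region). The
#' output is PDB text parseable by [read_structure()]; identical
#' arguments give identical bytes.
#'
#' @param n_residues Number of residues (>= 3).
#' @param geometry `"ideal_helix"`, `"extended"`, or `"random_coil"`.
#' @param chain Chain identifier.
#' @param seed Integer seed (sequence, B-factors, coil torsions).
#' @param aa_seq Optional one-letter sequence overriding the seeded
#'   random sequence.
#' @return A single string of PDB text.
#' @export
make_toy_structure <- function(n_residues, geometry = "ideal_helix",
                               chain = "A", seed = 1, aa_seq = NULL) {
  if (n_residues < 3L) stop("need at least 3 residues", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  aa <- if (is.null(aa_seq)) {
    sample(AA_ALPHABET, n_residues, replace = TRUE)
  } else {
    strsplit(aa_seq, "")[[1]]
  }
  stopifnot(length(aa) == n_residues)
  assert_aa(aa, "aa_seq")
  bfac <- round(stats::runif(n_residues, 5, 50), 2)
  tors <- toy_torsions(n_residues, geometry, seed)
  g <- BB_GEOM

  N <- CA <- C <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  a0 <- g$a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + g$b_CAC * c(-cos(a0), sin(a0), 0)
  for (i in 2:n_residues) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_CN, g$a_CACN, tors$psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_NCA, g$a_CNCA, 180)  # omega trans
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_CAC, g$a_NCAC, tors$phi[i])
  }
  O <- matrix(NA_real_, n_residues, 3)
  for (i in seq_len(n_residues)) {
    psi_i <- if (i < n_residues) tors$psi[i] else tors$psi[max(i - 1, 1)]
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_CO, g$a_CACO, psi_i - 180)
  }

  one2three <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)
  lines <- character(0)
  serial <- 0L
  fmt <- function(name, resname, resno, xyz, b, element) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, resname, chain, resno, xyz[1], xyz[2], xyz[3],
            1.00, b, element)
  }
  for (i in seq_len(n_residues)) {
    res3 <- one2three[aa[i]]
    lines <- c(lines,
               fmt("N", res3, i, N[i, ], bfac[i], "N"),
               fmt("CA", res3, i, CA[i, ], bfac[i], "C"),
               fmt("C", res3, i, C[i, ], bfac[i], "C"),
               fmt("O", res3, i, O[i, ], bfac[i], "O"))
    if (aa[i] != "G") {
      # standard tetrahedral CB from the N/C/CA frame
      b_v <- CA[i, ] - N[i, ]
      c_v <- C[i, ] - CA[i, ]
      a_v <- cross3(b_v, c_v)
      cb <- -0.58273431 * a_v + 0.56802827 * b_v - 0.54067466 * c_v + CA[i, ]
      lines <- c(lines, fmt("CB", res3, i, cb, bfac[i], "C"))
    }
  }
  paste(c(lines, "TER", "END"), collapse = "\n")
}

#' Generate a toy conservation table
#'
#' Seeded ConSurf-like per-position scores (lower = more conserved),
#' standard-normal marginals.
#'
#' @param n_residues Number of positions (1..n).
#' @param seed Integer seed.
#' @return Tibble with `resno` and `conservation`.
#' @export
make_toy_conservation <- function(n_residues, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed + 13L)
  tibble::tibble(resno = seq_len(n_residues),
                 conservation = round(stats::rnorm(n_residues), 3))
}

#' Generate a toy amino-acid property table
#'
#' Seeded numeric properties for the 20 amino acids; when `rank` is
#' given, the columns are linear combinations of that many orthonormal
#' latent factors, so the planted rank is known exactly.
#'
#' @param n_properties Number of property columns (>= 1).
#' @param rank Optional planted rank (<= min(19, n_properties)).
#' @param seed Integer seed.
#' @return A property table tibble (20 rows).
#' @export
make_toy_property_table <- function(n_properties = 10, rank = NULL,
                                    seed = 1) {
  stopifnot(n_properties >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed + 29L)
  m <- if (is.null(rank)) {
    matrix(stats::rnorm(20 * n_properties), 20, n_properties)
  } else {
    stopifnot(rank >= 1, rank <= min(19, n_properties))
    f <- qr.Q(qr(matrix(stats::rnorm(20 * rank), 20, rank)))
    coef <- stats::runif(n_properties, 0.5, 2) *
      sample(c(-1, 1), n_properties, replace = TRUE)
    factor_of <- rep_len(seq_len(rank), n_properties)
    sweep(f[, factor_of, drop = FALSE], 2, coef, "*")
  }
  colnames(m) <- sprintf("prop%03d", seq_len(n_properties))
  out <- tibble::as_tibble(as.data.frame(m))
  out$aa <- AA_ALPHABET
  new_property_table(dplyr::relocate(out, "aa"))
}

#' Generate a labeled synthetic mutation table
#'
#' Draws mutations at structure positions with complete features and
#' labels them with a logistic model in standardized degree (+),
#' conservation (-) and substitution distance (+), mirroring the
#' empirical directionality of severe variants (buried, connected,
#' conserved positions and dissimilar replacements). The generating
#' coefficients are returned for recovery tests. With
#' `severe_fraction` set, labels are the top quantile of the latent
#' score, so at `noise_sd = 0` the classes are linearly separable and
#' class counts match the requested imbalance within rounding;
#' otherwise labels are Bernoulli draws from the logistic probability.
#'
#' @param features Residue feature tibble.
#' @param centralities Node centrality tibble.
#' @param distance_matrix An `aa_dist` matrix.
#' @param n Number of mutation records.
#' @param coefficients Named numeric: `intercept`, `degree`,
#'   `conservation`, `aa_distance` (on standardized features).
#' @param noise_sd Gaussian noise added to the latent score.
#' @param severe_fraction Optional target fraction of severe labels.
#' @param seed Integer seed.
#' @return Tibble with `position`, `wt_aa`, `mut_aa`, `activity_raw`,
#'   `activity`, `severity`, `label`; attributes `coefficients` and
#'   `noise_sd`. Errors if fewer than 2 records of a class result.
#' @export
make_synthetic_mutations <- function(features, centralities,
                                     distance_matrix, n = 400,
                                     coefficients = c(intercept = 0,
                                                      degree = 1.5,
                                                      conservation = -1.5,
                                                      aa_distance = 1),
                                     noise_sd = 0.5,
                                     severe_fraction = 0.35, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed + 101L)

  struct <- dplyr::inner_join(
    features, dplyr::select(centralities, "chain", "resno", "insert",
                            "degree"),
    by = c("chain", "resno", "insert")
  )
  ok <- !is.na(struct$conservation) & !is.na(struct$degree)
  struct <- struct[ok, , drop = FALSE]
  if (nrow(struct) < 3L) stop("too few usable positions", call. = FALSE)

  pick <- sample.int(nrow(struct), n, replace = TRUE)
  wt <- struct$aa[pick]
  mut <- vapply(wt, function(w) sample(setdiff(AA_ALPHABET, w), 1L),
                character(1))
  z <- function(v) as.numeric(scale(v))
  d <- aa_distance(distance_matrix, wt, mut)
  eta <- coefficients[["intercept"]] +
    coefficients[["degree"]] * z(struct$degree[pick]) +
    coefficients[["conservation"]] * z(struct$conservation[pick]) +
    coefficients[["aa_distance"]] * z(d) +
    stats::rnorm(n, 0, noise_sd)

  severe <- if (!is.null(severe_fraction)) {
    eta >= stats::quantile(eta, 1 - severe_fraction, type = 1)
  } else {
    stats::runif(n) < stats::plogis(eta)
  }
  if (sum(severe) < 2L || sum(!severe) < 2L) {
    stop("degenerate class balance; adjust severe_fraction or coefficients",
         call. = FALSE)
  }

  activity <- ifelse(severe, stats::runif(n, 0, 0.99),
                     stats::runif(n, 1, 40))
  out <- tibble::tibble(
    position = struct$resno[pick],
    wt_aa = wt,
    mut_aa = mut,
    activity_raw = formatC(activity, format = "f", digits = 2),
    activity = round(activity, 2),
    severity = label_severity(round(activity, 2)),
    label = factor(ifelse(severe, "severe", "mild_moderate"),
                   levels = c("mild_moderate", "severe"))
  )
  attr(out, "coefficients") <- coefficients
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Write a complete demo workspace
#'
#' Generates and writes a coherent set of inputs: a toy structure
#' (`structure.pdb`), a conservation table (`conservation.tsv`), a
#' property table (`properties.csv`), and a labeled mutation table
#' (`mutations.csv`), all derived from one seed.
#'
#' @param dir Output directory (created if needed).
#' @param n_residues,n_mutations Sizes.
#' @param geometry Structure conformation.
#' @param seed Integer seed.
#' @param noise_sd,severe_fraction Label-model parameters.
#' @return Named list of file paths, invisibly.
#' @export
make_demo_workspace <- function(dir, n_residues = 60, n_mutations = 400,
                                geometry = "random_coil", seed = 1,
                                noise_sd = 0.5, severe_fraction = 0.35) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    structure = file.path(dir, "structure.pdb"),
    conservation = file.path(dir, "conservation.tsv"),
    properties = file.path(dir, "properties.csv"),
    mutations = file.path(dir, "mutations.csv")
  )
  pdb <- make_toy_structure(n_residues, geometry, seed = seed)
  writeLines(pdb, paths$structure)
  cons <- make_toy_conservation(n_residues, seed)
  utils::write.table(cons, paths$conservation, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  props <- make_toy_property_table(n_properties = 40, seed = seed)
  utils::write.csv(props, paths$properties, row.names = FALSE)

  atoms <- read_structure(paths$structure)
  feats <- residue_features(atoms, cons, n_points = 240)
  rin <- build_rin(atoms)
  cent <- rin_centralities(rin)
  dmat <- aa_distance_index(props)
  muts <- make_synthetic_mutations(feats, cent, dmat, n = n_mutations,
                                   noise_sd = noise_sd,
                                   severe_fraction = severe_fraction,
                                   seed = seed)
  utils::write.csv(muts, paths$mutations, row.names = FALSE)
  invisible(paths)
}
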