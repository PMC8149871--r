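# Structure parsing and per-residue structural features.

#' Read a protein structure into an atom table
#'
#' Parses a PDB file (fixed-column dialect) into one row per heavy atom.
#' Only the first model is used. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically by altloc id).
#' Selenomethionine and a small set of other modified residues are mapped
#' to their standard parents; other non-standard residues and waters are
#' skipped with a warning. Insertion codes are preserved.
#'
#' @param file Path to a PDB file, or a character vector of PDB lines
#'   (anything of length > 1, or containing a newline, is treated as text).
#' @return A tibble with one row per atom: `chain`, `resno`, `insert`,
#'   `resid` (three-letter), `aa` (one-letter), `eleno`, `elety` (atom
#'   name), `element`, `x`, `y`, `z`, `occupancy`, `b`.
#' @export
read_structure <- function(file) {
  path <- file
  if (length(file) > 1L || any(grepl("\n", file, fixed = TRUE))) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(file, "\n", fixed = TRUE)), path)
    on.exit(unlink(path), add = TRUE)
  } else if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stop("unparseable PDB input: ", conditionMessage(e), call. = FALSE)
    }
  )
  at <- tibble::as_tibble(pdb$atom)

  # waters out first, then rescue mapped modified residues from HETATM
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  mapped <- at$resid %in% names(AA_NONSTANDARD_MAP)
  at$resid[mapped] <- unname(AA_NONSTANDARD_MAP[at$resid[mapped]])
  at$type[mapped] <- "ATOM"
  at <- at[at$type == "ATOM", , drop = FALSE]

  nonstd <- !(at$resid %in% names(AA_THREE_TO_ONE))
  if (any(nonstd)) {
    warning("skipping non-standard residues: ",
            paste(unique(at$resid[nonstd]), collapse = ", "), call. = FALSE)
    at <- at[!nonstd, , drop = FALSE]
  }
  if (nrow(at) == 0L) {
    stop("structure contains no standard amino-acid residues", call. = FALSE)
  }

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc: keep, per (residue, atom name), highest occupancy then
  # alphabetically first altloc id
  at <- dplyr::arrange(at, .data$chain, .data$resno, .data$insert,
                       .data$elety, dplyr::desc(.data$o), .data$alt)
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$insert,
                        .data$elety, .keep_all = TRUE)

  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    # fall back on the first letter of the atom name (heavy atoms only)
    element[missing_el] <- substr(gsub("[0-9']", "", at$elety[missing_el]), 1, 1)
  }

  out <- tibble::tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    insert = at$insert,
    resid = at$resid,
    aa = aa_three2one(at$resid),
    eleno = as.integer(at$eleno),
    elety = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o,
    b = at$b
  )
  dplyr::arrange(out, .data$chain, .data$resno, .data$insert, .data$eleno)
}

# Unique residue identifier strings, "chain:resno:insert".
residue_id <- function(chain, resno, insert) {
  paste(chain, resno, ifelse(is.na(insert) | insert == "", "", insert),
        sep = ":")
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Canonical molecular frame (principal axes with skewness-fixed signs),
# so the sphere point template co-rotates with the structure and the
# sampled areas are exactly equivariant under rigid-body motion.
canonical_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  X <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(X), symmetric = TRUE)
  V <- ev$vectors
  for (k in 1:3) {
    s <- sum((X %*% V[, k])^3)
    if (abs(s) > 1e-8 && s < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

atom_radii <- function(atoms, radii = NULL) {
  tab <- VDW_RADII
  if (!is.null(radii)) tab[names(radii)] <- radii
  r <- unname(tab[atoms$element])
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "),
         "; supply them via `radii`", call. = FALSE)
  }
  r
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerically exposes each atom's solvent-accessible sphere (van der
#' Waals radius plus probe radius) with a deterministic quasi-uniform
#' point set and counts points not buried inside any neighbouring
#' atom's solvent sphere.
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Number of test points per atom; more points, finer
#'   area resolution.
#' @param radii Optional named numeric vector overriding or extending the
#'   built-in element radii.
#' @return The atom tibble with an added `sasa` column (Angstrom^2).
#' @export
atom_sasa <- function(atoms, probe_radius = 1.4, n_points = 960, radii = NULL) {
  stopifnot(probe_radius >= 0, n_points >= 12)
  n <- nrow(atoms)
  r <- atom_radii(atoms, radii) + probe_radius
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  pts <- sphere_points(n_points) %*% t(canonical_frame(xyz))
  max_r <- max(r)

  # neighbour prefilter on a coarse grid: two solvent spheres can only
  # intersect if their centres are within the sum of their radii
  cell <- 2 * max_r
  key <- function(m) {
    paste(floor(m[, 1] / cell), floor(m[, 2] / cell), floor(m[, 3] / cell))
  }
  cells <- key(xyz)
  cell_index <- split(seq_len(n), cells)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

  coords_cell <- do.call(rbind, strsplit(names(cell_index), " "))
  storage.mode(coords_cell) <- "integer"

  cell_of_atom <- match(cells, names(cell_index))
  neighbour_cache <- vector("list", length(cell_index))

  area <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cell_of_atom[i]
    nb <- neighbour_cache[[ci]]
    if (is.null(nb)) {
      around <- sweep(offs, 2, coords_cell[ci, ], "+")
      keys <- paste(around[, 1], around[, 2], around[, 3])
      nb <- unlist(cell_index[intersect(keys, names(cell_index))],
                   use.names = FALSE)
      neighbour_cache[[ci]] <- nb
    }
    d2 <- (xyz[nb, 1] - xyz[i, 1])^2 + (xyz[nb, 2] - xyz[i, 2])^2 +
      (xyz[nb, 3] - xyz[i, 3])^2
    close <- nb[nb != i & d2 < (r[nb] + r[i])^2]
    if (length(close) == 0L) {
      area[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in close) {
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | dj2 < r[j]^2
      if (all(buried)) break
    }
    area[i] <- 4 * pi * r[i]^2 * sum(!buried) / n_points
  }
  dplyr::mutate(atoms, sasa = area)
}

#' Per-residue surface areas
#'
#' Sums Shrake-Rupley atomic areas within each residue to give `areaSAS`.
#' `areaSES` (solvent-excluded surface) has no exact re-implementation
#' here: by default it is approximated by re-running the same algorithm
#' with a probe radius of zero (the contact surface over van der Waals
#' spheres), which tracks but does not equal a true molecular surface.
#' A user-supplied backend function can replace the approximation.
#'
#' @inheritParams atom_sasa
#' @param ses One of `"probe0"` (default approximation), `"none"` (report
#'   `areaSES` as `NA`), or a function `f(atoms)` returning a numeric
#'   vector of per-atom areas.
#' @return A tibble with one row per residue: `chain`, `resno`, `insert`,
#'   `aa`, `areaSAS`, `areaSES`.
#' @export
compute_surfaces <- function(atoms, probe_radius = 1.4, n_points = 960,
                             radii = NULL, ses = "probe0") {
  with_sas <- atom_sasa(atoms, probe_radius, n_points, radii)
  ses_area <- if (is.function(ses)) {
    ses(atoms)
  } else if (identical(ses, "probe0")) {
    atom_sasa(atoms, 0, n_points, radii)$sasa
  } else if (identical(ses, "none")) {
    rep(NA_real_, nrow(atoms))
  } else {
    stop("`ses` must be \"probe0\", \"none\", or a function", call. = FALSE)
  }
  with_sas$ses <- ses_area
  dplyr::summarise(
    dplyr::group_by(with_sas, .data$chain, .data$resno, .data$insert,
                    .data$aa),
    areaSAS = sum(.data$sasa),
    areaSES = sum(.data$ses),
    .groups = "drop"
  )
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from the second towards the third atom,
#' clockwise rotation of the far bond is positive. Returns degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Backbone atom coordinates per residue, NA rows where an atom is absent.
backbone_coords <- function(atoms, name) {
  sel <- atoms[atoms$elety == name, c("chain", "resno", "insert", "x", "y", "z")]
  res <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$insert)
  out <- dplyr::left_join(res, sel, by = c("chain", "resno", "insert"))
  as.matrix(out[, c("x", "y", "z")])
}

#' Backbone phi/psi torsion angles
#'
#' Computes the standard backbone dihedrals from consecutive N, CA, C
#' atoms. Torsions are undefined (reported `NA`, never 0) at chain
#' termini and across chain breaks; a break is declared when the peptide
#' C-N distance exceeds `break_cutoff` or a backbone atom is missing
#' (the latter triggers a warning, not an error).
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param break_cutoff Maximum C(i)-N(i+1) distance (Angstrom) still
#'   treated as a peptide bond.
#' @return A tibble with `chain`, `resno`, `insert`, `aa`, `phi`, `psi`
#'   in degrees.
#' @export
compute_torsions <- function(atoms, break_cutoff = 2.5) {
  res <- dplyr::distinct(atoms, .data$chain, .data$resno, .data$insert,
                         .data$aa)
  n <- nrow(res)
  N <- backbone_coords(atoms, "N")
  CA <- backbone_coords(atoms, "CA")
  C <- backbone_coords(atoms, "C")
  if (anyNA(N) || anyNA(CA) || anyNA(C)) {
    warning("missing backbone atoms; affected torsions reported NA",
            call. = FALSE)
  }

  same_chain <- c(FALSE, res$chain[-1] == res$chain[-n])
  dCN <- c(NA_real_, sqrt(rowSums((N[-1, , drop = FALSE] -
                                     C[-n, , drop = FALSE])^2)))
  bonded_prev <- same_chain & !is.na(dCN) & dCN <= break_cutoff

  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L && bonded_prev[i] &&
        !anyNA(C[i - 1, ]) && !anyNA(N[i, ]) && !anyNA(CA[i, ]) &&
        !anyNA(C[i, ])) {
      phi[i] <- dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < n && bonded_prev[i + 1] &&
        !anyNA(N[i, ]) && !anyNA(CA[i, ]) && !anyNA(C[i, ]) &&
        !anyNA(N[i + 1, ])) {
      psi[i] <- dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  dplyr::mutate(res, phi = phi, psi = psi)
}

#' Read a per-residue conservation table
#'
#' Reads ConSurf-style whitespace- or tab-delimited grade files: one row
#' per position with at least a position column and a score column.
#' Lower scores mean higher conservation; values are passed through
#' unchanged.
#'
#' @param file Path to the table.
#' @param position_col,score_col Column name or index of the residue
#'   position and the conservation score.
#' @param header Whether the file has a header row.
#' @return A tibble with columns `resno` (integer) and `conservation`.
#' @export
read_conservation <- function(file, position_col = 1, score_col = 2,
                              header = TRUE) {
  raw <- utils::read.table(file, header = header, sep = "",
                           stringsAsFactors = FALSE, comment.char = "#")
  pick <- function(col) {
    if (is.character(col)) {
      if (!col %in% names(raw)) {
        stop("conservation file has no column '", col, "'", call. = FALSE)
      }
      raw[[col]]
    } else {
      raw[[as.integer(col)]]
    }
  }
  out <- tibble::tibble(
    resno = as.integer(pick(position_col)),
    conservation = as.numeric(pick(score_col))
  )
  if (anyDuplicated(out$resno)) {
    stop("duplicate positions in conservation file: ",
         paste(unique(out$resno[duplicated(out$resno)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Assemble the per-residue feature table
#'
#' Joins the structural measures into one record per residue: surface
#' areas, Kyte-Doolittle hydropathy (by residue type), backbone
#' torsions, mean heavy-atom B-factor, and the conservation score
#' (joined by structure position; unmapped residues get `NA` and
#' conservation rows absent from the structure are skipped with a
#' warning).
#'
#' @param atoms Atom tibble from [read_structure()].
#' @param conservation Optional tibble from [read_conservation()].
#' @param probe_radius,n_points,radii,ses Passed to [compute_surfaces()].
#' @param hydropathy Hydropathy lookup, a tibble like [kd_hydropathy()].
#' @return A tibble sorted by (chain, resno, insert) with columns `chain`,
#'   `resno`, `insert`, `aa`, `areaSAS`, `areaSES`, `kdHydrophobicity`,
#'   `PHI`, `PSI`, `bFactor`, `conservation`.
#' @export
residue_features <- function(atoms, conservation = NULL, probe_radius = 1.4,
                             n_points = 960, radii = NULL, ses = "probe0",
                             hydropathy = kd_hydropathy()) {
  surf <- compute_surfaces(atoms, probe_radius, n_points, radii, ses)
  tors <- compute_torsions(atoms)
  bfac <- dplyr::summarise(
    dplyr::group_by(atoms, .data$chain, .data$resno, .data$insert),
    bFactor = mean(.data$b),
    .groups = "drop"
  )
  out <- dplyr::left_join(surf, tors,
                          by = c("chain", "resno", "insert", "aa"))
  out <- dplyr::left_join(out, bfac, by = c("chain", "resno", "insert"))
  out <- dplyr::left_join(out, hydropathy, by = "aa")

  if (!is.null(conservation)) {
    if (anyDuplicated(conservation$resno)) {
      stop("duplicate positions in conservation table", call. = FALSE)
    }
    orphan <- setdiff(conservation$resno, out$resno)
    if (length(orphan) > 0L) {
      warning(length(orphan),
              " conservation position(s) absent from the structure, skipped",
              call. = FALSE)
    }
    out <- dplyr::left_join(out, conservation, by = "resno")
  } else {
    out$conservation <- NA_real_
  }

  out <- dplyr::select(out, "chain", "resno", "insert", "aa", "areaSAS",
                       "areaSES", "kdHydrophobicity", PHI = "phi",
                       PSI = "psi", "bFactor", "conservation")
  dplyr::arrange(out, .data$chain, .data$resno, .data$insert)
}

#' Write the residue feature table as CSV
#'
#' @param features Tibble from [residue_features()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_feature_table <- function(features, file) {
  utils::write.csv(features, file, row.names = FALSE, na = "")
  invisible(file)
}
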