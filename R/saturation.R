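# Saturation mutagenesis scan and structure annotation.

#' Score every possible substitution in the structure
#'
#' Enumerates the 19 substitutions at every structure position with
#' complete features, builds the corresponding design rows (structure
#' features constant within a position, only the substitution distance
#' varies), predicts Severity Scores with the trained ensemble, and
#' attaches ternary calls when a gray zone is supplied. Positions with
#' any missing feature are skipped and tallied.
#'
#' @param features Residue feature tibble from [residue_features()].
#' @param centralities Node centrality tibble from [rin_centralities()].
#' @param distance_matrix An `aa_dist` matrix.
#' @param ensemble A trained `severity_ensemble`.
#' @param zone Optional `gray_zone` for ternary calls.
#' @param chain Restrict to one chain (as in [build_design_matrix()]).
#' @return A tibble of class `saturation_table`, sorted by position
#'   then mutant code: `chain`, `resno`, `wt_aa`, `mut_aa`,
#'   `severity_score`, and `call` when a zone is given. Attribute
#'   `n_skipped` counts skipped positions.
#' @export
saturation_scan <- function(features, centralities, distance_matrix,
                            ensemble, zone = NULL, chain = NULL) {
  if (!is.null(chain)) {
    features <- features[features$chain %in% chain, , drop = FALSE]
    centralities <- centralities[centralities$chain %in% chain, ,
                                 drop = FALSE]
  }
  struct <- dplyr::left_join(
    features,
    dplyr::select(centralities, "chain", "resno", "insert", "degree",
                  "betweenness", "closeness", "constraint", "authority",
                  "pagerank", "kcore"),
    by = c("chain", "resno", "insert")
  )
  struct_cols <- setdiff(FEATURE_COLS, "aa_distance")
  usable <- stats::complete.cases(struct[, struct_cols])
  n_skipped <- sum(!usable)
  struct <- struct[usable, , drop = FALSE]
  if (nrow(struct) == 0L) {
    stop("no position has a complete feature set", call. = FALSE)
  }

  rows <- tidyr::crossing(
    dplyr::select(struct, "chain", "resno", "insert", wt_aa = "aa",
                  dplyr::all_of(struct_cols)),
    mut_aa = AA_ALPHABET
  )
  rows <- rows[rows$mut_aa != rows$wt_aa, , drop = FALSE]
  rows$aa_distance <- aa_distance(distance_matrix, rows$wt_aa, rows$mut_aa)

  pred <- stats::predict(ensemble, rows)
  rows$severity_score <- pred$severity_score
  if (!is.null(zone)) {
    rows$call <- classify_with_zone(rows$severity_score, zone)
  }
  out <- dplyr::arrange(
    dplyr::select(rows, "chain", "resno", "insert", "wt_aa", "mut_aa",
                  "severity_score", dplyr::any_of("call")),
    .data$chain, .data$resno, .data$insert, .data$mut_aa
  )
  class(out) <- c("saturation_table", class(out))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Aggregate saturation scores per position
#'
#' @param saturation A `saturation_table`.
#' @param aggregate `"mean"` (default) or `"max"` over the 19
#'   substitution scores of each position.
#' @return Tibble with `chain`, `resno`, `insert`, `wt_aa`, `score`.
#' @export
position_scores <- function(saturation, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  f <- if (aggregate == "mean") mean else max
  dplyr::summarise(
    dplyr::group_by(saturation, .data$chain, .data$resno, .data$insert,
                    .data$wt_aa),
    score = f(.data$severity_score),
    .groups = "drop"
  )
}

#' Write per-position scores into the B-factor column
#'
#' Produces a valid PDB where every atom's B-factor is replaced by its
#' residue's aggregated Severity Score scaled to \[0, 100\] with two
#' decimals; residues without a score get the sentinel -1.00. All other
#' columns are byte-identical to the input.
#'
#' @param pdb Path to a PDB file or a character vector of PDB lines.
#' @param scores Tibble from [position_scores()] (`chain`, `resno`,
#'   `insert`, `score` in \[0, 1\]).
#' @param file Optional output path.
#' @return Character vector of PDB lines, invisibly when `file` is
#'   given.
#' @export
annotate_structure <- function(pdb, scores, file = NULL) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) &&
               file.exists(pdb)) {
    readLines(pdb)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  if (any(scores$score < 0 | scores$score > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  key <- residue_id(scores$chain, scores$resno, scores$insert)
  lookup <- stats::setNames(scores$score, key)

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (length(idx) > 0L) {
    chain <- substr(lines[idx], 22, 22)
    resno <- as.integer(substr(lines[idx], 23, 26))
    insert <- trimws(substr(lines[idx], 27, 27))
    sc <- lookup[residue_id(chain, resno, insert)]
    missing <- is.na(sc)
    if (any(missing)) {
      message(sum(missing), " atom(s) in residues without a score; ",
              "B-factor set to -1.00")
    }
    bf <- ifelse(missing, -1, sc * 100)
    field <- sprintf("%6.2f", bf)
    lines[idx] <- paste0(substr(lines[idx], 1, 60), field,
                         substring(lines[idx], 67))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
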