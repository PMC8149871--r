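# Amino-acid substitution distance index: physicochemical property
# table -> PCA -> pairwise Euclidean distances.

new_property_table <- function(df) {
  stopifnot(is.data.frame(df), "aa" %in% names(df))
  assert_aa(df$aa, "property table")
  if (nrow(df) != 20L || anyDuplicated(df$aa)) {
    stop("a property table needs exactly one row per standard amino acid",
         call. = FALSE)
  }
  df <- df[match(AA_ALPHABET, df$aa), , drop = FALSE]
  tibble::as_tibble(df)
}

#' Bundled amino-acid property table
#'
#' Returns the AAindex collection of numeric amino-acid indices shipped
#' with the seqinr package (544 properties) as a property table: one row
#' per amino acid (alphabetical one-letter code), one column per index.
#'
#' @return A tibble with column `aa` plus 544 numeric property columns
#'   named by AAindex accession.
#' @export
aa_properties <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  m <- vapply(idx, function(a) a$I, numeric(20))
  # rows of each $I are named with seqinr's three-letter labels
  rn <- unname(AA_SEQINR_NAMES[names(idx[[1]]$I)])
  out <- tibble::as_tibble(m)
  out$aa <- rn
  new_property_table(dplyr::relocate(out, "aa"))
}

#' Read an AAindex1 flat file
#'
#' Parses the AAindex1 record format: `H` lines carry the accession, `I`
#' opens the value block whose next two lines hold ten values each in
#' the fixed order A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V. `NA` marks
#' missing values.
#'
#' @param file Path to an AAindex1 flat file.
#' @return A property table tibble (20 rows, one column per index).
#' @export
read_aaindex <- function(file) {
  lines <- readLines(file)
  h <- grep("^H ", lines)
  i <- grep("^I ", lines)
  if (length(h) == 0L || length(h) != length(i)) {
    stop("not an AAindex1 flat file: mismatched H/I records", call. = FALSE)
  }
  # row i: "I    A/L R/K ..." then two lines of 10 values
  order1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  order2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  vals <- lapply(seq_along(i), function(k) {
    acc <- sub("^H\\s+", "", lines[h[k]])
    row1 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i[k] + 1]),
                                                 "\\s+")[[1]]))
    row2 <- suppressWarnings(as.numeric(strsplit(trimws(lines[i[k] + 2]),
                                                 "\\s+")[[1]]))
    if (length(row1) != 10L || length(row2) != 10L) {
      stop("malformed value block in index ", acc, call. = FALSE)
    }
    stats::setNames(c(row1, row2), c(order1, order2))[AA_ALPHABET]
  })
  accs <- sub("^H\\s+", "", lines[h])
  m <- do.call(cbind, vals)
  colnames(m) <- accs
  out <- tibble::as_tibble(m)
  out$aa <- AA_ALPHABET
  new_property_table(dplyr::relocate(out, "aa"))
}

#' Read a property table from CSV
#'
#' Expects a CSV with an `aa` column of one-letter codes (any order) and
#' numeric property columns.
#'
#' @param file Path to the CSV.
#' @return A property table tibble.
#' @export
read_property_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  new_property_table(df)
}

#' Complete-case subset of a property table
#'
#' Drops every property column that has a missing value for any amino
#' acid (the global missing-data policy is removal, not imputation).
#'
#' @param table A property table.
#' @return The table restricted to complete properties, with the number
#'   of dropped columns in attribute `n_dropped`.
#' @export
complete_properties <- function(table) {
  num <- setdiff(names(table), "aa")
  keep <- num[vapply(table[num], function(x) !anyNA(x), logical(1))]
  out <- table[, c("aa", keep)]
  attr(out, "n_dropped") <- length(num) - length(keep)
  out
}

#' Principal-component reduction of amino-acid properties
#'
#' Runs PCA over the property columns (amino acids as observations) and
#' keeps the smallest number of components whose cumulative explained
#' variance reaches `variance_target`. Properties are standardized to
#' zero mean and unit variance by default since raw property scales are
#' incommensurate; constant columns are dropped before scaling.
#'
#' @param table A complete-case property table.
#' @param variance_target Fraction of variance to retain, in (0, 1].
#' @param scale Standardize properties before PCA (default `TRUE`).
#' @return A list of class `aa_pca`: `scores` (20 x k matrix, rows named
#'   by amino acid), `n_components`, `variance_retained`,
#'   `explained_variance` (per-component fractions).
#' @export
reduce_properties <- function(table, variance_target = 0.99, scale = TRUE) {
  stopifnot(variance_target > 0, variance_target <= 1)
  num <- setdiff(names(table), "aa")
  if (length(num) < 2L) {
    stop("need at least 2 properties for a reduction", call. = FALSE)
  }
  m <- as.matrix(table[num])
  if (anyNA(m)) {
    stop("property table has missing values; apply complete_properties() first",
         call. = FALSE)
  }
  constant <- apply(m, 2, stats::sd) == 0
  m <- m[, !constant, drop = FALSE]
  if (ncol(m) == 0L) {
    stop("all properties are constant; variance target unreachable",
         call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scale)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- which(cumsum(ev) >= variance_target - 1e-12)[1]
  if (is.na(k)) {
    stop("variance target unreachable", call. = FALSE)
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- table$aa
  structure(
    list(scores = scores, n_components = k,
         variance_retained = sum(ev[seq_len(k)]),
         explained_variance = ev),
    class = "aa_pca"
  )
}

#' @export
print.aa_pca <- function(x, ...) {
  cat(sprintf("Amino-acid property PCA: %d components, %.2f%% variance retained\n",
              x$n_components, 100 * x$variance_retained))
  invisible(x)
}

#' Pairwise amino-acid distance matrix
#'
#' Euclidean distances between amino acids in the (reduced) property
#' space. Rows and columns are ordered alphabetically by one-letter
#' code.
#'
#' @param scores An `aa_pca` object or a numeric matrix with one row per
#'   amino acid (rownames = one-letter codes).
#' @return A 20 x 20 symmetric matrix of class `aa_dist` with attributes
#'   `n_components` and `variance_retained` when derived from a PCA.
#' @export
aa_distance_matrix <- function(scores) {
  meta <- list(n_components = NA_integer_, variance_retained = NA_real_)
  if (inherits(scores, "aa_pca")) {
    meta <- scores[c("n_components", "variance_retained")]
    scores <- scores$scores
  }
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  assert_aa(rownames(scores), "score matrix rownames")
  scores <- scores[order(rownames(scores)), , drop = FALSE]
  d <- as.matrix(stats::dist(scores, method = "euclidean"))
  structure(d, class = c("aa_dist", class(d)),
            n_components = meta$n_components,
            variance_retained = meta$variance_retained)
}

#' One-step distance index from a property table
#'
#' Convenience wrapper: complete-case filter, PCA at the variance
#' target, Euclidean distance matrix.
#'
#' @inheritParams reduce_properties
#' @return An `aa_dist` matrix.
#' @export
aa_distance_index <- function(table, variance_target = 0.99, scale = TRUE) {
  aa_distance_matrix(
    reduce_properties(complete_properties(table), variance_target, scale)
  )
}

#' Write an amino-acid distance matrix as labeled CSV
#'
#' @param d An `aa_dist` matrix.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_aa_distance <- function(d, file) {
  utils::write.csv(as.data.frame(unclass(d)), file, row.names = TRUE)
  invisible(file)
}

#' Look up substitution distances
#'
#' @param d An `aa_dist` matrix.
#' @param wt,mut One-letter codes (vectorized).
#' @return Numeric vector of distances.
#' @export
aa_distance <- function(d, wt, mut) {
  assert_aa(wt, "wt"); assert_aa(mut, "mut")
  d[cbind(wt, mut)]
}
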