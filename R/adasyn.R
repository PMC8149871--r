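# ADASYN: adaptive synthetic oversampling of the minority class.

# Largest-remainder apportionment of `total` into integer counts
# proportional to `weights` (which sum to 1).
largest_remainder <- function(weights, total) {
  raw <- weights * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    # distribute the shortfall to the largest fractional remainders,
    # ties broken by index
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Indices of the k nearest rows to row i (excluding i), Euclidean,
# ties broken by row index.
knn_indices <- function(x, i, candidates, k) {
  cand <- candidates[candidates != i]
  d <- sqrt(rowSums((x[cand, , drop = FALSE] -
                       matrix(x[i, ], length(cand), ncol(x),
                              byrow = TRUE))^2))
  cand[order(d, cand)][seq_len(min(k, length(cand)))]
}

#' Adaptive synthetic minority oversampling (ADASYN)
#'
#' Balances a two-class dataset by generating synthetic minority
#' examples, more of them near minority points that are hard to learn.
#' With minority size \eqn{m_s} and majority size \eqn{m_l}, the total
#' synthetic budget is \eqn{G = (m_l - m_s)\beta}. Each minority point
#' gets difficulty \eqn{r_i} = (majority neighbours among its K nearest
#' neighbours in the full data) / K; the normalized \eqn{\hat r_i}
#' apportion G by largest remainder (so the counts sum to G exactly).
#' A synthetic point is \eqn{s = x_i + \lambda (x_z - x_i)} with
#' \eqn{\lambda \sim U(0,1)} and \eqn{x_z} a random one of the K nearest
#' minority neighbours of \eqn{x_i}. If no minority point has majority
#' neighbours (\eqn{\sum r_i = 0}) the weights fall back to uniform.
#'
#' @param x Numeric matrix or data frame of features (finite values).
#' @param y Binary labels (factor or vector with exactly 2 levels among
#'   the values present).
#' @param beta Fraction of the imbalance to close; 1 aims for full
#'   balance.
#' @param k Neighbourhood size.
#' @param seed Integer seed; the run is reproducible given (data, seed).
#' @return A list of class `adasyn_result`: `data` (tibble of original
#'   rows, unchanged, followed by synthetic rows, with `label` and
#'   `synthetic` columns), `parents` (tibble: synthetic row id, parent
#'   and partner original-row indices, `lambda`), `G`, `g_i`, `r_hat`,
#'   `minority`, and the generation parameters.
#' @export
adasyn <- function(x, y, beta = 1, k = 5, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("ADASYN needs exactly two classes, got ", length(classes),
         call. = FALSE)
  }
  counts <- table(y)
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(classes, minority)
  m_s <- sum(y == minority)
  m_l <- sum(y == majority)
  if (m_s < 2L) stop("minority class needs at least 2 examples",
                     call. = FALSE)
  stopifnot(k >= 1, beta >= 0)

  original <- tibble::as_tibble(as.data.frame(x))
  original$label <- y
  original$synthetic <- FALSE

  G <- round((m_l - m_s) * beta)
  empty <- function() {
    structure(
      list(data = original,
           parents = tibble::tibble(row = integer(), parent = integer(),
                                    partner = integer(), lambda = numeric()),
           G = G, g_i = integer(0), r_hat = numeric(0),
           minority = minority, beta = beta, k = k, seed = seed),
      class = "adasyn_result"
    )
  }
  if (G <= 0) return(empty())

  min_idx <- which(y == minority)
  all_idx <- seq_len(nrow(x))

  r <- vapply(min_idx, function(i) {
    nb <- knn_indices(x, i, all_idx, k)
    sum(y[nb] == majority) / k
  }, numeric(1))
  r_hat <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
  g <- largest_remainder(r_hat, G)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  rows <- vector("list", sum(g))
  parents <- matrix(0L, sum(g), 2)
  lambdas <- numeric(sum(g))
  s <- 0L
  for (ii in seq_along(min_idx)) {
    if (g[ii] == 0L) next
    i <- min_idx[ii]
    nb_min <- knn_indices(x, i, min_idx, k)
    for (rep_j in seq_len(g[ii])) {
      z <- nb_min[sample.int(length(nb_min), 1L)]
      lam <- stats::runif(1)
      s <- s + 1L
      rows[[s]] <- x[i, ] + lam * (x[z, ] - x[i, ])
      parents[s, ] <- c(i, z)
      lambdas[s] <- lam
    }
  }

  synth <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  names(synth) <- colnames(original)[seq_len(ncol(x))]
  synth$label <- minority
  synth$synthetic <- TRUE

  structure(
    list(
      data = dplyr::bind_rows(original, synth),
      parents = tibble::tibble(
        row = nrow(original) + seq_len(s),
        parent = parents[, 1], partner = parents[, 2], lambda = lambdas
      ),
      G = G, g_i = g, r_hat = r_hat, minority = minority,
      beta = beta, k = k, seed = seed
    ),
    class = "adasyn_result"
  )
}

#' @export
print.adasyn_result <- function(x, ...) {
  cat(sprintf(
    "ADASYN: %d synthetic '%s' rows (G = %d, beta = %g, K = %d, seed = %d)\n",
    sum(x$data$synthetic), x$minority, x$G, x$beta, x$k, x$seed))
  invisible(x)
}
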