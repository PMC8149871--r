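# Design matrix assembly, cross-validated grid search over the
# classifier suite, model selection by kappa/AUC, ensemble scoring.

# The classifier feature set: structural, conservation, network, and
# the substitution-distance column.
FEATURE_COLS <- c("areaSAS", "areaSES", "kdHydrophobicity", "PSI", "PHI",
                  "bFactor", "conservation", "degree", "betweenness",
                  "closeness", "constraint", "authority", "pagerank",
                  "kcore", "aa_distance")

#' Names of the classifier feature columns
#'
#' The fifteen per-instance features the ensemble consumes: seven
#' structural/conservation measures, seven network centralities, and
#' the wild-type-to-mutant substitution distance.
#'
#' @return Character vector of column names.
#' @export
feature_columns <- function() FEATURE_COLS

#' Assemble the classifier design matrix
#'
#' Joins curated mutation records to the per-residue structural
#' features and network centralities of their structure positions and
#' attaches the wild-type-to-mutant substitution distance. All
#' structure-derived columns are constant across mutations at the same
#' position; only `aa_distance` varies. Rows whose position is absent
#' from the structure, whose wild-type residue disagrees with the
#' structure sequence, or with any missing feature value are dropped
#' and tallied.
#'
#' @param mutations Tibble with `position` (mature-protein numbering),
#'   `wt_aa`, `mut_aa`, and a `label` factor (see
#'   [binarize_severity()]).
#' @param features Residue feature tibble from [residue_features()].
#' @param centralities Node centrality tibble from [rin_centralities()].
#' @param distance_matrix An `aa_dist` matrix.
#' @param numbering_offset Added to `position` to obtain structure
#'   numbering (0 when clinical and structure numbering agree).
#' @param chain Restrict the structure tables to one chain (default: use
#'   all rows; positions must then be unique across chains).
#' @return A tibble with `position`, `wt_aa`, `mut_aa`, the feature
#'   columns and `label`; attribute `drop_tally` records how many rows
#'   were lost to each rule.
#' @export
build_design_matrix <- function(mutations, features, centralities,
                                distance_matrix, numbering_offset = 0L,
                                chain = NULL) {
  if (!is.null(chain)) {
    features <- features[features$chain %in% chain, , drop = FALSE]
    centralities <- centralities[centralities$chain %in% chain, ,
                                 drop = FALSE]
  }
  if (anyDuplicated(features$resno)) {
    stop("structure positions are not unique; pass `chain`", call. = FALSE)
  }
  struct <- dplyr::left_join(
    features,
    dplyr::select(centralities, "resno", "degree", "betweenness",
                  "closeness", "constraint", "authority", "pagerank",
                  "kcore"),
    by = "resno"
  )

  mut <- dplyr::mutate(tibble::as_tibble(mutations),
                       resno = .data$position + numbering_offset)
  n0 <- nrow(mut)
  joined <- dplyr::inner_join(
    mut, dplyr::rename(struct, struct_aa = "aa"), by = "resno"
  )
  n_unmapped <- n0 - nrow(joined)

  wt_ok <- joined$wt_aa == joined$struct_aa
  n_wt_mismatch <- sum(!wt_ok)
  joined <- joined[wt_ok, , drop = FALSE]

  joined$aa_distance <- aa_distance(distance_matrix, joined$wt_aa,
                                    joined$mut_aa)

  complete <- stats::complete.cases(joined[, FEATURE_COLS])
  n_incomplete <- sum(!complete)
  out <- joined[complete, c("position", "wt_aa", "mut_aa", FEATURE_COLS,
                            intersect("label", names(joined)))]
  if (nrow(out) == 0L) {
    stop("no usable rows after filtering (unmapped: ", n_unmapped,
         ", wt mismatch: ", n_wt_mismatch, ", incomplete: ", n_incomplete,
         ")", call. = FALSE)
  }
  attr(out, "drop_tally") <- c(unmapped = n_unmapped,
                               wt_mismatch = n_wt_mismatch,
                               incomplete = n_incomplete)
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{(p_o - p_e) / (1 - p_e)}. Accepts a
#' confusion matrix of counts, or two label vectors.
#'
#' @param x A square confusion matrix, or predicted labels.
#' @param y Actual labels when `x` is a vector.
#' @return Kappa in \[-1, 1\]; 0 (with a warning) when expected
#'   agreement is 1.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))
cohen_kappa <- function(x, y = NULL) {
  cm <- if (is.null(y)) as.matrix(x) else {
    u <- sort(unique(c(as.character(x), as.character(y))))
    table(factor(as.character(x), u), factor(as.character(y), u))
  }
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("expected agreement is 1; kappa defined as 0", call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; tied scores contribute 1/2.
#'
#' @param scores Numeric scores, higher meaning more likely positive.
#' @param labels Binary labels.
#' @param positive The positive class; default the last sorted level.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  if (is.null(positive)) positive <- classes[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average member scores into a Severity Score
#'
#' Element-wise arithmetic mean of per-model score vectors.
#'
#' @param member_scores List of equal-length numeric vectors in
#'   \[0, 1\].
#' @return Numeric vector of ensemble Severity Scores.
#' @export
ensemble_scores <- function(member_scores) {
  stopifnot(length(member_scores) >= 1L)
  lens <- lengths(member_scores)
  if (length(unique(lens)) != 1L) {
    stop("member score vectors have different lengths", call. = FALSE)
  }
  Reduce(`+`, member_scores) / length(member_scores)
}

#' Stratified cross-validation folds
#'
#' Assigns rows to `k` folds preserving class proportions; the same
#' seeded partition is shared by every model.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row. Errors if any fold would miss a
#'   class.
#' @export
make_cv_folds <- function(labels, k = 10, seed = 1) {
  stopifnot(k >= 2)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  for (f in seq_len(k)) {
    if (length(unique(labels[fold != f])) < 2L ||
        length(unique(labels[fold == f])) < 2L) {
      stop("fold ", f, " lacks a class; too few examples for ", k,
           " stratified folds", call. = FALSE)
    }
  }
  fold
}

fit_normalizer <- function(x, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (method == "minmax") {
    list(method = method, a = apply(x, 2, min), b = apply(x, 2, max))
  } else {
    list(method = method, a = colMeans(x), b = apply(x, 2, stats::sd))
  }
}

apply_normalizer <- function(x, norm) {
  span <- norm$b - if (norm$method == "minmax") norm$a else 0
  span[span == 0 | (norm$method == "zscore" & norm$b == 0)] <- 1
  if (norm$method == "minmax") {
    sweep(sweep(x, 2, norm$a, "-"), 2, span, "/")
  } else {
    sweep(sweep(x, 2, norm$a, "-"), 2, norm$b + (norm$b == 0), "/")
  }
}

# --- model suite -----------------------------------------------------

model_spec <- function(name, grid, fit, predict) {
  list(name = name, grid = grid, fit = fit, predict = predict)
}

prob_severe <- function(p) pmin(pmax(as.numeric(p), 0), 1)

#' The classifier suite
#'
#' Six algorithms with their hyperparameter grids: decision tree
#' (minsplit, minbucket, cp), random forest (ntree, mtry, nodesize),
#' SVM with radial (gamma) and polynomial (coef0, degree) kernels,
#' naive Bayes (no hyperparameters), and gradient-boosted trees
#' (max_depth, eta, lambda). Grid endpoints follow the published search
#' ranges; the `"default"` preset steps them coarsely and the `"fast"`
#' preset is a reduced grid for quick runs. Every spec is a list of
#' `name`, `grid`, `fit(x, y, params, seed)` and `predict(model, x)`
#' returning the probability of the severe class, so the suite is fully
#' overridable.
#'
#' @param preset `"default"` or `"fast"`.
#' @return Named list of model specifications.
#' @export
model_suite <- function(preset = c("default", "fast")) {
  preset <- match.arg(preset)
  fast <- preset == "fast"

  dt_grid <- if (fast) {
    expand.grid(minsplit = c(2, 20), minbucket = c(1, 5),
                cp = c(0.001, 0.01))
  } else {
    expand.grid(minsplit = c(2, 10, 25, 50), minbucket = c(1, 5, 10, 20),
                cp = c(1e-4, 1e-3, 1e-2, 1e-1, 1))
  }
  rf_grid <- if (fast) {
    expand.grid(ntree = 50, mtry = c(2, 4), nodesize = c(1, 5))
  } else {
    expand.grid(ntree = c(4, 25, 50, 100), mtry = c(2, 4, 7),
                nodesize = c(1, 3, 5))
  }
  svr_grid <- if (fast) {
    data.frame(gamma = c(0.01, 0.1, 0.5))
  } else {
    data.frame(gamma = c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1, 1.25, 1.5))
  }
  svp_grid <- if (fast) {
    expand.grid(coef0 = c(0.1, 1), degree = c(2, 3))
  } else {
    expand.grid(coef0 = c(0.1, 0.5, 1, 1.5, 2), degree = 2:5)
  }
  xgb_grid <- if (fast) {
    expand.grid(max_depth = c(2, 6), eta = 0.3, lambda = c(0, 1))
  } else {
    expand.grid(max_depth = c(1, 3, 6, 12, 25), eta = c(0.1, 0.3),
                lambda = c(0, 0.5, 1))
  }

  list(
    decision_tree = model_spec(
      "decision_tree", dt_grid,
      fit = function(x, y, params, seed) {
        df <- as.data.frame(x); df$.y <- y
        rpart::rpart(.y ~ ., df, method = "class",
                     control = rpart::rpart.control(
                       minsplit = params$minsplit,
                       minbucket = params$minbucket, cp = params$cp))
      },
      predict = function(m, x) {
        prob_severe(stats::predict(m, as.data.frame(x),
                                   type = "prob")[, "severe"])
      }
    ),
    random_forest = model_spec(
      "random_forest", rf_grid,
      fit = function(x, y, params, seed) {
        set.seed(seed)
        randomForest::randomForest(
          x, y, ntree = params$ntree,
          mtry = min(params$mtry, ncol(x)), nodesize = params$nodesize)
      },
      predict = function(m, x) {
        prob_severe(stats::predict(m, x, type = "prob")[, "severe"])
      }
    ),
    svm_radial = model_spec(
      "svm_radial", svr_grid,
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(x, y, kernel = "radial", gamma = params$gamma,
                   probability = TRUE)
      },
      predict = function(m, x) {
        p <- stats::predict(m, x, probability = TRUE)
        prob_severe(attr(p, "probabilities")[, "severe"])
      }
    ),
    svm_polynomial = model_spec(
      "svm_polynomial", svp_grid,
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(x, y, kernel = "polynomial", coef0 = params$coef0,
                   degree = params$degree, probability = TRUE)
      },
      predict = function(m, x) {
        p <- stats::predict(m, x, probability = TRUE)
        prob_severe(attr(p, "probabilities")[, "severe"])
      }
    ),
    naive_bayes = model_spec(
      "naive_bayes", data.frame(.dummy = 0),
      fit = function(x, y, params, seed) {
        e1071::naiveBayes(as.data.frame(x), y)
      },
      predict = function(m, x) {
        prob_severe(stats::predict(m, as.data.frame(x),
                                   type = "raw")[, "severe"])
      }
    ),
    xgboost = model_spec(
      "xgboost", xgb_grid,
      fit = function(x, y, params, seed) {
        set.seed(seed)
        dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y == "severe"))
        xgboost::xgb.train(
          params = list(max_depth = params$max_depth, eta = params$eta,
                        lambda = params$lambda,
                        objective = "binary:logistic", nthread = 1),
          data = dtrain, nrounds = 50, verbose = 0)
      },
      predict = function(m, x) {
        prob_severe(stats::predict(m, xgboost::xgb.DMatrix(x)))
      }
    )
  )
}

fold_data <- function(x, y, fold_id, normalize, augment, beta, k_adasyn,
                      seed) {
  lapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    norm <- fit_normalizer(x[tr, , drop = FALSE], normalize)
    xtr <- apply_normalizer(x[tr, , drop = FALSE], norm)
    ytr <- y[tr]
    n_before <- nrow(xtr)
    if (augment) {
      aug <- adasyn(xtr, ytr, beta = beta, k = k_adasyn,
                    seed = seed + 1000L * f)
      feat <- setdiff(names(aug$data), c("label", "synthetic"))
      xtr <- as.matrix(aug$data[feat])
      colnames(xtr) <- colnames(x)
      ytr <- factor(aug$data$label, levels = levels(y))
    }
    list(fold = f,
         x_train = xtr, y_train = ytr,
         n_train = n_before, n_train_augmented = nrow(xtr),
         x_val = apply_normalizer(x[!tr, , drop = FALSE], norm),
         y_val = y[!tr], val_rows = which(!tr))
  })
}

#' Train the severity classifier ensemble
#'
#' Runs the full training protocol on a design matrix: a single seeded
#' stratified fold partition shared by every algorithm; per fold,
#' feature normalization fitted on the training part only, ADASYN
#' augmentation of the training part only (validation folds are never
#' touched); grid search per model with the best hyperparameters chosen
#' by mean fold kappa (mean AUC breaks ties); and an ensemble of the
#' top `n_members` models by the same criterion, refitted on the full
#' (normalized, optionally augmented) data. The ensemble's Severity
#' Score is the mean of the members' severe-class probabilities.
#'
#' @param design Design matrix tibble from [build_design_matrix()]
#'   (feature columns plus `label`).
#' @param models Model suite, as from [model_suite()].
#' @param folds Number of cross-validation folds.
#' @param seed Master seed governing folds, augmentation and stochastic
#'   learners.
#' @param augment Apply ADASYN inside training folds.
#' @param beta,k_adasyn ADASYN parameters.
#' @param normalize `"minmax"` (to \[0, 1\]) or `"zscore"`.
#' @param n_members Number of ensemble members.
#' @return An object of class `severity_ensemble` with members, CV
#'   metrics (`metrics`, `cv_detail`), the fold assignment, the
#'   normalization parameters and all seeds.
#' @export
severity_train <- function(design, models = model_suite("default"),
                           folds = 10, seed = 1, augment = TRUE,
                           beta = 1, k_adasyn = 5,
                           normalize = c("minmax", "zscore"),
                           n_members = 2) {
  normalize <- match.arg(normalize)
  x <- as.matrix(design[, FEATURE_COLS])
  y <- factor(design$label, levels = c("mild_moderate", "severe"))
  fold_id <- make_cv_folds(y, folds, seed)
  fd <- fold_data(x, y, fold_id, normalize, augment, beta, k_adasyn, seed)

  metric_rows <- list()
  detail_rows <- list()
  best_params <- list()
  for (spec in models) {
    grid <- spec$grid
    grid_means <- data.frame(kappa = numeric(nrow(grid)),
                             auc = numeric(nrow(grid)),
                             accuracy = numeric(nrow(grid)))
    fold_metrics_best <- NULL
    for (gi in seq_len(nrow(grid))) {
      fm <- vapply(fd, function(fdat) {
        m <- spec$fit(fdat$x_train, fdat$y_train, grid[gi, , drop = FALSE],
                      seed + fdat$fold)
        sc <- spec$predict(m, fdat$x_val)
        pred <- ifelse(sc >= 0.5, "severe", "mild_moderate")
        c(accuracy = mean(pred == as.character(fdat$y_val)),
          kappa = cohen_kappa(pred, as.character(fdat$y_val)),
          auc = roc_auc(sc, fdat$y_val, positive = "severe"))
      }, c(accuracy = 0, kappa = 0, auc = 0))
      grid_means$kappa[gi] <- mean(fm["kappa", ])
      grid_means$auc[gi] <- mean(fm["auc", ])
      grid_means$accuracy[gi] <- mean(fm["accuracy", ])
      if (gi == which.max(grid_means$kappa[seq_len(gi)] +
                            1e-9 * grid_means$auc[seq_len(gi)])) {
        fold_metrics_best <- fm
      }
    }
    best <- order(-grid_means$kappa, -grid_means$auc)[1]
    best_params[[spec$name]] <- grid[best, , drop = FALSE]
    metric_rows[[spec$name]] <- tibble::tibble(
      model = spec$name,
      kappa = grid_means$kappa[best],
      auc = grid_means$auc[best],
      accuracy = grid_means$accuracy[best],
      accuracy_sd = stats::sd(fold_metrics_best["accuracy", ]),
      params = list(best_params[[spec$name]])
    )
    detail_rows[[spec$name]] <- tibble::tibble(
      model = spec$name,
      fold = vapply(fd, `[[`, integer(1), "fold"),
      n_train = vapply(fd, `[[`, numeric(1), "n_train"),
      n_train_augmented = vapply(fd, `[[`, numeric(1),
                                 "n_train_augmented"),
      n_val = vapply(fd, function(f) length(f$val_rows), numeric(1)),
      accuracy = fold_metrics_best["accuracy", ],
      kappa = fold_metrics_best["kappa", ],
      auc = fold_metrics_best["auc", ]
    )
  }
  metrics <- dplyr::arrange(dplyr::bind_rows(metric_rows),
                            dplyr::desc(.data$kappa), dplyr::desc(.data$auc))
  member_names <- metrics$model[seq_len(min(n_members, nrow(metrics)))]
  metrics$selected <- metrics$model %in% member_names

  # refit members on the full data
  norm <- fit_normalizer(x, normalize)
  x_full <- apply_normalizer(x, norm)
  y_full <- y
  if (augment) {
    aug <- adasyn(x_full, y_full, beta = beta, k = k_adasyn, seed = seed)
    feat <- setdiff(names(aug$data), c("label", "synthetic"))
    x_full <- as.matrix(aug$data[feat])
    colnames(x_full) <- colnames(x)
    y_full <- factor(aug$data$label, levels = levels(y))
  }
  members <- lapply(member_names, function(nm) {
    spec <- models[[nm]]
    list(name = nm, spec = spec, params = best_params[[nm]],
         fit = spec$fit(x_full, y_full, best_params[[nm]], seed))
  })
  names(members) <- member_names

  structure(
    list(members = members, metrics = metrics,
         cv_detail = dplyr::bind_rows(detail_rows),
         fold_id = fold_id,
         val_rows = lapply(fd, `[[`, "val_rows"),
         normalizer = norm, feature_names = FEATURE_COLS,
         augment = augment, beta = beta, k_adasyn = k_adasyn,
         folds = folds, seed = seed, n_train = nrow(design)),
    class = "severity_ensemble"
  )
}

#' @export
print.severity_ensemble <- function(x, ...) {
  cat(sprintf(
    "Severity ensemble: %s (mean of member scores)\n%d training rows, %d-fold CV, seed %d\n",
    paste(names(x$members), collapse = " + "), x$n_train, x$folds, x$seed))
  sel <- x$metrics[x$metrics$selected, c("model", "kappa", "auc", "accuracy")]
  print(as.data.frame(sel), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict Severity Scores
#'
#' Scores new instances with every ensemble member and averages into
#' the Severity Score. Prediction is deterministic: no random numbers
#' are drawn.
#'
#' @param object A `severity_ensemble`.
#' @param newdata Tibble or matrix containing the feature columns.
#' @param ... Unused.
#' @return A tibble with one column of member scores per model and
#'   `severity_score`.
#' @export
predict.severity_ensemble <- function(object, newdata, ...) {
  x <- as.matrix(tibble::as_tibble(newdata)[, object$feature_names])
  x <- apply_normalizer(x, object$normalizer)
  member_scores <- lapply(object$members, function(m) m$spec$predict(m$fit, x))
  out <- tibble::as_tibble(member_scores)
  out$severity_score <- ensemble_scores(member_scores)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-model cross-validation metrics
#'
#' @param x A `severity_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per model: best-grid kappa, AUC,
#'   accuracy, hyperparameters and whether the model was selected.
#' @export
tidy.severity_ensemble <- function(x, ...) {
  m <- x$metrics
  m$params <- vapply(m$params, function(p) {
    p <- p[setdiff(names(p), ".dummy")]
    if (length(p) == 0) return("")
    paste(names(p), unlist(p), sep = "=", collapse = ", ")
  }, character(1))
  m
}

#' One-row ensemble summary
#'
#' @param x A `severity_ensemble`.
#' @param ... Unused.
#' @return Tibble with the member names, their mean CV kappa/AUC/
#'   accuracy, training size and seed.
#' @export
glance.severity_ensemble <- function(x, ...) {
  sel <- x$metrics[x$metrics$selected, ]
  tibble::tibble(
    members = paste(sel$model, collapse = "+"),
    mean_kappa = mean(sel$kappa),
    mean_auc = mean(sel$auc),
    mean_accuracy = mean(sel$accuracy),
    n_train = x$n_train,
    folds = x$folds,
    augmented = x$augment,
    seed = x$seed
  )
}
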