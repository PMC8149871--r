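test_that("kappa matches hand-computed agreement values", {
  expect_equal(cohen_kappa(diag(c(10, 20))), 1.0)
  # p_o = 35/50 = 0.7, p_e = (25*30 + 25*20)/2500 = 0.5
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2)), 0.4)
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1.0)
  expect_warning(k0 <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "kappa")
  expect_equal(k0, 0)
})

test_that("chance-level predictions give near-zero kappa", {
  set.seed(17)
  ks <- replicate(200, {
    y <- sample(c("a", "b"), 60, replace = TRUE)
    p <- sample(c("a", "b"), 60, replace = TRUE)
    cohen_kappa(p, y)
  })
  expect_lt(abs(mean(ks)), 0.05)
})

test_that("rank AUC handles separation, inversion and ties", {
  y <- c("neg", "neg", "pos", "pos")
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), y, positive = "pos"), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), y, positive = "pos"), 0.0)
  expect_equal(roc_auc(rep(0.5, 4), y, positive = "pos"), 0.5)
  expect_error(roc_auc(1:3, c("a", "a", "a")), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    y <- sample(c(0, 1), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + y  # informative but noisy, with possible ties
    s <- round(s, 1)
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, s, levels = c("0", "1"), direction = "<",
                          quiet = TRUE))))
    expect_equal(roc_auc(s, y, positive = "1"), ref, tolerance = 1e-12)
  }
})

test_that("ensemble scores are the element-wise mean", {
  expect_equal(ensemble_scores(list(c(0.2, 1), c(0.8, 0))), c(0.5, 0.5))
  expect_equal(ensemble_scores(list(c(0.3, 0.7))), c(0.3, 0.7))
  expect_error(ensemble_scores(list(1:2, 1:3)), "length")
})

test_that("ensemble variance never exceeds the mean member variance", {
  set.seed(41)
  m1 <- runif(200); m2 <- runif(200)
  ens <- ensemble_scores(list(m1, m2))
  expect_lte(var(ens), mean(c(var(m1), var(m2))))
})

test_that("design rows at one position differ only in the substitution distance", {
  b <- toy_bundle(40, seed = 7)
  pos <- b$features$resno[10]
  wt <- b$features$aa[10]
  muts <- tibble::tibble(
    position = c(pos, pos),
    wt_aa = wt,
    mut_aa = setdiff(c("A", "W", "R"), wt)[1:2],
    label = factor(c("severe", "mild_moderate"),
                   levels = c("mild_moderate", "severe"))
  )
  dm <- build_design_matrix(muts, b$features, b$centralities, b$dmat)
  shared <- setdiff(severin:::FEATURE_COLS, "aa_distance")
  expect_equal(dm[1, shared], dm[2, shared])
  expect_false(dm$aa_distance[1] == dm$aa_distance[2])
  expect_equal(dm$aa_distance,
               aa_distance(b$dmat, dm$wt_aa, dm$mut_aa))
})

test_that("unmapped, mismatched and incomplete rows are dropped with a tally", {
  b <- toy_bundle(40, seed = 7)
  good_pos <- b$features$resno[10]
  muts <- tibble::tibble(
    position = c(good_pos, 999L, good_pos, 1L),
    wt_aa = c(b$features$aa[10], "A", "W", b$features$aa[1]),
    mut_aa = c("W", "V", "A", "V"),
    label = factor("severe", levels = c("mild_moderate", "severe"))
  )
  muts$mut_aa[1] <- setdiff(severin:::AA_ALPHABET,
                            muts$wt_aa[1])[1]
  muts$mut_aa[3] <- "A"
  # row 2 unmapped; row 3 wt mismatch (unless position 10 really is W);
  # row 4 incomplete (terminal residue has no phi)
  dm <- build_design_matrix(muts, b$features, b$centralities, b$dmat)
  tally <- attr(dm, "drop_tally")
  expect_equal(sum(tally), 4L - nrow(dm))
  expect_equal(unname(tally["unmapped"]), 1L)
  expect_gte(unname(tally["incomplete"]), 1L)
})

test_that("stratified folds are seed-stable, shared, and class-complete", {
  y <- rep(c("a", "b"), c(70, 30))
  f1 <- make_cv_folds(y, 10, seed = 5)
  f2 <- make_cv_folds(y, 10, seed = 5)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:10)
  for (k in 1:10) expect_equal(length(unique(y[f1 == k])), 2L)
  expect_error(make_cv_folds(rep(c("a", "b"), c(98, 2)), 10, seed = 1),
               "lacks a class")
})

test_that("training selects two members, reports metrics, and predicts in [0,1]", {
  tb <- trained_bundle()
  ens <- tb$ensemble
  expect_length(ens$members, 2L)
  expect_s3_class(tidy(ens), "tbl_df")
  expect_true(all(c("kappa", "auc", "accuracy", "selected") %in%
                    names(tidy(ens))))
  expect_equal(sum(tidy(ens)$selected), 2L)
  g <- glance(ens)
  expect_equal(nrow(g), 1L)
  expect_gte(g$mean_auc, 0.8)

  pred <- predict(ens, tb$design)
  expect_true(all(pred$severity_score >= 0 & pred$severity_score <= 1))
  # deterministic at predict time
  expect_identical(pred, predict(ens, tb$design))
})

test_that("augmentation never touches validation folds", {
  tb <- trained_bundle()
  ens_plain <- severity_train(tb$design, model_suite("fast")["naive_bayes"],
                              folds = 5, seed = 11, augment = FALSE)
  ens_aug <- severity_train(tb$design, model_suite("fast")["naive_bayes"],
                            folds = 5, seed = 11, augment = TRUE)
  # identical seeded partition shared across runs and models
  expect_identical(ens_plain$fold_id, ens_aug$fold_id)
  expect_identical(ens_plain$val_rows, ens_aug$val_rows)
  # augmentation only ever grows the training side
  detail <- ens_aug$cv_detail
  expect_true(all(detail$n_train_augmented >= detail$n_train))
  expect_identical(ens_plain$cv_detail$n_val, detail$n_val)
  # validation rows are original design rows, byte-identical
  for (f in seq_along(ens_aug$val_rows)) {
    expect_identical(tb$design[ens_aug$val_rows[[f]], ],
                     tb$design[ens_plain$val_rows[[f]], ])
  }
})

test_that("label flip approximately flips the severity score", {
  tb <- trained_bundle()
  flipped <- tb$design
  flipped$label <- factor(
    ifelse(tb$design$label == "severe", "mild_moderate", "severe"),
    levels = c("mild_moderate", "severe")
  )
  suite <- model_suite("fast")["naive_bayes"]
  e1 <- severity_train(tb$design, suite, folds = 5, seed = 3,
                       augment = FALSE, n_members = 1)
  e2 <- severity_train(flipped, suite, folds = 5, seed = 3,
                       augment = FALSE, n_members = 1)
  s1 <- predict(e1, tb$design)$severity_score
  s2 <- predict(e2, tb$design)$severity_score
  # scores anticorrelate strongly; exact 1-s symmetry is not required
  expect_lt(cor(s1, s2), -0.95)
})

test_that("naive Bayes accepts an empty hyperparameter grid", {
  suite <- model_suite("fast")
  expect_equal(nrow(suite$naive_bayes$grid), 1L)
  expect_equal(setdiff(names(suite$naive_bayes$grid), ".dummy"),
               character(0))
  expect_length(suite, 6L)
  expect_setequal(names(suite),
                  c("decision_tree", "random_forest", "svm_radial",
                    "svm_polynomial", "naive_bayes", "xgboost"))
})
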