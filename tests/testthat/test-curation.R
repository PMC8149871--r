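test_that("activity normalization reproduces the worked substitutions", {
  out <- normalize_activity(c("10–24", "10-24", ">5", "<1", "<10",
                              "<11", "17", "2.5"))
  expect_equal(out$activity, c(17, 17, 5, 0, 10, 11, 17, 2.5))
  expect_false(any(out$rejected))
})

test_that("ambiguous and unparseable activities are rejected with reasons", {
  out <- normalize_activity(c("0 to 2", "<1 to 2", "<2", "chromogenic",
                              "", NA))
  expect_true(all(out$rejected))
  expect_equal(out$reason,
               c("ambiguous", "ambiguous", "ambiguous", "unparseable",
                 "missing", "missing"))
  # a range within one band is fine, a band-crossing range is not
  expect_false(normalize_activity("1-3")$rejected)
  expect_true(normalize_activity("3-8")$rejected)
})

test_that("severity bands are the clinical half-open intervals", {
  expect_equal(label_severity(c(0, 0.5, 0.99)), rep("severe", 3))
  expect_equal(label_severity(c(1, 3, 4.99)), rep("moderate", 3))
  expect_equal(label_severity(c(5, 20, 40)), rep("mild", 3))
  expect_equal(label_severity(75), "non_hemophilic")
  expect_error(label_severity(-1), "negative")
})

test_that("severity labeling is a monotone step function of activity", {
  grid <- seq(0, 100, by = 0.25)
  lab <- label_severity(grid)
  rank <- c(severe = 1, moderate = 2, mild = 3, non_hemophilic = 4)
  expect_true(all(diff(rank[lab]) >= 0))
})

eahad_fixture <- function() {
  tibble::tibble(
    position = c(100L, 200L, 300L, 2400L, 150L, 160L, 170L, 180L, 190L,
                 210L, 220L),
    wt_aa = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M"),
    mut_aa = c("V", "W", "Y", "A", "*", "S", "T", "N", "Q", "R", "M"),
    activity = c("12", "150", "0 to 2", "10", "0.5", "abc", "3", "2", "30",
                 "mild/moderate?", "8"),
    activity_2nd = c(NA, NA, NA, NA, NA, NA, "25", NA, NA, NA, NA),
    severity = c("mild", "mild", NA, "mild", "severe", NA, "moderate",
                 "moderate", "mild/moderate", NA, "mild"),
    inhibitor = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA)
  )
}

test_that("every EAHAD sanitation rule fires and is attributed once", {
  res <- sanitize_mutations(eahad_fixture(), "eahad")
  expect_equal(nrow(res$kept) + nrow(res$rejected), 11L)
  expect_equal(sum(res$tally$n), nrow(res$rejected))
  reasons <- res$rejected$reason
  expect_setequal(
    unique(reasons),
    c("activity_above_100", "ambiguous_activity", "outside_mature",
      "stop_codon", "unparseable_activity", "assay_discrepancy",
      "ambiguous_severity", "synonymous")
  )
  # the clean rows survive with numeric activity and derived labels
  expect_true(all(c(100L, 180L) %in% res$kept$position))
  expect_equal(res$kept$severity[res$kept$position == 180L], "moderate")
})

test_that("rows with neither activity nor inhibitor information drop", {
  df <- tibble::tibble(
    position = c(10L, 20L), wt_aa = c("A", "C"), mut_aa = c("V", "W"),
    activity = c(NA, NA), severity = c("mild", "severe"),
    inhibitor = c("yes", NA)
  )
  res <- sanitize_mutations(df, "eahad")
  expect_equal(res$kept$position, 10L)
  expect_equal(res$rejected$reason, "no_activity_no_inhibitor")
})

test_that("CHAMP dialect removes duplicates and stop codons", {
  df <- tibble::tibble(
    position = c(5L, 5L, 7L, 9L, 11L),
    wt_aa = c("A", "A", "C", "D", "E"),
    mut_aa = c("V", "V", "*", "G", "K"),
    severity = c("severe", "severe", "severe", "mild/moderate", "mild")
  )
  res <- sanitize_mutations(df, "champ")
  expect_equal(sort(res$kept$position), c(5L, 11L))
  expect_setequal(res$rejected$reason,
                  c("duplicate", "stop_codon", "ambiguous_severity"))
})

test_that("sanitation is idempotent", {
  res <- sanitize_mutations(eahad_fixture(), "eahad")
  again <- sanitize_mutations(res$kept, "eahad")
  expect_equal(nrow(again$rejected), 0L)
  expect_equal(again$kept$position, res$kept$position)
  expect_equal(again$kept$activity, res$kept$activity)
})

test_that("tallies plus kept rows account for every input row on fuzzed tables", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    df <- tibble::tibble(
      position = sample(c(-5L, 50L, 500L, 3000L), n, replace = TRUE),
      wt_aa = sample(severin:::AA_ALPHABET, n, replace = TRUE),
      mut_aa = sample(c(severin:::AA_ALPHABET, "*"), n, replace = TRUE),
      activity = sample(c("12", "150", "<1", "0 to 2", "junk", NA),
                        n, replace = TRUE),
      severity = sample(c("mild", "severe", "mild/moderate", NA),
                        n, replace = TRUE),
      inhibitor = sample(c("yes", NA), n, replace = TRUE)
    )
    for (dialect in c("eahad", "champ")) {
      res <- sanitize_mutations(df, dialect)
      expect_equal(nrow(res$kept) + sum(res$tally$n), n)
    }
  }
})

test_that("column mapping renames dialect headers and flags schema gaps", {
  raw <- data.frame(Codon = 7, WT_AA = "A", Mut_AA = "V",
                    FVIII_C_1st = "3", Severity = "moderate")
  mapped <- map_mutation_columns(raw, dialect_columns("eahad"))
  expect_true(all(c("position", "wt_aa", "mut_aa", "activity",
                    "severity") %in% names(mapped)))
  expect_error(
    map_mutation_columns(data.frame(Codon = 7), dialect_columns("eahad")),
    "mandatory"
  )
})

test_that("binarization merges mild and moderate and reports counts", {
  df <- tibble::tibble(
    severity = c(rep("mild", 202), rep("moderate", 77), rep("severe", 164),
                 NA, "non_hemophilic")
  )
  out <- binarize_severity(df)
  expect_equal(attr(out, "class_counts"),
               c(mild_moderate = 279L, severe = 164L))
  expect_equal(attr(out, "n_excluded"), 2L)

  expect_warning(binarize_severity(tibble::tibble(severity = rep("severe", 3))),
                 "one severity class")
  empty <- binarize_severity(tibble::tibble(severity = character(0)))
  expect_equal(nrow(empty), 0L)
  expect_equal(unname(attr(empty, "class_counts")), c(0L, 0L))
})
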