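# Curation of clinical mutation tables: activity normalization,
# sanitation rules, severity labeling.

# Clinical severity bands on FVIII:C activity (% of normal), half-open
# at the boundaries the literature leaves overlapping:
# severe [0,1), moderate [1,5), mild [5,40]; above 40 is non-hemophilic.
SEVERITY_BANDS <- list(severe = c(0, 1), moderate = c(1, 5), mild = c(5, 40))

#' Label hemophilia severity from clotting activity
#'
#' Maps FVIII:C activity (% of normal) to the clinical bands: severe
#' below 1%, moderate in \[1, 5), mild in \[5, 40\]. Activities above
#' 40% are labeled `"non_hemophilic"` (excluded from modeling
#' downstream); missing activities give `NA`.
#'
#' @param activity Numeric vector of FVIII:C activities in \[0, 100\].
#' @param bands Band definition, a list like the default (upper bounds
#'   are exclusive except the mild band's 40, which is inclusive).
#' @return Character vector: `"severe"`, `"moderate"`, `"mild"`,
#'   `"non_hemophilic"`, or `NA`.
#' @export
#' @examples
#' label_severity(c(0.5, 3, 20, 75))
label_severity <- function(activity, bands = SEVERITY_BANDS) {
  if (any(activity < 0, na.rm = TRUE)) {
    stop("negative activity values are outside the domain", call. = FALSE)
  }
  out <- rep(NA_character_, length(activity))
  out[activity >= bands$severe[1] & activity < bands$severe[2]] <- "severe"
  out[activity >= bands$moderate[1] & activity < bands$moderate[2]] <- "moderate"
  out[activity >= bands$mild[1] & activity <= bands$mild[2]] <- "mild"
  out[activity > bands$mild[2]] <- "non_hemophilic"
  out
}

# Sentinel strings that clinical tables use in the activity column and
# their fixed substitutions.
ACTIVITY_SENTINELS <- c("&gt;5" = 5, ">5" = 5, "<10" = 10, "<11" = 11,
                        "<1" = 0, "&lt;1" = 0)

parse_plain_number <- function(s) {
  s <- gsub("%", "", s, fixed = TRUE)
  suppressWarnings(as.numeric(s))
}

# Resolve one endpoint of a range: sentinel first, then plain number.
parse_endpoint <- function(s) {
  s <- trimws(s)
  if (s %in% names(ACTIVITY_SENTINELS)) {
    return(unname(ACTIVITY_SENTINELS[s]))
  }
  parse_plain_number(s)
}

normalize_activity_one <- function(raw) {
  reject <- function(reason) {
    list(value = NA_real_, rejected = TRUE, reason = reason)
  }
  ok <- function(value) list(value = value, rejected = FALSE,
                             reason = NA_character_)

  if (is.na(raw)) return(reject("missing"))
  s <- trimws(as.character(raw))
  if (s == "" || toupper(s) %in% c("NA", "N/A", "-", "?")) {
    return(reject("missing"))
  }
  if (s %in% names(ACTIVITY_SENTINELS)) {
    return(ok(unname(ACTIVITY_SENTINELS[s])))
  }
  v <- parse_plain_number(s)
  if (!is.na(v)) {
    if (v < 0) return(reject("negative"))
    return(ok(v))
  }
  # range forms: "a-b", "a–b", "a to b" (endpoints may be sentinels)
  parts <- strsplit(s, "\\s*(–|—|--|-|\\bto\\b)\\s*")[[1]]
  parts <- parts[parts != ""]
  if (length(parts) == 2L) {
    a <- parse_endpoint(parts[1])
    b <- parse_endpoint(parts[2])
    if (!is.na(a) && !is.na(b)) {
      if (a < 0 || b < 0) return(reject("negative"))
      # a range is usable only when both ends give the same diagnosis
      band_a <- label_severity(a)
      band_b <- label_severity(b)
      if (identical(band_a, band_b)) return(ok((a + b) / 2))
      return(reject("ambiguous"))
    }
  }
  # other inequality forms ("<2", ">30", ...) leave the diagnosis open
  if (grepl("^[<>≤≥]", s)) return(reject("ambiguous"))
  reject("unparseable")
}

#' Normalize raw FVIII:C activity strings
#'
#' Deterministic mapping of verbatim activity cells to percent values:
#' fixed sentinel substitutions (`">5"` to 5, `"<10"` to 10, `"<11"` to
#' 11, `"<1"` to 0), plain numbers passed through, and ranges
#' (`"10-24"`, `"10–24"`, `"a to b"`) replaced by their midpoint
#' when both endpoints fall in the same severity band. Ranges whose
#' endpoints imply different diagnoses (e.g. `"0 to 2"`) and
#' inequalities not on the sentinel list (e.g. `"<2"`) are rejected as
#' ambiguous; anything else non-numeric is rejected as unparseable.
#'
#' @param raw Character vector of verbatim activity cells.
#' @return A tibble with columns `activity_raw`, `activity` (numeric or
#'   `NA`), `rejected` (logical) and `reason` (`"missing"`,
#'   `"ambiguous"`, `"unparseable"`, `"negative"`, or `NA`).
#' @export
#' @examples
#' normalize_activity(c("10–24", ">5", "<1", "0 to 2", "abc"))
normalize_activity <- function(raw) {
  res <- lapply(raw, normalize_activity_one)
  tibble::tibble(
    activity_raw = as.character(raw),
    activity = vapply(res, `[[`, numeric(1), "value"),
    rejected = vapply(res, `[[`, logical(1), "rejected"),
    reason = vapply(res, `[[`, character(1), "reason")
  )
}

STOP_CODES <- c("*", "X", "TER", "STOP")

is_ambiguous_severity <- function(sev) {
  !is.na(sev) & grepl("/", sev, fixed = TRUE)
}

#' Column maps for the supported clinical table dialects
#'
#' Returns the mapping from canonical record fields (`position`,
#' `wt_aa`, `mut_aa`, `activity`, `activity_2nd`, `severity`,
#' `inhibitor`, `mutation_type`, `effect`) to the column names used by
#' each database export dialect. Pass the result (possibly edited) to
#' [map_mutation_columns()].
#'
#' @param dialect `"eahad"` or `"champ"`.
#' @return Named character vector (canonical = source column).
#' @export
dialect_columns <- function(dialect = c("eahad", "champ")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    eahad = c(position = "Codon", wt_aa = "WT_AA", mut_aa = "Mut_AA",
              activity = "FVIII_C_1st", activity_2nd = "FVIII_C_2st",
              severity = "Severity", inhibitor = "Inhibitor",
              mutation_type = "Type", effect = "Effect"),
    champ = c(position = "Mature_Position", wt_aa = "WT_AA",
              mut_aa = "Mut_AA", severity = "Reported_Severity",
              mutation_type = "Mutation_Type", effect = "Effect")
  )
}

#' Rename dialect columns to canonical names
#'
#' @param records A data frame as exported by the source database.
#' @param map Named character vector, canonical name = source column, as
#'   from [dialect_columns()]; entries absent from `records` whose
#'   canonical field is optional are skipped, missing mandatory columns
#'   (`position`, `wt_aa`, `mut_aa`) raise a schema error.
#' @return Tibble with canonical column names.
#' @export
map_mutation_columns <- function(records, map) {
  mandatory <- c("position", "wt_aa", "mut_aa")
  present <- map[map %in% names(records)]
  missing_mand <- setdiff(mandatory, names(present))
  if (length(missing_mand) > 0L) {
    stop("input table lacks mandatory column(s): ",
         paste(map[missing_mand], collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(records)[, unname(present)]
  names(out) <- names(present)
  out$position <- as.integer(out$position)
  out
}

#' Sanitize a clinical mutation table
#'
#' Applies the per-dialect cleaning rules in a fixed order, attributing
#' every dropped row to exactly one named rule. For EAHAD-style tables:
#' query-scope filter (point/polymorphism + missense where those
#' columns exist), mature-protein range check, activity above 100%,
#' unparseable activity, ambiguous activity, rows with neither activity
#' nor inhibitor information, first- vs second-assay discrepancies
#' (different severity bands), stop codons, and ambiguously reported
#' severity labels. For CHAMP-style tables: scope filter, ambiguous
#' severity, duplicate (position, wt, mut) triples, stop codons, and
#' out-of-range positions. Kept records carry the normalized `activity`
#' and a `severity` label derived from activity when available,
#' otherwise the reported label (lowercased).
#'
#' @param records Tibble with canonical columns (see
#'   [map_mutation_columns()]); `position` must be mature-protein
#'   numbering.
#' @param dialect `"eahad"` or `"champ"`.
#' @param protein_length Length of the mature protein (FVIII: 2332).
#' @return A list with `kept` (curated tibble), `rejected` (dropped rows
#'   plus `reason`), and `tally` (tibble of reason counts; the tally sum
#'   plus kept rows equals the input row count).
#' @export
sanitize_mutations <- function(records, dialect = c("eahad", "champ"),
                               protein_length = 2332L) {
  dialect <- match.arg(dialect)
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  has <- function(col) col %in% names(records)
  mark <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }

  records$wt_aa <- toupper(records$wt_aa)
  records$mut_aa <- toupper(records$mut_aa)

  if (has("mutation_type")) {
    ok_type <- grepl("point|polymorphism|missense|substitution",
                     records$mutation_type, ignore.case = TRUE)
    mark(!ok_type, "out_of_scope")
  }
  if (has("effect")) {
    mark(!grepl("missense", records$effect, ignore.case = TRUE),
         "out_of_scope")
  }
  mark(records$wt_aa == records$mut_aa, "synonymous")

  if (dialect == "eahad") {
    mark(is.na(records$position) | records$position < 1L |
           records$position > protein_length, "outside_mature")

    act <- normalize_activity(if (has("activity")) records$activity else
      rep(NA_character_, n))
    act2 <- normalize_activity(if (has("activity_2nd"))
      records$activity_2nd else rep(NA_character_, n))

    mark(act$activity > 100 | act2$activity > 100, "activity_above_100")
    mark(act$reason %in% "unparseable", "unparseable_activity")
    mark(act$reason %in% c("ambiguous", "negative"), "ambiguous_activity")

    inhib <- if (has("inhibitor")) {
      !is.na(records$inhibitor) & trimws(records$inhibitor) != ""
    } else rep(FALSE, n)
    mark(is.na(act$activity) & is.na(act2$activity) & !inhib,
         "no_activity_no_inhibitor")

    both <- !is.na(act$activity) & !is.na(act2$activity)
    discrepant <- both &
      label_severity(pmax(act$activity, 0)) !=
      label_severity(pmax(act2$activity, 0))
    mark(discrepant, "assay_discrepancy")

    mark(records$mut_aa %in% STOP_CODES, "stop_codon")
    if (has("severity")) {
      mark(is_ambiguous_severity(records$severity), "ambiguous_severity")
    }
    records$activity <- act$activity
  } else {
    if (has("severity")) {
      mark(is_ambiguous_severity(records$severity), "ambiguous_severity")
    }
    dup <- duplicated(records[, c("position", "wt_aa", "mut_aa")])
    mark(dup, "duplicate")
    mark(records$mut_aa %in% STOP_CODES, "stop_codon")
    mark(is.na(records$position) | records$position < 1L |
           records$position > protein_length, "outside_mature")
    if (!has("activity")) records$activity <- NA_real_
    records$activity <- suppressWarnings(as.numeric(records$activity))
  }

  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]

  sev <- label_severity(pmax(kept$activity, 0))
  if ("severity" %in% names(kept)) {
    reported <- tolower(trimws(kept$severity))
    reported[!reported %in% c("mild", "moderate", "severe")] <- NA_character_
    sev[is.na(sev)] <- reported[is.na(sev)]
  }
  kept$severity <- sev

  tally <- dplyr::count(tibble::tibble(reason = rejected$reason),
                        .data$reason, name = "n")
  list(kept = kept, rejected = rejected, tally = tally)
}

#' Collapse ternary severity to the two modeling classes
#'
#' Merges mild and moderate into one class against severe. Records with
#' missing severity or labeled non-hemophilic are excluded and counted.
#'
#' @param records Tibble with a `severity` column.
#' @return The records restricted to the two classes with an added
#'   `label` factor (`mild_moderate`, `severe`); attributes
#'   `class_counts` (named integer) and `n_excluded`. Warns when only
#'   one class remains.
#' @export
binarize_severity <- function(records) {
  usable <- records$severity %in% c("mild", "moderate", "severe")
  out <- records[usable, , drop = FALSE]
  out$label <- factor(
    ifelse(out$severity == "severe", "severe", "mild_moderate"),
    levels = c("mild_moderate", "severe")
  )
  counts <- table(out$label)
  if (nrow(out) > 0L && any(counts == 0L)) {
    warning("only one severity class present after binarization",
            call. = FALSE)
  }
  attr(out, "class_counts") <- stats::setNames(as.integer(counts),
                                               names(counts))
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' Write curated records and a rejection report
#'
#' @param sanitized Result of [sanitize_mutations()].
#' @param csv_file Path for the curated CSV.
#' @param report_file Optional path for a JSON rejection report
#'   (requires jsonlite).
#' @return `sanitized`, invisibly.
#' @export
write_curated <- function(sanitized, csv_file, report_file = NULL) {
  utils::write.csv(sanitized$kept, csv_file, row.names = FALSE, na = "")
  if (!is.null(report_file)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required to write the rejection report",
           call. = FALSE)
    }
    jsonlite::write_json(
      list(n_input = nrow(sanitized$kept) + nrow(sanitized$rejected),
           n_kept = nrow(sanitized$kept),
           tally = sanitized$tally),
      report_file, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(sanitized)
}
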