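#' Construct a response matrix
#'
#' Wraps a persons-by-items grid of ordinal responses together with person
#' identifiers and optional covariates. Internally all responses are coded
#' `0 .. m_i`; `NA` marks a missing response. Column order follows
#' `spec$items`.
#'
#' @param responses integer matrix (persons x items) of internal 0-based
#'   codes, `NA` for missing; columns in the order of `spec$items`.
#' @param spec a [scale_spec()].
#' @param person_ids optional character vector of person identifiers.
#' @param covariates optional data frame of per-person covariates (e.g.
#'   `age`, `group`).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, spec, person_ids = NULL,
                            covariates = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (ncol(responses) != length(spec$items))
    stop("response grid has ", ncol(responses), " columns but the spec has ",
         length(spec$items), " items")
  colnames(responses) <- spec$items
  mi <- spec_max_codes(spec)
  for (j in seq_along(spec$items)) {
    v <- responses[, j]
    bad <- which(!is.na(v) & (v < 0L | v > mi[j]))
    if (length(bad))
      stop("item ", spec$items[j], ": internal code out of range [0, ",
           mi[j], "] for person(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  n <- nrow(responses)
  if (is.null(person_ids)) person_ids <- sprintf("P%04d", seq_len(n))
  person_ids <- as.character(person_ids)
  if (length(person_ids) != n) stop("person_ids length mismatch")
  rownames(responses) <- person_ids
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates row count mismatch")
  } else {
    covariates <- data.frame(row.names = person_ids)
  }
  structure(
    list(responses = responses, person_ids = person_ids,
         covariates = covariates, spec = spec),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix: ", nrow(x$responses), " persons x ",
      ncol(x$responses), " items", sep = "")
  nmiss <- sum(is.na(x$responses))
  if (nmiss) cat(" (", nmiss, " missing cells)", sep = "")
  if (ncol(x$covariates))
    cat("; covariates: ", paste(names(x$covariates), collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Subset persons of a response matrix
#'
#' @param x a [response_matrix()].
#' @param i person index (integer, logical or id).
#' @param ... unused.
#' @return a [response_matrix()] with the selected persons.
#' @export
`[.response_matrix` <- function(x, i, ...) {
  response_matrix(x$responses[i, , drop = FALSE], x$spec,
                  person_ids = x$person_ids[i],
                  covariates = x$covariates[i, , drop = FALSE])
}

#' Read a response CSV file
#'
#' Expects a header row holding the item identifiers of `spec` (order free;
#' columns are re-ordered to match), plus any number of covariate columns
#' (e.g. `age`, `id`). Item cells must be integers in
#' `[min_code, max_code]` or empty (missing). External codes are shifted to
#' internal 0-based codes.
#'
#' @param path CSV file path.
#' @param spec a [scale_spec()].
#' @param id_column optional name of a column holding person identifiers.
#' @return a [response_matrix()].
#' @export
load_responses <- function(path, spec, id_column = "id") {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = "")
  missing_items <- setdiff(spec$items, names(df))
  if (length(missing_items))
    stop("response file lacks item column(s): ",
         paste(missing_items, collapse = ", "))
  mi <- spec_max_codes(spec)
  resp <- matrix(NA_integer_, nrow(df), length(spec$items))
  for (j in seq_along(spec$items)) {
    item <- spec$items[j]
    raw <- df[[item]]
    filled <- !is.na(raw)
    num <- suppressWarnings(as.numeric(raw[filled]))
    if (anyNA(num) || any(num != round(num))) {
      row <- which(filled)[which(is.na(num) | num != round(num))[1L]]
      stop("non-integer value in item ", item, ", row ", row)
    }
    lo <- spec$min_code
    hi <- spec$min_code + mi[j]
    if (any(num < lo | num > hi)) {
      row <- which(filled)[which(num < lo | num > hi)[1L]]
      stop("value out of range [", lo, ", ", hi, "] in item ", item,
           ", row ", row)
    }
    resp[filled, j] <- as.integer(num - lo)
  }
  cov_cols <- setdiff(names(df), c(spec$items, id_column))
  covariates <- if (length(cov_cols)) {
    cv <- df[cov_cols]
    cv[] <- lapply(cv, utils::type.convert, as.is = TRUE)
    cv
  } else NULL
  ids <- if (id_column %in% names(df)) df[[id_column]] else NULL
  response_matrix(resp, spec, person_ids = ids, covariates = covariates)
}

#' Write a response matrix as CSV
#'
#' The inverse of [load_responses()]: external codes, empty cells for
#' missing responses, an `id` column and all covariate columns.
#'
#' @param rm a [response_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path) {
  ext <- rm$responses + rm$spec$min_code
  df <- data.frame(id = rm$person_ids, ext, check.names = FALSE)
  if (ncol(rm$covariates)) df <- cbind(df, rm$covariates)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Keep only complete cases
#'
#' Drops persons with any missing item response or any missing value on a
#' required covariate, and tallies the exclusions by rule in a fixed order:
#' all items missing first, then one / two / three-or-more missing items,
#' then missing covariates (applied to persons whose responses are complete).
#'
#' @param rm a [response_matrix()].
#' @param required_covariates character vector of covariate names that must
#'   be non-missing (e.g. `"age"`).
#' @return list with `data` (the filtered [response_matrix()]) and `report`,
#'   an `exclusion_report` whose counts sum to `n_input - n_retained`.
#' @export
filter_complete_cases <- function(rm, required_covariates = character()) {
  miss <- rowSums(is.na(rm$responses))
  k <- ncol(rm$responses)
  missing_cov <- rep(FALSE, nrow(rm$responses))
  for (v in required_covariates) {
    if (!v %in% names(rm$covariates))
      stop("required covariate not present: ", v)
    missing_cov <- missing_cov | is.na(rm$covariates[[v]])
  }
  rule <- rep(NA_character_, length(miss))
  rule[miss == k] <- "all_items_missing"
  rule[miss >= 3 & miss < k] <- "3+_items_missing"
  rule[miss == 2] <- "2_items_missing"
  rule[miss == 1] <- "1_item_missing"
  rule[miss == 0 & missing_cov] <- "missing_covariate"
  keep <- is.na(rule)
  counts <- c(
    all_items_missing = sum(rule == "all_items_missing", na.rm = TRUE),
    `1_item_missing`  = sum(rule == "1_item_missing", na.rm = TRUE),
    `2_items_missing` = sum(rule == "2_items_missing", na.rm = TRUE),
    `3+_items_missing` = sum(rule == "3+_items_missing", na.rm = TRUE),
    missing_covariate = sum(rule == "missing_covariate", na.rm = TRUE)
  )
  report <- structure(
    list(counts = counts, n_input = length(keep), n_retained = sum(keep)),
    class = "exclusion_report"
  )
  list(data = rm[keep], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Complete-case filtering: ", x$n_input, " -> ", x$n_retained,
      " persons retained\n", sep = "")
  for (nm in names(x$counts))
    if (x$counts[nm] > 0)
      cat("  excluded, ", nm, ": ", x$counts[nm], "\n", sep = "")
  invisible(x)
}

#' Draw disjoint random person samples
#'
#' Samples persons without replacement into disjoint subsamples of the
#' requested sizes, reproducibly for a fixed seed (the cross-validation
#' device of splitting a cohort into two analysis samples).
#'
#' @param rm a [response_matrix()].
#' @param sizes integer vector of sample sizes; the sum must not exceed the
#'   number of persons.
#' @param seed integer seed.
#' @return list of [response_matrix()] objects, one per size.
#' @export
split_random_samples <- function(rm, sizes, seed) {
  sizes <- as.integer(sizes)
  n <- nrow(rm$responses)
  if (sum(sizes) > n)
    stop("requested ", sum(sizes), " persons but only ", n, " available")
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  out <- vector("list", length(sizes))
  at <- 0L
  for (s in seq_along(sizes)) {
    out[[s]] <- rm[sort(perm[at + seq_len(sizes[s])])]
    at <- at + sizes[s]
  }
  out
}

#' Median-split age grouping
#'
#' Splits a numeric age vector at its median into `"younger"` (at or below
#' the split point by default — ties go to the lower group) and `"older"`.
#'
#' @param age numeric vector.
#' @param split split point; defaults to `median(age)`.
#' @param ties_lower if `TRUE` (default) ages equal to the split point are
#'   "younger", otherwise "older".
#' @return factor with levels `younger`, `older`, plus attribute `split`.
#' @export
age_groups <- function(age, split = NULL, ties_lower = TRUE) {
  if (is.null(split)) split <- stats::median(age, na.rm = TRUE)
  younger <- if (ties_lower) age <= split else age < split
  out <- factor(ifelse(younger, "younger", "older"),
                levels = c("younger", "older"))
  attr(out, "split") <- split
  out
}
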