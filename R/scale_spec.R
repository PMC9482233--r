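#' Define a polytomous scale specification
#'
#' A scale specification describes the fixed structure of a questionnaire:
#' the ordered item identifiers, the subscale each item belongs to, the
#' number of ordered response categories per item, and the external coding
#' range used in data files. All estimation routines work on internal
#' 0-based category codes (`0 .. m_i`); external files use
#' `min_code .. max_code`.
#'
#' @param items character vector of item identifiers, in column order.
#' @param subscales character vector (same length) giving the subscale label
#'   of each item.
#' @param n_categories integer vector (recycled) with the number of ordered
#'   response categories per item; must be at least 2.
#' @param min_code,max_code integers giving the external coding range; for a
#'   scale whose items all have `k` categories, `max_code - min_code + 1`
#'   must equal `k`.
#' @return An object of class `scale_spec` with fields `items`,
#'   `subscale_of`, `n_categories` (named integer vector, `m_i + 1`),
#'   `min_code`, `max_code`.
#' @examples
#' sp <- scale_spec(c("A1", "A2", "B1"), c("A", "A", "B"), n_categories = 3)
#' sp
#' @seealso [bat_spec()] for the bundled Burnout Assessment Tool definition.
#' @export
scale_spec <- function(items, subscales, n_categories, min_code = 1L,
                       max_code = min_code + max(n_categories) - 1L) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("duplicated item identifiers")
  if (length(subscales) != length(items))
    stop("'subscales' must have one entry per item")
  n_categories <- rep_len(as.integer(n_categories), length(items))
  if (any(n_categories < 2L)) stop("every item needs at least 2 categories")
  min_code <- as.integer(min_code)
  max_code <- as.integer(max_code)
  if (max_code - min_code + 1L < max(n_categories))
    stop("external coding range narrower than the largest category count")
  structure(
    list(
      items = items,
      subscale_of = stats::setNames(as.character(subscales), items),
      n_categories = stats::setNames(n_categories, items),
      min_code = min_code,
      max_code = max_code
    ),
    class = "scale_spec"
  )
}

#' @export
print.scale_spec <- function(x, ...) {
  tab <- table(factor(x$subscale_of, levels = unique(x$subscale_of)))
  cat("Scale specification: ", length(x$items), " items in ",
      length(tab), " subscale(s)\n", sep = "")
  cat("  ", paste0(names(tab), "=", as.integer(tab), collapse = ", "), "\n",
      sep = "")
  cat("  categories per item: ",
      paste(sort(unique(x$n_categories)), collapse = ", "),
      "; external coding ", x$min_code, "..", x$max_code, "\n", sep = "")
  invisible(x)
}

#' Maximum internal category code per item
#'
#' @param spec a [scale_spec()].
#' @return named integer vector `m_i = n_categories - 1`.
#' @keywords internal
spec_max_codes <- function(spec) spec$n_categories - 1L

#' The Burnout Assessment Tool scale definition
#'
#' The 23-item Burnout Assessment Tool (BAT): four subscales — exhaustion
#' (EX, 8 items), mental distance (MD, 5 items), cognitive impairment
#' (CI, 5 items) and emotional impairment (EI, 5 items) — each item rated on
#' five frequency categories coded 1 ("never") to 5 ("always") externally,
#' 0 to 4 internally.
#'
#' @return A [scale_spec()] for the BAT.
#' @examples
#' bat_spec()
#' @export
bat_spec <- function() {
  items <- c(paste0("EX", 1:8), paste0("MD", 1:5),
             paste0("CI", 1:5), paste0("EI", 1:5))
  scale_spec(
    items = items,
    subscales = substr(items, 1L, 2L),
    n_categories = 5L,
    min_code = 1L,
    max_code = 5L
  )
}

#' Subscale membership as an index list
#'
#' @param spec a [scale_spec()].
#' @return named list mapping each subscale label to the integer column
#'   indices of its items.
#' @export
subscale_index <- function(spec) {
  subs <- spec$subscale_of
  labs <- unique(subs)
  lapply(stats::setNames(labs, labs), function(s) which(subs == s))
}

#' Read a scale specification from a JSON config
#'
#' The config holds `items` (array of identifiers), `subscales` (array of
#' labels, parallel to `items`), `n_categories` (scalar or per-item array)
#' and optional `min_code` / `max_code`. The bundled BAT definition ships
#' as `system.file("extdata", "bat_spec.json", package = "pcmval")`.
#'
#' @param path JSON file path.
#' @return a [scale_spec()].
#' @examples
#' sp <- read_scale_spec(system.file("extdata", "bat_spec.json",
#'                                   package = "pcmval"))
#' identical(sp, bat_spec())
#' @export
read_scale_spec <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("items", "subscales", "n_categories"))
    if (is.null(cfg[[f]])) stop("scale config lacks field: ", f)
  min_code <- cfg$min_code %||% 1L
  scale_spec(cfg$items, cfg$subscales, cfg$n_categories,
             min_code = min_code,
             max_code = cfg$max_code %||%
               (min_code + max(cfg$n_categories) - 1L))
}
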