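#' Construct an item bank
#'
#' An item bank is the calibrated set of polytomous questionnaire items a
#' test session draws from.  Each item carries a Rasch partial-credit-model
#' parameterisation: an overall difficulty in logits and `n_steps` ordered
#' step thresholds whose mean equals the difficulty.  Items may additionally
#' carry a conditional route map (skip logic): a mapping from an answer
#' category to the item asked next.  Items flagged `in_pool` form the
#' adaptive-testing pool; skip items are never pool members.
#'
#' @param items data.frame with columns `item_id` (integer, unique), `text`
#'   (character), `n_steps` (integer >= 1, the number of score steps; the
#'   maximum category score equals `n_steps`), `difficulty` (logits) and
#'   `in_pool` (logical).
#' @param thresholds named list (names = `item_id`) of numeric threshold
#'   vectors, one per item, each of length `n_steps`.  If `NULL`, thresholds
#'   are generated symmetrically around each difficulty with
#'   `threshold_spacing` logits between adjacent steps, so that their mean
#'   reproduces the difficulty exactly.
#' @param routes named list (names = `item_id`) of named integer vectors
#'   mapping answer category codes to the `item_id` asked next.  Items absent
#'   from the list (or mapped to an empty vector) are ordinary items that
#'   fall through to the next item in bank order.
#' @param threshold_spacing logit distance between adjacent generated step
#'   thresholds (ignored when `thresholds` is supplied).
#'
#' @return An object of class `item_bank`: a list with elements `items`
#'   (the validated data.frame, file/questionnaire order preserved),
#'   `thresholds`, `routes` and `pool_ids`.
#' @export
item_bank <- function(items, thresholds = NULL, routes = NULL,
                      threshold_spacing = 1.0) {
  required <- c("item_id", "text", "n_steps", "difficulty", "in_pool")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("item bank is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  items$item_id <- as.integer(items$item_id)
  items$n_steps <- as.integer(items$n_steps)
  items$difficulty <- as.numeric(items$difficulty)
  items$in_pool <- as.logical(items$in_pool)
  rownames(items) <- NULL

  if (anyNA(items$item_id)) stop("item_id must be integer and non-missing")
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0L) {
    stop("duplicate item_id in bank: ", paste(unique(dup), collapse = ", "))
  }
  bad_steps <- which(is.na(items$n_steps) | items$n_steps < 1L)
  if (length(bad_steps) > 0L) {
    stop("n_steps must be >= 1; offending row(s): ",
         paste(bad_steps, collapse = ", "))
  }
  if (anyNA(items$difficulty)) stop("difficulty must be numeric, non-missing")

  ids <- as.character(items$item_id)
  if (is.null(thresholds)) thresholds <- stats::setNames(vector("list", 0L), character())
  thr <- vector("list", nrow(items))
  names(thr) <- ids
  for (r in seq_len(nrow(items))) {
    id <- ids[r]
    m <- items$n_steps[r]
    tv <- thresholds[[id]]
    if (is.null(tv) || length(tv) == 0L || all(is.na(tv))) {
      tv <- symmetric_thresholds(items$difficulty[r], m, threshold_spacing)
    }
    tv <- as.numeric(tv)
    if (length(tv) != m) {
      stop("item ", id, ": ", length(tv), " thresholds supplied but n_steps = ", m)
    }
    if (abs(mean(tv) - items$difficulty[r]) > 1e-9) {
      stop("item ", id, ": mean of step thresholds (", mean(tv),
           ") does not equal the stated difficulty (", items$difficulty[r], ")")
    }
    thr[[id]] <- tv
  }

  if (is.null(routes)) routes <- list()
  rmap <- vector("list", nrow(items))
  names(rmap) <- ids
  for (r in seq_len(nrow(items))) {
    id <- ids[r]
    rv <- routes[[id]]
    if (is.null(rv) || length(rv) == 0L) {
      rmap[[id]] <- stats::setNames(integer(0), character())
      next
    }
    keys <- suppressWarnings(as.integer(names(rv)))
    targets <- as.integer(rv)
    if (anyNA(keys)) stop("item ", id, ": route answer codes must be integers")
    if (any(keys < 0L | keys > items$n_steps[r])) {
      stop("item ", id, ": route answer code outside valid categories 0..",
           items$n_steps[r])
    }
    if (!all(targets %in% items$item_id)) {
      stop("item ", id, ": route target(s) ",
           paste(setdiff(targets, items$item_id), collapse = ", "),
           " not present in the bank")
    }
    if (items$in_pool[r]) {
      stop("item ", id, ": pool items must not carry a route map ",
           "(skip items are excluded from the adaptive pool)")
    }
    rmap[[id]] <- stats::setNames(targets, as.character(keys))
  }

  structure(
    list(items = items, thresholds = thr, routes = rmap,
         pool_ids = items$item_id[items$in_pool]),
    class = "item_bank"
  )
}

#' Symmetric step thresholds around a difficulty
#'
#' Generates `n_steps` thresholds centred on `difficulty` with fixed spacing,
#' e.g. one step gives `[d]`, two steps `[d - s/2, d + s/2]`, three steps
#' `[d - s, d, d + s]`.  The mean of the generated thresholds equals the
#' difficulty by construction, so an item calibrated only by its overall
#' difficulty and category count acquires a full partial-credit
#' parameterisation.
#'
#' @param difficulty item difficulty in logits.
#' @param n_steps number of score steps (>= 1).
#' @param spacing logit distance between adjacent thresholds.
#' @return numeric vector of length `n_steps`.
#' @export
symmetric_thresholds <- function(difficulty, n_steps, spacing = 1.0) {
  difficulty + spacing * (seq_len(n_steps) - (n_steps + 1) / 2)
}

#' Load an item bank from file
#'
#' Reads the bank schema from delimited text (CSV with header) or an
#' equivalent structured JSON file.  Columns / fields: `item_id`, `text`,
#' `n_steps`, `difficulty`, `in_pool`, optional `thresholds`
#' (semicolon-joined logits; generated symmetrically when empty) and optional
#' `routes` (semicolon-joined `answer:target` pairs, empty for ordinary
#' items).
#'
#' @param path file path.
#' @param format `"delimited"` (CSV) or `"structured"` (JSON).
#' @param threshold_spacing spacing used when thresholds must be generated.
#' @return validated [item_bank()], rows in file order.
#' @export
load_item_bank <- function(path, format = c("delimited", "structured"),
                           threshold_spacing = 1.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("item bank file not found: ", path)
  if (format == "delimited") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
    for (cn in names(raw)) raw[[cn]] <- as.character(raw[[cn]])
  }
  required <- c("item_id", "text", "n_steps", "difficulty", "in_pool")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("item bank file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  items <- data.frame(
    item_id = suppressWarnings(as.integer(raw$item_id)),
    text = raw$text,
    n_steps = suppressWarnings(as.integer(raw$n_steps)),
    difficulty = suppressWarnings(as.numeric(raw$difficulty)),
    in_pool = as.logical(toupper(raw$in_pool)),
    stringsAsFactors = FALSE
  )
  if (anyNA(items$item_id)) {
    stop("missing or non-integer item_id in row(s): ",
         paste(which(is.na(items$item_id)), collapse = ", "))
  }
  ids <- as.character(items$item_id)

  thresholds <- NULL
  if ("thresholds" %in% names(raw)) {
    thresholds <- lapply(raw$thresholds, function(s) {
      if (is.na(s) || !nzchar(s)) return(NULL)
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
    })
    names(thresholds) <- ids
  }
  routes <- NULL
  if ("routes" %in% names(raw)) {
    routes <- lapply(raw$routes, parse_route_string)
    names(routes) <- ids
  }
  item_bank(items, thresholds = thresholds, routes = routes,
            threshold_spacing = threshold_spacing)
}

# "1:40;2:41" -> c(`1` = 40L, `2` = 41L); empty string -> NULL
parse_route_string <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(NULL)
  pairs <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  bad <- vapply(pairs, length, integer(1)) != 2L
  if (any(bad)) stop("malformed route specification: ", s)
  stats::setNames(
    vapply(pairs, function(p) as.integer(p[2L]), integer(1)),
    vapply(pairs, function(p) p[1L], character(1))
  )
}

#' Save an item bank to file
#'
#' Writes the same schema [load_item_bank()] reads; a save/load round trip
#' reproduces every field.
#'
#' @param bank an [item_bank()].
#' @param path output path.
#' @param format `"delimited"` or `"structured"`.
#' @return `path`, invisibly.
#' @export
save_item_bank <- function(bank, path, format = c("delimited", "structured")) {
  format <- match.arg(format)
  stopifnot(inherits(bank, "item_bank"))
  ids <- as.character(bank$items$item_id)
  out <- bank$items
  out$thresholds <- vapply(ids, function(id) {
    paste(format(bank$thresholds[[id]], digits = 17, trim = TRUE,
                 scientific = FALSE), collapse = ";")
  }, character(1))
  out$routes <- vapply(ids, function(id) {
    rv <- bank$routes[[id]]
    if (length(rv) == 0L) return("")
    paste(paste0(names(rv), ":", rv), collapse = ";")
  }, character(1))
  if (format == "delimited") {
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = FALSE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' The bundled 24-item inpatient-experience bank
#'
#' Returns the packaged adaptive-testing pool: 24 polytomous items covering
#' ward environment, doctors, nurses, patient care and treatment, each with a
#' calibrated difficulty in logits and one to three score steps.  Step
#' thresholds are generated by the symmetric-spread rule
#' ([symmetric_thresholds()]) so that each item's threshold mean equals its
#' published difficulty.
#'
#' @param threshold_spacing logit spacing between generated step thresholds.
#' @return an [item_bank()] of 24 pool items.
#' @export
default_nhs_bank <- function(threshold_spacing = 1.0) {
  path <- system.file("extdata", "nhs24_bank.csv", package = "pcmcat",
                      mustWork = TRUE)
  load_item_bank(path, "delimited", threshold_spacing = threshold_spacing)
}

#' A small synthetic bank demonstrating conditional-path routing
#'
#' Six synthetic items with two skip items whose answers redirect the
#' questionnaire flow; the bank exists to exercise [route_next_item()] and is
#' not part of any calibrated instrument.
#'
#' @return an [item_bank()] of 6 non-pool items.
#' @export
demo_routing_bank <- function() {
  path <- system.file("extdata", "routing_demo_synthetic.csv",
                      package = "pcmcat", mustWork = TRUE)
  load_item_bank(path, "delimited")
}

#' @export
print.item_bank <- function(x, ...) {
  cat("Item bank:", nrow(x$items), "items,",
      length(x$pool_ids), "in the adaptive pool\n")
  n_routed <- sum(vapply(x$routes, length, integer(1)) > 0L)
  if (n_routed > 0L) cat("  skip items with routing:", n_routed, "\n")
  cat("  difficulty range:",
      paste(format(range(x$items$difficulty), digits = 3), collapse = " to "),
      "logits\n")
  invisible(x)
}

# internal accessors -------------------------------------------------------

bank_row <- function(bank, item_id) {
  r <- match(item_id, bank$items$item_id)
  if (is.na(r)) stop("item ", item_id, " not present in the bank")
  r
}

bank_thresholds <- function(bank, item_id) {
  bank$thresholds[[as.character(item_id)]]
}

bank_max_score <- function(bank, item_id) {
  bank$items$n_steps[bank_row(bank, item_id)]
}
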