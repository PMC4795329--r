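#' Stopping rules for an adaptive session
#'
#' Three rules, combined with OR and checked in fixed precedence after each
#' response: (a) person reliability of the current estimate reaches
#' `reliability_target`; (b) at least `min_items` items answered and the mean
#' absolute change over the last `window` theta updates falls below
#' `residual_threshold`; (c) the pool is exhausted or `max_items` reached.
#' The reliability rule carries no minimum-item gate; only the residual rule
#' is gated behind `min_items`.
#'
#' @param min_items minimum answered items before the residual rule may fire.
#' @param reliability_target person-reliability stopping target in (0, 1).
#' @param residual_threshold logit threshold on the mean of the last `window`
#'   absolute theta changes.
#' @param window number of theta changes averaged by the residual rule.
#' @param max_items hard cap on administered items (`NULL` = pool size).
#' @return object of class `cat_rules`.
#' @export
cat_rules <- function(min_items = 5L, reliability_target = 0.80,
                      residual_threshold = 0.05, window = 5L,
                      max_items = NULL) {
  stopifnot(min_items >= 1L,
            reliability_target > 0, reliability_target < 1,
            residual_threshold > 0, window >= 1L)
  structure(list(min_items = as.integer(min_items),
                 reliability_target = reliability_target,
                 residual_threshold = residual_threshold,
                 window = as.integer(window),
                 max_items = if (is.null(max_items)) NULL else as.integer(max_items)),
            class = "cat_rules")
}

#' Select the next adaptive item
#'
#' The first item is drawn uniformly at random from the pool; every later
#' item is the not-yet-administered pool item with maximal information
#' (score variance) at the provisional ability, ties broken toward the lowest
#' item_id.
#'
#' @param provisional_theta current ability estimate, logits.
#' @param administered item_ids already asked.
#' @param bank an [item_bank()].
#' @param first logical; draw the opening item at random?
#' @return the selected item_id (integer).
#' @export
select_next_item <- function(provisional_theta, administered, bank,
                             first = FALSE) {
  stopifnot(inherits(bank, "item_bank"))
  remaining <- setdiff(bank$pool_ids, administered)
  if (length(remaining) == 0L) stop("item pool exhausted: no items remain")
  if (first) return(remaining[sample.int(length(remaining), 1L)])
  info <- vapply(remaining, function(id) {
    pcm_moments(provisional_theta, bank$thresholds[[as.character(id)]])[2L]
  }, numeric(1))
  best <- info >= max(info) - 1e-12
  min(remaining[best])
}

#' Evaluate the stopping rules against a session state
#'
#' @param session a [run_cat()] session (or any list with `administered`,
#'   `theta_history` and a `final` estimate carrying `reliability`).
#' @param rules a [cat_rules()].
#' @param pool_size number of items in the adaptive pool.
#' @return list `stop` (logical) and `reason` (`"reliability"`, `"residual"`,
#'   `"max_items"`, `"pool_exhausted"`, or `NA`).
#' @export
should_stop <- function(session, rules, pool_size = NULL) {
  stopifnot(inherits(rules, "cat_rules"))
  n <- length(session$administered)
  if (n < 1L) stop("session has no administered items")
  if (session$final$reliability >= rules$reliability_target) {
    return(list(stop = TRUE, reason = "reliability"))
  }
  if (n >= rules$min_items &&
      length(session$theta_history) >= rules$window + 1L) {
    td <- trend_diagnostics(session$theta_history, rules$window)
    if (td$residual < rules$residual_threshold) {
      return(list(stop = TRUE, reason = "residual"))
    }
  }
  if (!is.null(rules$max_items) && n >= rules$max_items) {
    return(list(stop = TRUE, reason = "max_items"))
  }
  if (!is.null(pool_size) && n >= pool_size) {
    return(list(stop = TRUE, reason = "pool_exhausted"))
  }
  list(stop = FALSE, reason = NA_character_)
}

#' Run one adaptive test session
#'
#' Administers pool items one at a time: select (random first item, then
#' maximum information at the provisional ability), obtain the answer from
#' `respondent`, re-estimate theta by maximum likelihood over everything
#' answered so far, record the trajectory, and stop once [should_stop()]
#' fires.  The provisional ability before any answer is 0 (pool-centred
#' start).  Person fit is evaluated at the final estimate.
#'
#' @param respondent answer oracle: `function(item_id)` returning a category
#'   score valid for that item.  [cohort_respondent()] adapts a simulated
#'   cohort row into such an oracle.
#' @param bank an [item_bank()].
#' @param rules a [cat_rules()].
#' @param seed integer seed driving the random first-item draw.
#' @param theta_bound,reliability_form,theta_var passed to
#'   [estimate_theta()].
#' @return object of class `cat_session`: `administered` (ordered item_ids),
#'   `responses` (named vector), `theta_history`, `sem_history`,
#'   `stop_reason`, `final` ([estimate_theta()] result), `fit`
#'   ([person_fit()] result), `seed`.
#' @export
run_cat <- function(respondent, bank, rules = cat_rules(), seed = 1L,
                    theta_bound = 4.0,
                    reliability_form = c("printed", "conventional"),
                    theta_var = 1.0) {
  reliability_form <- match.arg(reliability_form)
  stopifnot(inherits(bank, "item_bank"), is.function(respondent))
  pool_size <- length(bank$pool_ids)
  if (pool_size == 0L) stop("bank has no pool items")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% 2147483647L)

  administered <- integer(0)
  x <- numeric(0)
  thr_list <- list()
  theta_history <- numeric(0)
  sem_history <- numeric(0)
  theta <- 0.0
  final <- NULL
  stop_reason <- NA_character_

  repeat {
    id <- select_next_item(theta, administered, bank,
                           first = length(administered) == 0L)
    ans <- respondent(id)
    max_k <- bank_max_score(bank, id)
    if (!is.numeric(ans) || length(ans) != 1L || is.na(ans) ||
        ans != round(ans) || ans < 0 || ans > max_k) {
      stop("respondent returned invalid category ", format(ans),
           " for item ", id, " (valid: 0..", max_k, ")")
    }
    administered <- c(administered, id)
    x <- c(x, as.numeric(ans))
    thr_list <- c(thr_list, bank$thresholds[as.character(id)])

    fit <- mle_theta(x, thr_list, theta_bound, start = theta)
    theta <- fit[["theta"]]
    theta_history <- c(theta_history, theta)
    sem_history <- c(sem_history, fit[["sem"]])
    final <- structure(
      list(theta = theta, sem = fit[["sem"]],
           reliability = reliability_from_sem(fit[["sem"]], reliability_form,
                                              theta_var),
           n_items = length(x), converged = as.logical(fit[["converged"]]),
           at_bound = as.logical(fit[["at_bound"]])),
      class = "person_estimate")

    verdict <- should_stop(
      list(administered = administered, theta_history = theta_history,
           final = final),
      rules, pool_size = pool_size)
    if (verdict$stop) {
      stop_reason <- verdict$reason
      break
    }
  }

  responses <- stats::setNames(as.integer(x), as.character(administered))
  session <- structure(
    list(administered = administered, responses = responses,
         theta_history = theta_history, sem_history = sem_history,
         stop_reason = stop_reason, final = final,
         fit = person_fit(responses, bank, final$theta),
         seed = as.integer(seed)),
    class = "cat_session")
  session
}

#' Answer oracle backed by a simulated cohort row
#'
#' @param cohort a [simulate_cohort()] result.
#' @param person row index of the respondent.
#' @return `function(item_id)` returning that person's pre-simulated
#'   category score.
#' @export
cohort_respondent <- function(cohort, person) {
  stopifnot(inherits(cohort, "pcm_cohort"),
            person >= 1L, person <= nrow(cohort$responses))
  row <- cohort$responses[person, ]
  function(item_id) {
    v <- row[[as.character(item_id)]]
    if (is.null(v)) stop("cohort has no responses for item ", item_id)
    v
  }
}

#' Conditional-path routing to the next questionnaire item
#'
#' Skip items carry a route map from answer categories to the item asked
#' next; ordinary items (empty route map, or an answer with no route entry)
#' fall through to the next item in bank order.  Returns `NA` at the end of
#' the questionnaire.
#'
#' @param bank an [item_bank()].
#' @param current item_id just answered.
#' @param answer category score given (validated against the item).
#' @return next item_id, or `NA_integer_` when the questionnaire ends.
#' @export
route_next_item <- function(bank, current, answer) {
  stopifnot(inherits(bank, "item_bank"))
  r <- bank_row(bank, current)
  max_k <- bank$items$n_steps[r]
  if (!is.numeric(answer) || length(answer) != 1L || is.na(answer) ||
      answer != round(answer) || answer < 0 || answer > max_k) {
    stop("answer ", format(answer), " invalid for item ", current,
         " (valid: 0..", max_k, ")")
  }
  rv <- bank$routes[[as.character(current)]]
  hit <- match(as.character(as.integer(answer)), names(rv))
  if (!is.na(hit)) return(unname(rv[hit]))
  if (r == nrow(bank$items)) return(NA_integer_)
  bank$items$item_id[r + 1L]
}

#' Impute expected responses for unanswered pool items
#'
#' Completes a finished session over the full pool: answered items keep the
#' observed categories; each unanswered pool item receives the model-expected
#' score at the final theta, rounded half-up and clipped to the item's
#' category range.  This turns a short adaptive record into a full response
#' profile usable for item-level service reporting.
#'
#' @param session a [run_cat()] result.
#' @param bank the [item_bank()] the session ran on.
#' @return named integer vector of categories covering every pool item.
#' @export
impute_unanswered <- function(session, bank) {
  stopifnot(inherits(session, "cat_session"), inherits(bank, "item_bank"))
  theta <- session$final$theta
  out <- stats::setNames(integer(length(bank$pool_ids)),
                         as.character(bank$pool_ids))
  for (id in bank$pool_ids) {
    key <- as.character(id)
    if (key %in% names(session$responses)) {
      out[[key]] <- session$responses[[key]]
    } else {
      e <- pcm_moments(theta, bank$thresholds[[key]])[1L]
      out[[key]] <- as.integer(min(max(floor(e + 0.5), 0), length(bank$thresholds[[key]])))
    }
  }
  out
}

#' Export a session trace as delimited text
#'
#' One row per administered item with the step number, item, answer, running
#' theta and SEM, and—once enough steps exist—the convergence residual and
#' trend correlation of the trajectory up to that step.
#'
#' @param session a [run_cat()] result.
#' @param path output CSV path.
#' @param window trend window passed to [trend_diagnostics()].
#' @return the trace data.frame, invisibly; written to `path` when given.
#' @export
write_session_trace <- function(session, path = NULL, window = 5L) {
  stopifnot(inherits(session, "cat_session"))
  n <- length(session$administered)
  residual <- rep(NA_real_, n)
  trend_corr <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    if (s >= window + 1L) {
      td <- trend_diagnostics(session$theta_history[seq_len(s)], window)
      residual[s] <- td$residual
      trend_corr[s] <- td$trend_corr
    }
  }
  trace <- data.frame(
    step = seq_len(n),
    item_id = session$administered,
    answer = as.integer(session$responses),
    theta = session$theta_history,
    sem = session$sem_history,
    residual = residual,
    trend_corr = trend_corr
  )
  if (!is.null(path)) utils::write.csv(trace, path, row.names = FALSE)
  invisible(trace)
}

#' @export
print.cat_session <- function(x, ...) {
  cat("Adaptive session:", length(x$administered), "items, stopped on",
      x$stop_reason, "\n")
  cat(sprintf("  final theta %.3f (SEM %.3f, reliability %.3f); outfit MNSQ %.2f%s\n",
              x$final$theta, x$final$sem, x$final$reliability,
              x$fit$outfit_mnsq,
              if (x$fit$aberrant) " [aberrant]" else ""))
  invisible(x)
}
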