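#' Maximum-likelihood person estimation
#'
#' Estimates the person measure theta from a set of polytomous responses by
#' maximising the partial-credit-model log-likelihood.  The score equation
#' `sum_i (x_i - E_i(theta)) = 0` is solved by safeguarded Newton iteration
#' (step = score / information, clamped to at most 1 logit per iteration,
#' estimate confined to `[-theta_bound, theta_bound]`).  The standard error
#' of measurement is `1/sqrt(sum_i W_i(theta_hat))`, the reciprocal square
#' root of the test information at the estimate.  Person reliability is, by
#' default, `(1 - SEM)^2` (floored at 0 for SEM >= 1); set
#' `reliability_form = "conventional"` for the usual
#' `1 - SEM^2 / Var(theta)` with `theta_var` the assumed trait variance.
#'
#' Extreme response vectors (all categories at the minimum or all at the
#' maximum) have no finite maximiser; the estimate is clamped to
#' `-theta_bound` or `+theta_bound` and flagged `at_bound`.
#'
#' @param responses named vector (or list) of category scores, names =
#'   item_ids present in `bank`.
#' @param bank an [item_bank()].
#' @param theta_bound absolute bound on the estimate, logits.
#' @param reliability_form `"printed"` for `(1 - SEM)^2`, `"conventional"`
#'   for `1 - SEM^2/theta_var`.
#' @param theta_var trait variance used by the conventional reliability form.
#' @param start starting value for the Newton iteration.
#' @return object of class `person_estimate`: list with `theta`, `sem`,
#'   `reliability`, `n_items`, `converged`, `at_bound`.
#' @export
estimate_theta <- function(responses, bank, theta_bound = 4.0,
                           reliability_form = c("printed", "conventional"),
                           theta_var = 1.0, start = 0.0) {
  reliability_form <- match.arg(reliability_form)
  stopifnot(inherits(bank, "item_bank"))
  x <- unlist(responses)
  if (length(x) == 0L) stop("at least one response is required")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("responses must be named by item_id")
  }
  unknown <- setdiff(ids, as.character(bank$items$item_id))
  if (length(unknown) > 0L) {
    stop("responses reference item(s) not in the bank: ",
         paste(unknown, collapse = ", "))
  }
  thr_list <- bank$thresholds[ids]
  max_scores <- vapply(thr_list, length, integer(1))
  x <- as.numeric(x)
  if (any(x < 0 | x > max_scores | x != round(x))) {
    stop("responses must be integer category scores within each item's range")
  }
  fit <- mle_theta(x, thr_list, theta_bound, start)
  rel <- reliability_from_sem(fit[["sem"]], reliability_form, theta_var)
  structure(
    list(theta = fit[["theta"]], sem = fit[["sem"]], reliability = rel,
         n_items = length(x), converged = as.logical(fit[["converged"]]),
         at_bound = as.logical(fit[["at_bound"]])),
    class = "person_estimate"
  )
}

# core Newton solver; x numeric scores, thr_list list of threshold vectors
mle_theta <- function(x, thr_list, bound = 4.0, start = 0.0,
                      tol = 1e-5, max_iter = 50L) {
  total <- sum(x)
  max_total <- sum(vapply(thr_list, length, integer(1)))
  if (total <= 0 || total >= max_total) {
    th <- if (total <= 0) -bound else bound
    info <- pcm_test_moments(th, thr_list)[2L]
    return(c(theta = th, sem = 1 / sqrt(info), converged = 1, at_bound = 1))
  }
  th <- min(max(start, -bound), bound)
  converged <- FALSE
  info <- NA_real_
  for (it in seq_len(max_iter)) {
    m <- pcm_test_moments(th, thr_list)
    info <- m[2L]
    step <- (total - m[1L]) / info
    if (step > 1) step <- 1 else if (step < -1) step <- -1
    new <- min(max(th + step, -bound), bound)
    delta <- new - th
    th <- new
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  info <- pcm_test_moments(th, thr_list)[2L]
  c(theta = th, sem = 1 / sqrt(info), converged = as.numeric(converged),
    at_bound = as.numeric(abs(th) >= bound - 1e-12))
}

#' Person reliability from a standard error of measurement
#'
#' The default (`"printed"`) form is `(1 - SEM)^2`, the quantity the adaptive
#' stopping rule compares against its target; it is floored at 0 once
#' SEM >= 1 so that large early-test uncertainty can never register as high
#' reliability.  The `"conventional"` form is `1 - SEM^2 / theta_var`,
#' clipped to `[0, 1]`.
#'
#' @param sem standard error of measurement, logits (> 0).
#' @param form `"printed"` or `"conventional"`.
#' @param theta_var trait variance for the conventional form.
#' @return reliability in `[0, 1]`.
#' @export
reliability_from_sem <- function(sem, form = c("printed", "conventional"),
                                 theta_var = 1.0) {
  form <- match.arg(form)
  if (!is.finite(sem) || sem < 0) return(0)
  r <- if (form == "printed") {
    if (sem >= 1) 0 else (1 - sem)^2
  } else {
    1 - sem^2 / theta_var
  }
  min(max(r, 0), 1)
}

#' Person fit statistics (infit / outfit mean squares)
#'
#' Standardised residuals `z_i = (x_i - E_i)/sqrt(W_i)` are computed at the
#' supplied theta; outfit is the unweighted mean of `z_i^2`, infit the
#' information-weighted form `sum (x_i - E_i)^2 / sum W_i`.  Values near 1
#' indicate model-consistent responding; an outfit of 2.0 or more flags a
#' possibly aberrant response pattern (careless, random or otherwise
#' inconsistent responding).  Items with numerically zero information at
#' theta are dropped from the sums with a warning.
#'
#' @inheritParams estimate_theta
#' @param theta person measure at which residuals are evaluated (finite).
#' @param aberrance_threshold outfit value at or above which the response
#'   pattern is flagged aberrant.
#' @return object of class `fit_stats`: list with `infit_mnsq`,
#'   `outfit_mnsq`, `aberrant`, `n_items`.
#' @export
person_fit <- function(responses, bank, theta, aberrance_threshold = 2.0) {
  stopifnot(inherits(bank, "item_bank"))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop("theta must be a finite numeric scalar")
  }
  x <- unlist(responses)
  if (length(x) == 0L) stop("at least one response is required")
  thr_list <- bank$thresholds[names(x)]
  if (any(vapply(thr_list, is.null, logical(1)))) {
    stop("responses reference item(s) not in the bank")
  }
  EW <- vapply(thr_list, function(thr) pcm_moments(theta, thr), numeric(2))
  E <- EW[1L, ]
  W <- EW[2L, ]
  usable <- W > 1e-12
  if (!all(usable)) {
    warning(sum(!usable), " item(s) carry zero information at theta = ",
            format(theta, digits = 4), " and were excluded from fit sums")
  }
  x <- as.numeric(x)[usable]
  E <- E[usable]
  W <- W[usable]
  if (length(x) == 0L) stop("no item retains information at this theta")
  sq <- (x - E)^2
  outfit <- mean(sq / W)
  infit <- sum(sq) / sum(W)
  structure(
    list(infit_mnsq = infit, outfit_mnsq = outfit,
         aberrant = outfit >= aberrance_threshold, n_items = length(x)),
    class = "fit_stats"
  )
}

#' Item fit statistics over a cohort
#'
#' Pools standardised residuals per item across persons: for item i,
#' outfit = mean over persons of `z_pi^2` and infit = `sum (x_pi - E_pi)^2 /
#' sum W_pi`, with expectations evaluated at each person's theta.  Used to
#' check that simulated (or observed) data meet the conventional
#' unidimensionality screen of mean squares between 0.5 and 1.5.
#'
#' @param responses persons x items integer matrix, columns named by item_id.
#' @param bank an [item_bank()].
#' @param thetas person measures, one per row of `responses`.
#' @return data.frame with columns `item_id`, `infit_mnsq`, `outfit_mnsq`.
#' @export
item_fit <- function(responses, bank, thetas) {
  stopifnot(inherits(bank, "item_bank"),
            nrow(responses) == length(thetas))
  ids <- colnames(responses)
  out <- data.frame(item_id = as.integer(ids),
                    infit_mnsq = NA_real_, outfit_mnsq = NA_real_)
  n <- nrow(responses)
  E <- matrix(0, n, length(ids))
  W <- matrix(0, n, length(ids))
  thr_list <- bank$thresholds[ids]
  for (p in seq_len(n)) {
    for (j in seq_along(ids)) {
      m <- pcm_moments(thetas[p], thr_list[[j]])
      E[p, j] <- m[1L]
      W[p, j] <- m[2L]
    }
  }
  for (j in seq_along(ids)) {
    sq <- (responses[, j] - E[, j])^2
    ok <- W[, j] > 1e-12
    out$outfit_mnsq[j] <- mean(sq[ok] / W[ok, j])
    out$infit_mnsq[j] <- sum(sq[ok]) / sum(W[ok, j])
  }
  out
}

#' Convergence diagnostics of an adaptive-session theta trajectory
#'
#' Two trend quantities over the tail of the estimate history: the residual,
#' the mean absolute change over the last five consecutive theta updates
#' (requires at least six recorded values), and the trend correlation, the
#' Pearson correlation between the last five theta values and their step
#' numbers.  A flat trajectory (zero variance over the window) has trend
#' correlation 0 by convention.  Small residuals and a flat trend indicate
#' the person measure has converged.
#'
#' @param theta_history ordered numeric vector of successive estimates.
#' @param window number of changes averaged (and values correlated).
#' @return object of class `trend_diagnostics`: list with `residual`
#'   (logits, >= 0) and `trend_corr` in `[-1, 1]`.
#' @export
trend_diagnostics <- function(theta_history, window = 5L) {
  th <- as.numeric(theta_history)
  if (length(th) < window + 1L) {
    stop("insufficient steps: need at least ", window + 1L,
         " theta values, got ", length(th))
  }
  tail_vals <- th[(length(th) - window):length(th)]
  residual <- mean(abs(diff(tail_vals)))
  last <- th[(length(th) - window + 1L):length(th)]
  trend_corr <- if (stats::sd(last) < 1e-12) 0 else
    stats::cor(last, seq_along(last))
  structure(list(residual = residual, trend_corr = trend_corr),
            class = "trend_diagnostics")
}

#' @export
print.person_estimate <- function(x, ...) {
  cat(sprintf("theta = %.3f logits (SEM %.3f, reliability %.3f, %d items)%s%s\n",
              x$theta, x$sem, x$reliability, x$n_items,
              if (x$at_bound) " [at bound]" else "",
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("infit MNSQ = %.3f, outfit MNSQ = %.3f%s (%d items)\n",
              x$infit_mnsq, x$outfit_mnsq,
              if (x$aberrant) " [aberrant pattern]" else "", x$n_items))
  invisible(x)
}
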