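#' Partial credit model category probabilities
#'
#' Under the partial credit model the probability of scoring category
#' `k` on an item with step thresholds `d[1..m]` is proportional to
#' `exp(sum_{j<=k} (theta - d[j]))`, with the empty sum (k = 0) equal to
#' zero.  All items share a common discrimination of 1 (pure Rasch
#' parameterisation).  Computation subtracts the running maximum before
#' exponentiating so the normalisation is overflow-safe at any finite theta.
#'
#' @param theta person ability in logits (finite scalar).
#' @param item either an item_id present in `bank`, or a numeric vector of
#'   step thresholds used directly.
#' @param bank an [item_bank()]; required when `item` is an id.
#' @return numeric vector of length `n_steps + 1`, probabilities of
#'   categories `0..n_steps`, summing to 1.
#' @export
category_probabilities <- function(theta, item, bank = NULL) {
  thr <- resolve_thresholds(item, bank)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop("theta must be a finite numeric scalar")
  }
  pcm_probs(theta, thr)
}

#' Expected score and information of an item
#'
#' The expected item score `E = sum k P(k)` and the item information
#' `W = sum k^2 P(k) - E^2`, i.e. the variance of the item score at theta.
#' Under the Rasch family the score variance is also the Fisher information
#' and the derivative of the expected score, so test information is additive
#' over items and the person standard error is `1/sqrt(sum W_i)`.
#'
#' @inheritParams category_probabilities
#' @return named numeric vector `c(expected, information)`.
#' @export
score_moments <- function(theta, item, bank = NULL) {
  thr <- resolve_thresholds(item, bank)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop("theta must be a finite numeric scalar")
  }
  m <- pcm_moments(theta, thr)
  c(expected = m[1L], information = m[2L])
}

resolve_thresholds <- function(item, bank) {
  if (inherits(bank, "item_bank") && length(item) == 1L &&
      !is.null(bank_thresholds(bank, item))) {
    return(bank_thresholds(bank, item))
  }
  if (is.numeric(item) && length(item) >= 1L) return(as.numeric(item))
  stop("item must be an item_id found in `bank` or a numeric threshold vector")
}

# hot-path internals: thresholds vector in, no validation ------------------

pcm_probs <- function(theta, thr) {
  s <- c(0, cumsum(theta - thr))
  e <- exp(s - max(s))
  e / sum(e)
}

pcm_moments <- function(theta, thr) {
  p <- pcm_probs(theta, thr)
  k <- 0:(length(p) - 1L)
  e <- sum(k * p)
  c(e, sum(k * k * p) - e * e)
}

# sum of expected scores and informations over a list of threshold vectors
pcm_test_moments <- function(theta, thr_list) {
  E <- 0
  W <- 0
  for (thr in thr_list) {
    m <- pcm_moments(theta, thr)
    E <- E + m[1L]
    W <- W + m[2L]
  }
  c(E, W)
}

#' Simulate a respondent cohort under the partial credit model
#'
#' Draws `n_persons` latent abilities from Normal(`theta_mean`,
#' `theta_sd`) and, for every item in the bank, a category response by
#' inverse-CDF sampling from the model probabilities at the person's true
#' ability.  Each person uses a private random substream derived
#' deterministically from `seed` and the person index, so person `i`'s
#' ability and responses do not change when the cohort is enlarged.
#'
#' @param bank an [item_bank()].
#' @param n_persons cohort size (>= 1).
#' @param theta_mean,theta_sd generating ability distribution, logits
#'   (`theta_sd > 0`).
#' @param seed integer seed; identical seeds reproduce the cohort exactly.
#' @return object of class `pcm_cohort`: list with `true_theta` (length
#'   `n_persons`), `responses` (`n_persons` x items integer matrix, columns
#'   named by item_id), `seed` and `config`.
#' @export
simulate_cohort <- function(bank, n_persons, theta_mean = 0, theta_sd = 1,
                            seed = 1L) {
  stopifnot(inherits(bank, "item_bank"))
  if (!is.numeric(n_persons) || n_persons < 1) stop("n_persons must be >= 1")
  if (!is.numeric(theta_sd) || !is.finite(theta_sd) || theta_sd <= 0) {
    stop("theta_sd must be > 0")
  }
  if (!is.finite(theta_mean)) stop("theta_mean must be finite")
  n_persons <- as.integer(n_persons)
  ids <- bank$items$item_id
  thr_list <- bank$thresholds[as.character(ids)]
  n_items <- length(ids)

  theta <- numeric(n_persons)
  resp <- matrix(NA_integer_, n_persons, n_items,
                 dimnames = list(NULL, as.character(ids)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_rng(old), add = TRUE)
  for (i in seq_len(n_persons)) {
    set.seed(person_substream(seed, i))
    th <- stats::rnorm(1L, theta_mean, theta_sd)
    theta[i] <- th
    u <- stats::runif(n_items)
    for (j in seq_len(n_items)) {
      p <- pcm_probs(th, thr_list[[j]])
      resp[i, j] <- findInterval(u[j], cumsum(p)[-length(p)]) # 0..n_steps
    }
  }
  structure(
    list(true_theta = theta, responses = resp, seed = as.integer(seed),
         config = list(n_persons = n_persons, theta_mean = theta_mean,
                       theta_sd = theta_sd, item_ids = ids)),
    class = "pcm_cohort"
  )
}

# deterministic per-person substream seed, kept inside 32-bit integer range
person_substream <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 + 48271 * as.numeric(i)) %% 2147483647)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.pcm_cohort <- function(x, ...) {
  cat("PCM cohort:", length(x$true_theta), "persons x",
      ncol(x$responses), "items (seed", x$seed, ")\n")
  cat("  true theta: mean", format(mean(x$true_theta), digits = 3),
      "sd", format(stats::sd(x$true_theta), digits = 3), "logits\n")
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' One row per person: the true ability followed by one column per item
#' (named `item_<id>`).
#'
#' @param cohort a `pcm_cohort`.
#' @param path file path.
#' @return `path` invisibly (write); a `pcm_cohort` without config echo
#'   (read).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "pcm_cohort"))
  df <- data.frame(true_theta = cohort$true_theta)
  resp <- as.data.frame(cohort$responses)
  names(resp) <- paste0("item_", colnames(cohort$responses))
  utils::write.csv(cbind(df, resp), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  item_cols <- grep("^item_", names(df), value = TRUE)
  resp <- as.matrix(df[item_cols])
  storage.mode(resp) <- "integer"
  colnames(resp) <- sub("^item_", "", item_cols)
  structure(
    list(true_theta = df$true_theta, responses = resp, seed = NA_integer_,
         config = list(n_persons = nrow(df))),
    class = "pcm_cohort"
  )
}
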