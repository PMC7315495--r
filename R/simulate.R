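#' Restricted within-stage randomization
#'
#' Allocates patients to arms with exact per-arm counts in each stage: the
#' stage-one allocation is a uniformly random permutation of a multiset
#' holding exactly \code{n_ks[k, 1]} copies of each initially open arm, and
#' the stage-two allocation likewise includes the added arm.  Counts are
#' exact in every realisation (one maximal permuted block per stage).
#'
#' Draws from the session random number generator; call \code{set.seed()}
#' first for reproducibility.
#'
#' @param design a \code{\link{trial_design}}.
#' @return integer vector of arm labels (0..K+1) in enrolment order; the
#'   first \eqn{N_1} entries are stage one.
#' @export
allocate_arms <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  n_ks <- design$n_ks
  arms <- 0:(design$K + 1L)
  pool1 <- rep.int(arms, n_ks[, 1L])
  pool2 <- rep.int(arms, n_ks[, 2L])
  c(pool1[sample.int(length(pool1))], pool2[sample.int(length(pool2))])
}

#' Evaluate the calendar-time trend for given enrolment positions
#'
#' For a linear trend the contribution is
#' \eqn{\lambda (j - 1) / (n_{tot} - 1)}, rising from 0 for the first
#' patient to \eqn{\lambda} for the last, with \eqn{n_{tot}} the full-trial
#' size including the added arm.  For a step trend it is
#' \eqn{\lambda \cdot I(\mathrm{stage} = 2)}.
#'
#' @param trend a \code{\link{trend_spec}}.
#' @param j enrolment order index (vectorised), \code{1 <= j <= total_n}.
#' @param total_n total number of patients in the trial.
#' @param stage stage indicator per position (1 or 2); required for the
#'   step family.
#' @return numeric vector of trend contributions \eqn{\tau(j)}.
#' @examples
#' trend_value(trend_spec("linear", 0.08), j = c(1, 1376), total_n = 1376)
#' @export
trend_value <- function(trend, j, total_n, stage = NULL) {
  stopifnot(inherits(trend, "trend_spec"))
  if (any(j < 1L) || any(j > total_n)) stop("`j` must lie in 1..total_n")
  switch(trend$family,
    none = rep(0, length(j)),
    linear = {
      if (total_n < 2L) stop("a linear trend needs total_n >= 2")
      trend$lam * (j - 1) / (total_n - 1)
    },
    step = {
      if (is.null(stage)) stop("the step trend needs the `stage` indicator")
      trend$lam * (stage == 2L)
    })
}

# simulation core shared by simulate_trial() and the Monte-Carlo runner;
# returns plain vectors to keep the per-replicate cost low.
simulate_vectors <- function(design, effects, trend) {
  n_ks <- design$n_ks
  total_n <- sum(n_ks)
  N1 <- sum(n_ks[, 1L])
  arm <- allocate_arms(design)
  stage <- rep.int(1:2, c(N1, total_n - N1))
  j <- seq_len(total_n)
  x <- effects$mu[arm + 1L] + trend_value(trend, j, total_n, stage)
  if (design$sigma2 > 0) x <- x + rnorm(total_n, sd = sqrt(design$sigma2))
  list(j = j, stage = stage, arm = arm, x = x)
}

#' Simulate one platform trial
#'
#' Generates patient-level responses
#' \eqn{X_j = \mu_{T_j} + \tau(j) + \epsilon_j} with
#' \eqn{\epsilon_j \sim N(0, \sigma^2)} i.i.d., arm allocation from
#' \code{\link{allocate_arms}} and an optional calendar-time trend.
#' Enrolment order \code{j} is global: stage-two indices continue from
#' \eqn{N_1 + 1}, matching the full-trial normalisation of the linear
#' trend.
#'
#' @param design a \code{\link{trial_design}}.
#' @param effects an \code{\link{effect_spec}} with \code{length(delta)}
#'   equal to \code{K + 1}.
#' @param trend a \code{\link{trend_spec}}; default no trend.
#' @return a data frame of class \code{trial_data} with one row per
#'   patient and columns \code{j}, \code{stage}, \code{arm}, \code{x}.
#' @examples
#' d <- trial_design(n_arm = c(550, 550), timing = 0.5, n_new = 275)
#' set.seed(1)
#' head(simulate_trial(d, effect_spec(0, c(0.15, 0.15))))
#' @export
simulate_trial <- function(design, effects,
                           trend = trend_spec("none")) {
  stopifnot(inherits(design, "trial_design"), inherits(effects, "effect_spec"))
  if (length(effects$delta) != design$K + 1L)
    stop("`effects$delta` must have length K + 1")
  v <- simulate_vectors(design, effects, trend)
  structure(data.frame(j = v$j, stage = v$stage, arm = v$arm, x = v$x),
            class = c("trial_data", "data.frame"))
}

#' Write simulated trial data to CSV
#'
#' Fixed header \code{j,stage,arm,response}; one row per patient.
#'
#' @param data a \code{trial_data} data frame from
#'   \code{\link{simulate_trial}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  out <- data.frame(j = data$j, stage = data$stage, arm = data$arm,
                    response = data$x)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
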