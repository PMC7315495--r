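#' Stage-wise sample sizes for a trial that adds an arm
#'
#' Splits each initially open arm's total sample size into stage-one and
#' stage-two counts according to the timing of arm addition, and appends the
#' added arm, which recruits in stage two only.
#'
#' The timing is the fraction \eqn{n_{01}/n_0} of control patients enrolled
#' before the new arm joins.  A fractional stage-one count is rounded half
#' up, so a timing of 0.25 with \eqn{n_0 = 550} gives \eqn{n_{01} = 138}.
#'
#' @param K number of initial experimental arms (control is arm 0, the
#'   added arm is arm K+1).
#' @param n_arm integer vector of total per-arm sample sizes for arms
#'   0..K (control first).
#' @param timing fraction of control patients enrolled before the new arm
#'   is added; strictly between 0 and 1, and such that at least one control
#'   patient falls in each stage.
#' @param n_new stage-two sample size of the added arm.
#' @return integer matrix with K+2 rows (arms 0..K+1) and columns
#'   \code{s1}, \code{s2}; row sums reproduce \code{c(n_arm, n_new)}.
#' @examples
#' derive_stage_sizes(K = 1, n_arm = c(550, 550), timing = 0.5, n_new = 275)
#' @export
derive_stage_sizes <- function(K, n_arm, timing, n_new) {
  if (length(n_arm) != K + 1L)
    stop("`n_arm` must have length K + 1 (arms 0..K)")
  if (any(n_arm <= 0) || any(n_arm != round(n_arm)))
    stop("`n_arm` must be positive integers")
  if (n_new <= 0 || n_new != round(n_new))
    stop("`n_new` must be a positive integer")
  if (!is.numeric(timing) || length(timing) != 1L || timing <= 0 || timing >= 1)
    stop("`timing` must lie strictly between 0 and 1")
  n_s1 <- round_half_up(timing * n_arm)
  if (n_s1[1L] == 0L || n_s1[1L] == n_arm[1L])
    stop("timing leaves no concurrent or no non-concurrent control patients")
  if (any(n_s1 < 0L) || any(n_s1 > n_arm))
    stop("derived stage-one sizes fall outside [0, n_arm]")
  n_ks <- cbind(s1 = c(n_s1, 0L), s2 = c(n_arm - n_s1, as.integer(n_new)))
  rownames(n_ks) <- paste0("arm", 0:(K + 1L))
  storage.mode(n_ks) <- "integer"
  n_ks
}

# round-half-up (never banker's rounding): 137.5 -> 138
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Specify a two-stage platform-trial design
#'
#' A design holds everything needed for simulation and analytic operating
#' characteristics: per-arm sample sizes of the initially open arms, the
#' timing of adding the new arm, the added arm's size, the response
#' variance, and the one-sided significance level.
#'
#' The control arm is arm 0; arms 1..K are open from the start; arm K+1 is
#' added at the end of stage one and recruits \code{n_new} patients in
#' stage two.  All hypothesis tests are one-sided superiority tests of
#' \eqn{H_{0k}: \mu_k = \mu_0} against \eqn{H_{1k}: \mu_k > \mu_0}.
#'
#' @inheritParams derive_stage_sizes
#' @param sigma2 known response variance \eqn{\sigma^2}.
#' @param alpha one-sided significance level.
#' @return an object of class \code{trial_design}: a list with elements
#'   \code{K}, \code{n_arm}, \code{timing}, \code{n_new}, \code{sigma2},
#'   \code{alpha} and the derived stage-size matrix \code{n_ks}.
#' @examples
#' d <- trial_design(n_arm = c(550, 550), timing = 0.5, n_new = 275)
#' d$n_ks
#' @export
trial_design <- function(n_arm, timing, n_new, sigma2 = 1, alpha = 0.05,
                         K = length(n_arm) - 1L) {
  if (K < 0L) stop("`K` must be a non-negative integer")
  if (!is.numeric(sigma2) || sigma2 < 0) stop("`sigma2` must be >= 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  n_ks <- derive_stage_sizes(K, n_arm, timing, n_new)
  structure(
    list(K = as.integer(K), n_arm = as.integer(n_arm), timing = timing,
         n_new = as.integer(n_new), sigma2 = sigma2, alpha = alpha,
         n_ks = n_ks),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Two-stage platform trial: K = %d initial arm(s) + control, arm %d added at timing %g\n",
    x$K, x$K + 1L, x$timing))
  cat(sprintf("sigma^2 = %g, one-sided alpha = %g\n", x$sigma2, x$alpha))
  cat("Stage-wise sample sizes:\n")
  print(x$n_ks)
  invisible(x)
}

#' Specify arm means via control mean and treatment effects
#'
#' @param mu0 control mean response.
#' @param delta vector of treatment-versus-control effects
#'   \eqn{\delta_k = \mu_k - \mu_0} for arms 1..K+1 (length K+1).
#' @return object of class \code{effect_spec} with elements \code{mu0},
#'   \code{delta} and the implied arm means \code{mu} (arms 0..K+1).
#' @examples
#' effect_spec(mu0 = 0, delta = c(0.15, 0.15))
#' @export
effect_spec <- function(mu0 = 0, delta) {
  if (!is.numeric(delta) || length(delta) < 1L)
    stop("`delta` must cover arms 1..K+1")
  structure(list(mu0 = mu0, delta = as.numeric(delta),
                 mu = c(mu0, mu0 + as.numeric(delta))),
            class = "effect_spec")
}

#' Specify a calendar-time trend
#'
#' Two fixed trend shapes are supported, both growing with enrolment order:
#' a linear drift from 0 for the first patient to \code{lam} for the last,
#' and a step of height \code{lam} affecting every stage-two patient.  With
#' unit variance, \code{lam} is the trend magnitude as a fraction of a
#' standard deviation; negative values give decreasing trends.
#'
#' @param family one of \code{"none"}, \code{"linear"}, \code{"step"}.
#' @param lam trend magnitude \eqn{\lambda} in response units; ignored
#'   (forced to 0) for \code{family = "none"}.
#' @return object of class \code{trend_spec}.
#' @examples
#' trend_spec("step", 0.08)
#' @export
trend_spec <- function(family = c("none", "linear", "step"), lam = 0) {
  family <- match.arg(family)
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam))
    stop("`lam` must be a finite number")
  if (family == "none") lam <- 0
  structure(list(family = family, lam = lam), class = "trend_spec")
}

#' Read a trial design (and optional trend/effects) from a config file
#'
#' The file may be YAML or JSON; the format is chosen from the extension
#' (\code{.json} for JSON, anything else parsed as YAML, of which JSON is a
#' subset).  Recognised keys mirror the constructor arguments: a
#' \code{design} block with \code{n_arm}, \code{timing}, \code{n_new},
#' \code{sigma2}, \code{alpha}; an optional \code{trend} block with
#' \code{family}, \code{lam}; an optional \code{effects} block with
#' \code{mu0}, \code{delta}.  Integer sizes round-trip exactly.
#'
#' @param path path to the configuration file.
#' @return a list with elements \code{design} (\code{trial_design}) and,
#'   when present in the file, \code{trend} (\code{trend_spec}) and
#'   \code{effects} (\code{effect_spec}).
#' @export
read_trial_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg$design)) stop("config file has no `design` block")
  d <- cfg$design
  out <- list(design = trial_design(
    n_arm = d$n_arm, timing = d$timing, n_new = d$n_new,
    sigma2 = if (is.null(d$sigma2)) 1 else d$sigma2,
    alpha = if (is.null(d$alpha)) 0.05 else d$alpha))
  if (!is.null(cfg$trend))
    out$trend <- trend_spec(cfg$trend$family,
                            if (is.null(cfg$trend$lam)) 0 else cfg$trend$lam)
  if (!is.null(cfg$effects))
    out$effects <- effect_spec(
      mu0 = if (is.null(cfg$effects$mu0)) 0 else cfg$effects$mu0,
      delta = cfg$effects$delta)
  out
}
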