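#' Closed-form power of the one-sided z-test
#'
#' Marginal power of rejecting \eqn{H_{0k}: \mu_k = \mu_0} with known
#' variance:
#' \deqn{\Phi\left[\frac{\delta_k}{\sqrt{\sigma^2/n_k + \sigma^2/n_0}}
#'   - \Phi^{-1}(1-\alpha)\right].}
#' At \eqn{\delta_k = 0} this equals \eqn{\alpha}.
#'
#' @param delta treatment-versus-control effect \eqn{\delta_k}.
#' @param sigma2 known response variance.
#' @param n_k,n_0 sample sizes of the treatment and of the control data
#'   used in the comparison.
#' @param alpha one-sided significance level.
#' @return rejection probability.
#' @examples
#' ztest_power(0.15, 1, 550, 550, 0.05)  # 0.800
#' @export
ztest_power <- function(delta, sigma2, n_k, n_0, alpha = 0.05) {
  if (any(c(n_k, n_0) <= 0) || sigma2 <= 0)
    stop("sample sizes and sigma2 must be positive")
  pnorm(delta / sqrt(sigma2 / n_k + sigma2 / n_0) - qnorm(1 - alpha))
}

#' Analytic covariance of the GLS treatment-effect estimates
#'
#' Builds the contrast covariance \eqn{\Sigma} and design matrix \eqn{D} of
#' the stage-wise mean-difference model (exactly as
#' \code{\link{wls_stagewise}} does, but data-free) and returns
#' \eqn{cov(\hat\delta) = (D'\Sigma^{-1}D)^{-1}}.
#'
#' @param design a \code{\link{trial_design}}.
#' @param variant \code{"all"} or \code{"s2"}: control data used for the
#'   added arm's contrast.
#' @return list with \code{cov} (full \eqn{(K+1)\times(K+1)} covariance)
#'   and \code{var_delta} (its diagonal, named per arm).
#' @export
wls_variance <- function(design, variant = c("all", "s2")) {
  variant <- match.arg(variant)
  if (design$sigma2 <= 0) stop("analytic variances need sigma2 > 0")
  st <- wls_structure(design, variant)
  Si <- tryCatch(solve(st$Sigma), error = function(e)
    stop("singular contrast covariance: ", conditionMessage(e)))
  A <- solve(crossprod(st$D, Si %*% st$D))
  list(cov = A,
       var_delta = stats::setNames(diag(A),
                                   paste0("delta_", seq_len(design$K + 1L))))
}

#' Analytic marginal power of the GLS analyses
#'
#' Per-arm one-sided rejection probability
#' \eqn{\Phi(\delta_k / \sqrt{var(\hat\delta_k)} - \Phi^{-1}(1-\alpha))}
#' using the marginal variances from \code{\link{wls_variance}}.
#'
#' @param design a \code{\link{trial_design}}.
#' @param delta effect vector for arms 1..K+1.
#' @param variant \code{"all"} or \code{"s2"}.
#' @return named vector of marginal powers.
#' @examples
#' d <- trial_design(c(550, 550), timing = 0.5, n_new = 550)
#' wls_marginal_power(d, c(0.15, 0.15), "all")  # 0.800 for both arms
#' @export
wls_marginal_power <- function(design, delta, variant = c("all", "s2")) {
  variant <- match.arg(variant)
  if (length(delta) != design$K + 1L)
    stop("`delta` must have length K + 1")
  v <- wls_variance(design, variant)$var_delta
  pnorm(delta / sqrt(v) - qnorm(1 - design$alpha))
}

#' Borrowing of strength from non-concurrent controls
#'
#' The proportional reduction in the added-arm contrast variance achieved
#' by including non-concurrent control data:
#' \deqn{BoS = (V_0 - V_a)/V_0,}
#' where \eqn{V_0} is \eqn{var(\hat\delta_{K+1})} from the concurrent-only
#' GLS analysis and \eqn{V_a} from the all-control analysis.  Defined only
#' for the added arm; \eqn{BoS \in [0, 1)}, increasing with the timing of
#' addition.
#'
#' @param design a \code{\link{trial_design}}.
#' @return the BoS value (dimensionless).
#' @export
borrowing_of_strength <- function(design) {
  kk <- design$K + 1L
  V0 <- wls_variance(design, "s2")$var_delta[kk]
  Va <- wls_variance(design, "all")$var_delta[kk]
  unname((V0 - Va) / V0)
}

#' Analytic operating-characteristic curves over the timing grid
#'
#' For each timing of arm addition and each added-arm size option,
#' computes the added-arm marginal power under the concurrent-only z-test,
#' the all-control z-test and both GLS variants, plus the GLS variances and
#' the borrowing of strength.  This is the numeric content behind power /
#' BoS curves against the timing of addition.
#'
#' @param n_arm per-arm sizes of the initially open arms (control first).
#' @param delta added-arm effect used for the power columns.
#' @param n_new_options named list or vector of added-arm sizes; each may
#'   be the string \code{"n02"} (match stage-two controls), a number, or a
#'   function of the design's \code{n_02}.
#' @param timings timing grid (default 0.1 to 0.9 in steps of 0.05).
#' @param sigma2,alpha as in \code{\link{trial_design}}.
#' @return data frame with one row per (timing, n_new option) and columns
#'   \code{timing}, \code{n_new}, \code{power_z_concurrent},
#'   \code{power_z_all}, \code{power_wls_s2}, \code{power_wls_all},
#'   \code{var_s2}, \code{var_all}, \code{bos}.
#' @export
oc_curves <- function(n_arm = c(550, 550), delta = 0.15,
                      n_new_options = c(n02 = "n02", n0 = 550, `2n0` = 1100),
                      timings = seq(0.1, 0.9, by = 0.05),
                      sigma2 = 1, alpha = 0.05) {
  K <- length(n_arm) - 1L
  rows <- lapply(timings, function(tm) {
    n01 <- round_half_up(tm * n_arm[1L])
    n02 <- n_arm[1L] - n01
    do.call(rbind, lapply(seq_along(n_new_options), function(o) {
      opt <- n_new_options[[o]]
      n_new <- if (identical(opt, "n02")) n02 else as.integer(opt)
      d <- trial_design(n_arm, timing = tm, n_new = n_new,
                        sigma2 = sigma2, alpha = alpha)
      dl <- rep(delta, K + 1L)
      vs2 <- wls_variance(d, "s2")$var_delta[K + 1L]
      val <- wls_variance(d, "all")$var_delta[K + 1L]
      data.frame(
        timing = tm, option = names(n_new_options)[o], n_new = n_new,
        power_z_concurrent = ztest_power(delta, sigma2, n_new, n02, alpha),
        power_z_all = ztest_power(delta, sigma2, n_new, n_arm[1L], alpha),
        power_wls_s2 = unname(wls_marginal_power(d, dl, "s2")[K + 1L]),
        power_wls_all = unname(wls_marginal_power(d, dl, "all")[K + 1L]),
        var_s2 = unname(vs2), var_all = unname(val),
        bos = borrowing_of_strength(d))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
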