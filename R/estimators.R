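#' @title Analysis approaches for a trial that adds an arm
#' @description Six analyses of one realised trial are provided: the
#'   independent z-test (\code{\link{z_test}}), generalized least squares on
#'   stage-wise treatment-minus-control mean differences with all or only
#'   concurrent control data (\code{\link{wls_stagewise}}), and patient
#'   level regressions with either a linear enrolment-order term or a
#'   stage indicator (\code{\link{regression_fit}}).  All inference is
#'   one-sided with \eqn{\sigma^2} treated as known.
#' @name estimators
NULL

# ---- shared internals -----------------------------------------------------

# per-cell (arm x stage) counts and means; means are NA for empty cells
cell_stats <- function(arm, stage, x, design) {
  K2 <- design$K + 2L
  idx <- arm * 2L + stage                 # 1..2*K2, unique per (arm, stage)
  sums <- rowsum(x, idx)
  cnt <- tabulate(idx, nbins = 2L * K2)
  means <- matrix(NA_real_, K2, 2L,
                  dimnames = list(rownames(design$n_ks), c("s1", "s2")))
  got <- as.integer(rownames(sums))
  s <- 2L - got %% 2L
  means[cbind((got - s) %/% 2L + 1L, s)] <- sums[, 1L] / cnt[got]
  list(counts = matrix(cnt, K2, 2L, byrow = TRUE,
                       dimnames = dimnames(means)),
       means = means)
}

check_trial_data <- function(data, design) {
  cs <- cell_stats(data$arm, data$stage, data$x, design)
  if (!all(cs$counts == design$n_ks))
    stop("per-arm per-stage counts of `data` do not match the design")
  planned <- design$n_ks > 0L
  if (any(planned & is.na(cs$means)))
    stop("empty cell with a positive planned count")
  cs
}

# overall control mean from cell means, weighted by stage sizes
control_overall <- function(means, design) {
  n0 <- design$n_ks[1L, ]
  sum(n0 * means[1L, ]) / sum(n0)
}

# contrast structure of the stage-wise mean-difference model: response map,
# design matrix D and covariance Sigma (data-free, shared with analytic_oc)
wls_structure <- function(design, variant = c("all", "s2")) {
  variant <- match.arg(variant)
  K <- design$K
  s2 <- design$sigma2
  n_ks <- design$n_ks
  n0s <- n_ks[1L, ]
  n0 <- sum(n0s)
  rows <- cbind(k = rep(seq_len(K), each = 2L), s = rep(1:2, K))
  rows <- rbind(rows, c(K + 1L, 2L))
  m <- nrow(rows)
  Sigma <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (ii in i:(m - 1L)) {
    if (rows[i, "s"] != rows[ii, "s"]) next
    s <- rows[i, "s"]
    Sigma[i, ii] <- Sigma[ii, i] <- if (i == ii)
      s2 / n_ks[rows[i, "k"] + 1L, s] + s2 / n0s[s] else s2 / n0s[s]
  }
  if (variant == "s2") {
    Sigma[m, m] <- s2 / design$n_new + s2 / n0s[2L]
    sh <- which(rows[-m, "s"] == 2L)
    Sigma[m, sh] <- Sigma[sh, m] <- s2 / n0s[2L]
  } else {
    Sigma[m, m] <- s2 / design$n_new + s2 / n0
    Sigma[m, -m] <- Sigma[-m, m] <- s2 / n0
  }
  D <- matrix(0, m, K + 1L)
  D[cbind(seq_len(m), rows[, "k"])] <- 1
  list(rows = rows, D = D, Sigma = Sigma)
}

# GLS fit of the stage-wise mean differences given cell means
wls_fit <- function(means, design, variant) {
  st <- wls_structure(design, variant)
  K <- design$K
  y <- numeric(nrow(st$rows))
  for (i in seq_len(nrow(st$rows))) {
    k <- st$rows[i, "k"]; s <- st$rows[i, "s"]
    y[i] <- means[k + 1L, s] - means[1L, s]
  }
  if (variant == "all")
    y[length(y)] <- means[K + 2L, 2L] - control_overall(means, design)
  Si <- tryCatch(solve(st$Sigma), error = function(e)
    stop("singular contrast covariance (duplicate or zero-size cells): ",
         conditionMessage(e)))
  A <- solve(crossprod(st$D, Si %*% st$D))
  delta <- drop(A %*% crossprod(st$D, Si %*% y))
  list(delta = delta, cov = A)
}

# OLS fit via normal equations with known-sigma^2 coefficient covariance
reg_fit <- function(x, arm, stage, j, design, model) {
  K <- design$K
  if (model %in% c("Mb1", "Mb2")) {
    keep <- arm == 0L | arm == K + 1L
    x <- x[keep]; arm <- arm[keep]; stage <- stage[keep]; j <- j[keep]
    dummies <- matrix(as.numeric(arm == K + 1L), ncol = 1L,
                      dimnames = list(NULL, paste0("arm", K + 1L)))
  } else {
    dummies <- outer(arm, seq_len(K + 1L), `==`) + 0
    colnames(dummies) <- paste0("arm", seq_len(K + 1L))
  }
  covar <- if (model %in% c("Ma1", "Mb1")) cbind(j = j)
           else cbind(stage2 = as.numeric(stage == 2L))
  X <- cbind(intercept = 1, dummies, covar)
  XtX <- crossprod(X)
  ch <- tryCatch(chol(XtX), error = function(e) {
    qx <- qr(X)
    stop("rank-deficient design matrix in ", model, "; collinear column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]],
               collapse = ", "))
  })
  XtXinv <- chol2inv(ch)
  coefs <- drop(XtXinv %*% crossprod(X, x))
  names(coefs) <- colnames(X)
  list(coef = coefs, cov = design$sigma2 * XtXinv,
       delta_idx = if (model %in% c("Mb1", "Mb2")) 2L else 2L:(K + 2L))
}

# ---- joint_estimate container ---------------------------------------------

new_joint_estimate <- function(method, delta_hat, cov, alpha,
                               nuisance = NULL) {
  se <- sqrt(pmax(diag(as.matrix(cov)), 0))
  # known-variance z statistics; a degenerate zero variance gives z = +/-Inf
  # by the sign of the estimate (0/0 defined as 0: do not reject)
  z <- ifelse(se > 0, delta_hat / se, sign(delta_hat) * Inf)
  z[se == 0 & delta_hat == 0] <- 0
  structure(list(method = method, delta_hat = delta_hat,
                 cov = as.matrix(cov), zstat = z,
                 reject = z > qnorm(1 - alpha), alpha = alpha,
                 nuisance = nuisance),
            class = "joint_estimate")
}

#' @export
print.joint_estimate <- function(x, ...) {
  cat(sprintf("%s estimates (one-sided alpha = %g):\n", x$method, x$alpha))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy one-row-per-contrast view of a fitted analysis
#'
#' @param x a \code{joint_estimate}.
#' @param ... unused.
#' @return data frame with columns \code{method}, \code{parameter},
#'   \code{estimate}, \code{std_error}, \code{zstat}, \code{reject}.
#' @export
as.data.frame.joint_estimate <- function(x, ...) {
  data.frame(method = x$method, parameter = names(x$delta_hat),
             estimate = unname(x$delta_hat),
             std_error = sqrt(diag(x$cov)),
             zstat = unname(x$zstat), reject = unname(x$reject),
             row.names = NULL)
}

# ---- public analyses ------------------------------------------------------

#' Stage-wise and overall sample means
#'
#' Computes \eqn{\bar X_{k.s}} for every occupied arm-by-stage cell and the
#' overall per-arm means
#' \eqn{\bar X_k = (n_{k1}\bar X_{k.1} + n_{k2}\bar X_{k.2})/n_k}.  The
#' added arm has no stage-one cell; its entry is \code{NA} there (absent,
#' not zero) and its overall mean is its stage-two mean.
#'
#' @param data a \code{trial_data} data frame.
#' @param design the matching \code{\link{trial_design}}.
#' @return list of class \code{stage_means} with \code{counts} and
#'   \code{means} (arms x stages matrices) and \code{overall} (per-arm
#'   vector).
#' @export
stage_means <- function(data, design) {
  cs <- check_trial_data(data, design)
  n_ks <- design$n_ks
  w <- n_ks / rowSums(n_ks)
  overall <- rowSums(ifelse(n_ks > 0L, w * cs$means, 0))
  structure(list(counts = cs$counts, means = cs$means, overall = overall),
            class = "stage_means")
}

#' Independent z-test of one treatment against control
#'
#' Tests \eqn{H_{0k}: \mu_k = \mu_0} against the one-sided alternative
#' using sample means and the known variance.  For the added arm
#' (\code{k = K + 1}), \code{control_scope} selects whether all control
#' data (estimate \eqn{\bar X_{K+1,2} - \bar X_0}) or only concurrent
#' stage-two control data (\eqn{\bar X_{K+1,2} - \bar X_{0.2}}) enters the
#' comparison.  Initial arms are always compared against all control data;
#' requesting the concurrent scope for them is an error.
#'
#' @param data a \code{trial_data} data frame.
#' @param design the matching \code{\link{trial_design}}.
#' @param k arm to test (1..K+1).
#' @param control_scope \code{"all"} or \code{"concurrent"}.
#' @return a \code{joint_estimate} with a single contrast.
#' @export
z_test <- function(data, design, k, control_scope = c("all", "concurrent")) {
  control_scope <- match.arg(control_scope)
  K <- design$K
  if (k < 1L || k > K + 1L) stop("`k` must be an arm in 1..K+1")
  if (control_scope == "concurrent" && k <= K)
    stop("the concurrent-control scope is defined only for the added arm")
  cs <- check_trial_data(data, design)
  s2 <- design$sigma2
  if (k == K + 1L) {
    mk <- cs$means[K + 2L, 2L]
    nk <- design$n_new
  } else {
    n_k <- design$n_ks[k + 1L, ]
    mk <- sum(n_k * cs$means[k + 1L, ]) / sum(n_k)
    nk <- sum(n_k)
  }
  if (control_scope == "all") {
    m0 <- control_overall(cs$means, design)
    n0 <- sum(design$n_ks[1L, ])
  } else {
    m0 <- cs$means[1L, 2L]
    n0 <- design$n_ks[1L, 2L]
  }
  est <- stats::setNames(mk - m0, paste0("delta_", k))
  method <- if (control_scope == "all") "Z_all" else "Z_concurrent"
  new_joint_estimate(method, est, s2 / nk + s2 / n0, design$alpha)
}

#' Generalized least squares on stage-wise mean differences
#'
#' Fits the shared-control model of the stage-wise treatment-minus-control
#' mean differences \eqn{\bar X^{(k)}_s = \delta_k + \eta^{(k)}_s}.  Each
#' initial arm contributes its two stage-wise differences
#' \eqn{\bar X_{k.s} - \bar X_{0.s}}; the added arm contributes a single
#' stage-two difference against either the overall control mean
#' (\code{variant = "all"}, using non-concurrent and concurrent controls)
#' or the stage-two control mean only (\code{variant = "s2"}).  The exact
#' covariance of the differences — variances
#' \eqn{\sigma^2/n_{ks} + \sigma^2/n_{0s}}, within-stage covariance
#' \eqn{\sigma^2/n_{0s}} from the shared control, zero across stages, and
#' \eqn{\sigma^2/n_0} between the all-control contrast and every other —
#' weights the fit:
#' \eqn{\hat\delta = (D'\Sigma^{-1}D)^{-1} D'\Sigma^{-1} y} with
#' \eqn{cov(\hat\delta) = (D'\Sigma^{-1}D)^{-1}}.  Marginal one-sided
#' z-tests are reported per contrast.
#'
#' @param data a \code{trial_data} data frame.
#' @param design the matching \code{\link{trial_design}}.
#' @param variant \code{"all"} (non-concurrent + concurrent control data
#'   for the added arm) or \code{"s2"} (concurrent only).
#' @return a \code{joint_estimate} with contrasts \eqn{\delta_1, ...,
#'   \delta_{K+1}}.
#' @export
wls_stagewise <- function(data, design, variant = c("all", "s2")) {
  variant <- match.arg(variant)
  cs <- check_trial_data(data, design)
  fit <- wls_fit(cs$means, design, variant)
  est <- stats::setNames(fit$delta, paste0("delta_", seq_len(design$K + 1L)))
  new_joint_estimate(paste0("WLS_", variant), est, fit$cov, design$alpha)
}

#' Patient-level regression analyses
#'
#' Ordinary least squares on patient-level responses with the known-variance
#' coefficient covariance \eqn{\sigma^2 (X'X)^{-1}}.  Four model forms:
#' \describe{
#'   \item{Ma1}{all arms; intercept, arm indicators for arms 1..K+1, and a
#'     linear term in enrolment order \code{j}.}
#'   \item{Ma2}{all arms; the linear term replaced by a stage indicator.}
#'   \item{Mb1}{control and added-arm patients only; intercept, added-arm
#'     indicator, linear term in \code{j}.}
#'   \item{Mb2}{as Mb1 with a stage indicator instead of \code{j}.}
#' }
#' Control is the reference level absorbed by the intercept.  The added-arm
#' coefficient (and, for Ma models, each initial-arm coefficient) gets a
#' marginal one-sided z-test.
#'
#' @param data a \code{trial_data} data frame.
#' @param design the matching \code{\link{trial_design}}.
#' @param model one of \code{"Ma1"}, \code{"Ma2"}, \code{"Mb1"},
#'   \code{"Mb2"}.
#' @return a \code{joint_estimate}; nuisance parameters (intercept and the
#'   trend slope or stage effect) are kept in \code{$nuisance}.
#' @export
regression_fit <- function(data, design,
                           model = c("Ma1", "Ma2", "Mb1", "Mb2")) {
  model <- match.arg(model)
  check_trial_data(data, design)
  fit <- reg_fit(data$x, data$arm, data$stage, data$j, design, model)
  di <- fit$delta_idx
  est <- fit$coef[di]
  names(est) <- if (model %in% c("Mb1", "Mb2"))
    paste0("delta_", design$K + 1L) else paste0("delta_", seq_along(di))
  nuis <- fit$coef[-di]
  new_joint_estimate(model, est, fit$cov[di, di, drop = FALSE],
                     design$alpha, nuisance = nuis)
}
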