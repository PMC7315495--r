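#' @title Monte-Carlo operating characteristics
#' @description \code{\link{run_scenario}} replicates a trial design under
#'   one effect/trend configuration and summarises every analysis
#'   approach; grid wrappers reproduce the maximum/median absolute-bias
#'   table and the power / type-I-error / rMSE surfaces over the scenario
#'   grid (timing of addition x added-arm size x trend magnitude).
#' @name experiment_runner
NULL

MC_METHODS <- c("Z_concurrent", "Z_all", "WLS_all", "WLS_s2",
                "Ma1", "Ma2", "Mb1", "Mb2")

# evaluate `code` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

# order-independent per-scenario seed derived from the master seed and the
# scenario coordinates, so scenarios can run alone, in subsets or in
# parallel with identical streams
scenario_seed <- function(master, ...) {
  key <- paste(format(list(...), digits = 15), collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((master %% 2147483647 + h) %% 2147483646 + 1)
}

#' Monte-Carlo summary of one scenario
#'
#' Simulates \code{n_reps} independent trials under the given design,
#' effects and trend, applies the requested analysis approaches to each,
#' and aggregates per method and per hypothesis the bias of the contrast
#' estimate, the empirical one-sided rejection rate, the root mean squared
#' error \eqn{\sqrt{bias^2 + var}}, and Monte-Carlo standard errors.
#' Deterministic given \code{seed}; the caller's RNG state is restored.
#'
#' @param design a \code{\link{trial_design}}.
#' @param effects an \code{\link{effect_spec}}.
#' @param trend a \code{\link{trend_spec}}.
#' @param n_reps number of replicates.
#' @param seed integer seed for this scenario.
#' @param methods subset of
#'   \code{c("Z_concurrent","Z_all","WLS_all","WLS_s2","Ma1","Ma2","Mb1","Mb2")}.
#'   \code{Z_concurrent}, \code{Mb1} and \code{Mb2} estimate the added-arm
#'   contrast only; the others cover every arm.
#' @return data frame of class \code{scenario_summary}: one row per
#'   (method, arm) with columns \code{method}, \code{arm},
#'   \code{hypothesis}, \code{true_delta}, \code{mean_est}, \code{bias},
#'   \code{sd_est}, \code{rmse}, \code{reject_rate}, \code{mc_se_bias},
#'   \code{mc_se_reject}, \code{n_reps}, \code{seed}.
#' @export
run_scenario <- function(design, effects, trend = trend_spec("none"),
                         n_reps = 10000L, seed = 1L,
                         methods = MC_METHODS) {
  stopifnot(inherits(design, "trial_design"), inherits(effects, "effect_spec"),
            inherits(trend, "trend_spec"), n_reps >= 1L)
  methods <- match.arg(methods, MC_METHODS, several.ok = TRUE)
  K <- design$K
  kk <- K + 1L
  crit <- qnorm(1 - design$alpha)
  s2 <- design$sigma2
  n_ks <- design$n_ks
  n0s <- n_ks[1L, ]; n0 <- sum(n0s)

  entry_arms <- function(m)
    if (m %in% c("Z_concurrent", "Mb1", "Mb2")) kk else seq_len(kk)
  entries <- do.call(rbind, lapply(methods, function(m)
    data.frame(method = m, arm = entry_arms(m))))
  ne <- nrow(entries)
  est <- matrix(NA_real_, n_reps, ne)
  zst <- matrix(NA_real_, n_reps, ne)

  if (s2 == 0 && any(grepl("^WLS", methods)))
    stop("the GLS analyses need sigma2 > 0")
  need_cells <- any(methods %in% c("Z_concurrent", "Z_all",
                                   "WLS_all", "WLS_s2"))
  w_arm <- n_ks / rowSums(n_ks)            # overall-mean weights per arm
  empty <- n_ks == 0L                      # cells with no planned patients
  # fixed standard errors for the mean-based analyses (known sigma^2)
  n_trt <- c(rowSums(n_ks)[seq_len(K) + 1L], design$n_new)
  se_z_all <- sqrt(s2 / n_trt + s2 / n0)
  se_z_conc <- sqrt(s2 / design$n_new + s2 / n0s[2L])
  # the GLS projection is data-free: precompute delta_hat = P %*% y once
  wls_pre <- lapply(c(all = "all", s2 = "s2"), function(v) {
    if (!paste0("WLS_", v) %in% methods) return(NULL)
    st <- wls_structure(design, v)
    Si <- solve(st$Sigma)
    A <- solve(crossprod(st$D, Si %*% st$D))
    list(P = A %*% crossprod(st$D, Si), se = sqrt(diag(A)),
         iy_trt = cbind(st$rows[, "k"] + 1L, st$rows[, "s"]),
         iy_ctl = cbind(1L, st$rows[, "s"]), m = nrow(st$rows))
  })

  cols <- split(seq_len(ne), entries$method)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      v <- simulate_vectors(design, effects, trend)
      if (need_cells) cm <- cell_stats(v$arm, v$stage, v$x, design)$means
      for (m in methods) tryCatch({
        ci <- cols[[m]]
        if (m == "Z_all") {
          cmz <- cm
          cmz[empty] <- 0
          ov <- rowSums(w_arm * cmz)
          e <- ov[2:(K + 2L)] - ov[1L]
          z <- if (s2 > 0) e / se_z_all else ifelse(e == 0, 0, sign(e) * Inf)
        } else if (m == "Z_concurrent") {
          e <- cm[K + 2L, 2L] - cm[1L, 2L]
          z <- if (s2 > 0) e / se_z_conc else ifelse(e == 0, 0, sign(e) * Inf)
        } else if (m %in% c("WLS_all", "WLS_s2")) {
          vn <- sub("WLS_", "", m)
          p <- wls_pre[[vn]]
          y <- cm[p$iy_trt] - cm[p$iy_ctl]
          if (vn == "all")
            y[p$m] <- cm[K + 2L, 2L] - sum(w_arm[1L, ] * cm[1L, ])
          e <- drop(p$P %*% y)
          z <- e / p$se
        } else {
          f <- reg_fit(v$x, v$arm, v$stage, v$j, design, m)
          e <- f$coef[f$delta_idx]
          se <- sqrt(diag(f$cov)[f$delta_idx])
          z <- ifelse(se > 0, e / se, ifelse(e == 0, 0, sign(e) * Inf))
        }
        est[r, ci] <- e
        zst[r, ci] <- z
      }, error = function(err)
        stop("estimator ", m, " failed at replicate ", r, ": ",
             conditionMessage(err), call. = FALSE))
    }
  })

  truth <- effects$delta[entries$arm]
  mean_est <- colMeans(est)
  bias <- mean_est - truth
  varm <- colMeans(est^2) - mean_est^2       # population MC variance
  rej <- colMeans(zst > crit)
  out <- data.frame(
    method = entries$method, arm = entries$arm,
    hypothesis = paste0("H0", entries$arm),
    true_delta = truth, mean_est = mean_est, bias = bias,
    sd_est = sqrt(varm), rmse = sqrt(bias^2 + varm),
    reject_rate = rej,
    mc_se_bias = sqrt(varm / n_reps),
    mc_se_reject = sqrt(rej * (1 - rej) / n_reps),
    n_reps = n_reps, seed = seed, row.names = NULL)
  class(out) <- c("scenario_summary", "data.frame")
  attr(out, "scenario") <- list(timing = design$timing,
                                n_new = design$n_new,
                                trend = trend$family, lambda = trend$lam,
                                delta = effects$delta)
  out
}

#' The scenario grid of the simulation study
#'
#' Crosses the timing of arm addition with the added-arm size options.
#' Size options may be \code{"n02"} (match the stage-two control count,
#' which varies with timing) or numbers.
#'
#' @param n_arm per-arm sizes of the initially open arms (control first).
#' @param timings timings of addition.
#' @param n_new_options named vector of added-arm size options.
#' @return data frame with columns \code{timing}, \code{option},
#'   \code{n_new}.
#' @export
scenario_grid <- function(n_arm = c(550, 550),
                          timings = c(0.25, 0.5, 0.75),
                          n_new_options = c(n02 = "n02", n0 = 550,
                                            `2n0` = 1100)) {
  do.call(rbind, lapply(timings, function(tm) {
    n02 <- as.integer(n_arm[1L]) - round_half_up(tm * n_arm[1L])
    data.frame(timing = tm, option = names(n_new_options),
               n_new = vapply(n_new_options, function(o)
                 as.integer(if (identical(o, "n02")) n02 else o),
                 integer(1L)))
  }))
}

#' Run the Monte-Carlo study over a scenario grid
#'
#' Workhorse behind \code{\link{reproduce_table1}} and the surface
#' reproductions: runs \code{\link{run_scenario}} for every combination of
#' grid scenario, trend configuration and effect regime, with per-scenario
#' seeds derived deterministically from \code{seed} and the scenario
#' coordinates (so any subset of the grid reproduces the full run's
#' values).
#'
#' @param grid data frame from \code{\link{scenario_grid}}.
#' @param trends data frame with columns \code{family} and \code{lambda};
#'   default crosses linear and step trends with
#'   \eqn{\lambda \in \{0.02, 0.04, 0.06, 0.08\}}.
#' @param regimes subset of \code{c("alternative", "null")}; the
#'   alternative sets every \eqn{\delta_k} to \code{delta_alt}, the null
#'   sets all to zero.
#' @param n_arm,sigma2,alpha design parameters shared by all scenarios.
#' @param delta_alt effect size under the alternative.
#' @param n_reps,seed replication count and master seed.
#' @param methods analysis approaches to apply (see
#'   \code{\link{run_scenario}}).
#' @return stacked data frame: scenario columns (\code{timing},
#'   \code{option}, \code{n_new}, \code{trend}, \code{lambda},
#'   \code{regime}) plus the \code{scenario_summary} columns.
#' @export
run_study <- function(grid = scenario_grid(),
                      trends = expand.grid(family = c("linear", "step"),
                                           lambda = c(0.02, 0.04, 0.06, 0.08),
                                           stringsAsFactors = FALSE),
                      regimes = "alternative",
                      n_arm = c(550, 550), sigma2 = 1, alpha = 0.05,
                      delta_alt = 0.15, n_reps = 10000L, seed = 1L,
                      methods = MC_METHODS) {
  K <- length(n_arm) - 1L
  res <- vector("list", nrow(grid) * nrow(trends) * length(regimes))
  i <- 0L
  for (g in seq_len(nrow(grid))) {
    design <- trial_design(n_arm, timing = grid$timing[g],
                           n_new = grid$n_new[g], sigma2 = sigma2,
                           alpha = alpha)
    for (tr in seq_len(nrow(trends))) {
      trend <- trend_spec(trends$family[tr], trends$lambda[tr])
      for (rg in regimes) {
        eff <- effect_spec(0, rep(if (rg == "alternative") delta_alt else 0,
                                  K + 1L))
        sc_seed <- scenario_seed(seed, grid$timing[g], grid$n_new[g],
                                 trend$family, trend$lam, rg)
        s <- run_scenario(design, eff, trend, n_reps = n_reps,
                          seed = sc_seed, methods = methods)
        i <- i + 1L
        res[[i]] <- cbind(
          data.frame(timing = grid$timing[g], option = grid$option[g],
                     n_new = grid$n_new[g], trend = trend$family,
                     lambda = trend$lam, regime = rg),
          as.data.frame(s))
      }
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Maximum and median absolute bias of the added-arm estimate
#'
#' For each trend family, trend magnitude and analysis approach, takes the
#' maximum and the median over the nine (timing x added-arm size)
#' scenarios of the absolute bias of the estimated added-arm contrast
#' under the alternative (all effects 0.15).  Absolute biases below the
#' reporting threshold are set to zero, mirroring the convention that
#' values at the Monte-Carlo noise floor are displayed as 0.
#'
#' @param n_reps replicates per scenario.
#' @param seed master seed.
#' @param trends,lambdas trend families and magnitudes to cover.
#' @param methods analysis approaches (default: the six model-based ones).
#' @param zero_tol absolute biases below this are reported as 0.
#' @param grid scenario grid (default the nine study scenarios).
#' @return data frame with columns \code{trend}, \code{lambda},
#'   \code{method}, \code{max_abs_bias}, \code{median_abs_bias}; the
#'   per-scenario results are attached as attribute \code{"detail"}.
#' @export
reproduce_table1 <- function(n_reps = 10000L, seed = 1L,
                             trends = c("linear", "step"),
                             lambdas = c(0.02, 0.04, 0.06, 0.08),
                             methods = c("WLS_all", "WLS_s2", "Ma1",
                                         "Ma2", "Mb1", "Mb2"),
                             zero_tol = 1e-3,
                             grid = scenario_grid()) {
  tg <- expand.grid(family = trends, lambda = lambdas,
                    stringsAsFactors = FALSE)
  detail <- run_study(grid = grid, trends = tg, regimes = "alternative",
                      n_reps = n_reps, seed = seed, methods = methods)
  kk <- max(detail$arm)
  dd <- detail[detail$arm == kk, ]
  agg <- do.call(rbind, lapply(split(
    dd, list(dd$trend, dd$lambda, dd$method), drop = TRUE),
    function(g) data.frame(trend = g$trend[1L], lambda = g$lambda[1L],
                           method = g$method[1L],
                           max_abs_bias = max(abs(g$bias)),
                           median_abs_bias = median(abs(g$bias)))))
  agg$max_abs_bias[agg$max_abs_bias < zero_tol] <- 0
  agg$median_abs_bias[agg$median_abs_bias < zero_tol] <- 0
  agg <- agg[order(agg$trend, agg$lambda, match(agg$method, methods)), ]
  rownames(agg) <- NULL
  attr(agg, "detail") <- detail
  agg
}

#' Empirical marginal power and type-I error surfaces
#'
#' Rejection rates of the added-arm hypothesis (and, for the full-data
#' approaches, of the initial-arm hypotheses) per method, scenario and
#' trend magnitude — the numeric content of power and type-I-error figures
#' over the scenario grid.  The no-trend row is included by default.
#'
#' @inheritParams reproduce_table1
#' @param regimes \code{"alternative"} gives marginal power,
#'   \code{"null"} gives type-I error; both by default.
#' @return data frame as \code{\link{run_study}}, restricted to the
#'   rejection-rate columns.
#' @export
reproduce_power_and_error_surfaces <- function(
    n_reps = 10000L, seed = 1L,
    trends = c("none", "linear", "step"),
    lambdas = c(0.02, 0.04, 0.06, 0.08),
    regimes = c("alternative", "null"),
    methods = MC_METHODS, grid = scenario_grid()) {
  tg <- unique(do.call(rbind, lapply(trends, function(f)
    data.frame(family = f, lambda = if (f == "none") 0 else lambdas))))
  out <- run_study(grid = grid, trends = tg, regimes = regimes,
                   n_reps = n_reps, seed = seed, methods = methods)
  out[c("timing", "option", "n_new", "trend", "lambda", "regime", "method",
        "arm", "hypothesis", "reject_rate", "mc_se_reject", "n_reps",
        "seed")]
}

#' Root-mean-squared-error tables over the scenario grid
#'
#' rMSE of the added-arm contrast estimate per method, scenario and trend
#' magnitude, under the alternative.
#'
#' @inheritParams reproduce_table1
#' @return data frame with the scenario columns plus \code{method},
#'   \code{bias}, \code{sd_est}, \code{rmse}.
#' @export
reproduce_rmse_tables <- function(n_reps = 10000L, seed = 1L,
                                  trends = c("none", "linear", "step"),
                                  lambdas = c(0.02, 0.04, 0.06, 0.08),
                                  methods = MC_METHODS,
                                  grid = scenario_grid()) {
  tg <- unique(do.call(rbind, lapply(trends, function(f)
    data.frame(family = f, lambda = if (f == "none") 0 else lambdas))))
  out <- run_study(grid = grid, trends = tg, regimes = "alternative",
                   n_reps = n_reps, seed = seed, methods = methods)
  out <- out[out$arm == max(out$arm), ]
  out[c("timing", "option", "n_new", "trend", "lambda", "method", "bias",
        "sd_est", "rmse", "n_reps", "seed")]
}

#' Write a JSON manifest describing a Monte-Carlo run
#'
#' @param path output path.
#' @param seed master seed used.
#' @param grid the scenario grid data frame.
#' @param extra named list of additional fields.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, seed, grid = scenario_grid(),
                               extra = list()) {
  manifest <- c(list(
    package = "ncctrial",
    version = as.character(utils::packageVersion("ncctrial")),
    r_version = R.version.string,
    seed = seed, grid = grid,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
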