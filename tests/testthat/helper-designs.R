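# shared fixtures: the study design and small designs for fast checks

study_design <- function(timing = 0.5, n_new = 275, sigma2 = 1,
                         alpha = 0.05) {
  trial_design(n_arm = c(550, 550), timing = timing, n_new = n_new,
               sigma2 = sigma2, alpha = alpha)
}

study_effects <- function(delta = 0.15, K = 1) effect_spec(0, rep(delta, K + 1))

small_design <- function(n0 = 40, timing = 0.5, n_new = 20, K = 1,
                         sigma2 = 1)
  trial_design(n_arm = rep(n0, K + 1), timing = timing, n_new = n_new,
               sigma2 = sigma2)

# independent GLS oracle: whiten with the Cholesky factor of Sigma and use
# lm.fit on the transformed system (route disjoint from the package's
# closed-form projection)
gls_oracle <- function(y, D, Sigma) {
  L <- chol(Sigma)
  yw <- backsolve(L, y, transpose = TRUE)
  Dw <- backsolve(L, D, transpose = TRUE)
  f <- lm.fit(Dw, yw)
  list(coef = unname(f$coefficients),
       cov = chol2inv(qr.R(f$qr))[order(f$qr$pivot), order(f$qr$pivot),
                                  drop = FALSE])
}

# rebuild the contrast system for a realised trial straight from the model
# description (used to feed gls_oracle without touching package internals
# beyond the documented covariance structure)
contrast_system <- function(data, design, variant) {
  K <- design$K
  n_ks <- design$n_ks
  s2 <- design$sigma2
  mn <- function(k, s) mean(data$x[data$arm == k & data$stage == s])
  ov0 <- with(design, sum(n_ks[1, ] * c(mn(0, 1), mn(0, 2))) / sum(n_ks[1, ]))
  y <- c()
  ks <- list()
  for (k in seq_len(K)) for (s in 1:2) {
    y <- c(y, mn(k, s) - mn(0, s)); ks[[length(ks) + 1]] <- c(k, s)
  }
  y <- c(y, mn(K + 1, 2) - if (variant == "all") ov0 else mn(0, 2))
  ks[[length(ks) + 1]] <- c(K + 1, 2)
  m <- length(y)
  Sigma <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ki <- ks[[i]]; kj <- ks[[j]]
    last_i <- i == m; last_j <- j == m
    Sigma[i, j] <-
      if (i == j) {
        nk <- if (last_i) design$n_new else n_ks[ki[1] + 1, ki[2]]
        n0 <- if (last_i && variant == "all") sum(n_ks[1, ])
              else n_ks[1, ki[2]]
        s2 / nk + s2 / n0
      } else if ((last_i || last_j) && variant == "all") {
        s2 / sum(n_ks[1, ])
      } else if (ki[2] == kj[2]) {
        s2 / n_ks[1, ki[2]]
      } else 0
  }
  D <- matrix(0, m, K + 1)
  for (i in seq_len(m)) D[i, ks[[i]][1]] <- 1
  list(y = y, D = D, Sigma = Sigma)
}
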