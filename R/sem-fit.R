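# Maximum-likelihood fitting of sem_model objects.
#
# The discrepancy minimized is the standard ML fit function
#   F(theta) = log|Sigma| + tr(S Sigma^-1) - log|S| - p,
# with chi2 = (n - 1) F(theta_hat).  Variances are optimized on the log
# scale so they stay positive; a variance pinned at the floor is flagged
# as a Heywood case.  Robust (sandwich) standard errors and a
# Satorra-Bentler-type scaled test statistic are available when the raw
# data matrix is supplied.

num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

num_hess <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  h <- eps * pmax(1, abs(x))
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    xpp <- xpm <- xmp <- xmm <- x
    xpp[i] <- xpp[i] + h[i]; xpp[j] <- xpp[j] + h[j]
    xpm[i] <- xpm[i] + h[i]; xpm[j] <- xpm[j] - h[j]
    xmp[i] <- xmp[i] - h[i]; xmp[j] <- xmp[j] + h[j]
    xmm[i] <- xmm[i] - h[i]; xmm[j] <- xmm[j] - h[j]
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
      (4 * h[i] * h[j])
  }
  H
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

duplication_matrix <- function(p) {
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  k <- 0
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

sem_fml <- function(S, Sigma, logdetS, p) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  v <- logdet + tr - logdetS - p
  if (!is.finite(v)) 1e10 else v
}

sem_start_values <- function(model, S) {
  pt <- model$partable
  start <- pt$start
  for (lat in names(model$latents)) {
    marker <- model$latents[[lat]][1]
    vm <- S[marker, marker]
    i_lv <- which(pt$type == "latvar" & pt$lhs == lat)
    if (pt$free[i_lv]) start[i_lv] <- 0.5 * vm
    phi0 <- 0.5 * vm
    for (ind in model$latents[[lat]]) {
      i_l <- which(pt$type == "loading" & pt$lhs == lat & pt$rhs == ind)
      if (pt$free[i_l]) start[i_l] <- S[ind, marker] / phi0
    }
  }
  for (v in model$observed) {
    i_r <- which(pt$type == "resid" & pt$lhs == v)
    start[i_r] <- 0.5 * S[v, v]
  }
  start[pt$type == "path"] <- 0.1
  start
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance matrix `S` of
#' the (adjusted) indicators and the model-implied covariance.  Point
#' estimates depend only on `S` and `n`; supplying the raw `data` rows
#' additionally enables sandwich (robust) standard errors and a scaled test
#' statistic correcting the chi-square for non-normal kurtosis.
#'
#' @param S Sample covariance matrix of the model's observed variables
#'   (dimnames must cover the indicator names).
#' @param n Sample size behind `S`.
#' @param model A [sem_model()] with df >= 0.
#' @param data Optional data.frame/matrix of raw observations (only needed
#'   for robust standard errors).
#' @param se `"standard"` (normal-theory, from the Hessian), `"robust"`
#'   (sandwich; needs `data`) or `"none"`.
#' @param start Optional full start vector over the parameter table.
#' @param max_restarts Jittered restarts attempted on non-convergence.
#' @return An object of class `sem_fit`: estimates table, implied
#'   covariance, `chi2`, `df`, `pvalue`, `F_min`, convergence and Heywood
#'   flags, and (with `se = "robust"`) `chi2_scaled` and `scaling_factor`.
#' @export
fit_ml <- function(S, n, model, data = NULL,
                   se = c("standard", "robust", "none"),
                   start = NULL, max_restarts = 3L) {
  se <- match.arg(se)
  stopifnot(inherits(model, "sem_model"))
  obs <- model$observed
  if (is.null(dimnames(S)) || !all(obs %in% rownames(S)))
    stop("S must carry dimnames covering the model indicators", call. = FALSE)
  S <- as.matrix(S[obs, obs])
  S <- (S + t(S)) / 2
  chS <- tryCatch(chol(S), error = function(e)
    stop("S is not positive definite", call. = FALSE))
  logdetS <- 2 * sum(log(diag(chS)))
  df <- as.numeric(model_degrees_of_freedom(model))
  if (df < 0) stop("model is underidentified (df < 0)", call. = FALSE)
  p <- model$p
  pt <- model$partable
  free <- which(pt$free)
  is_var <- pt$type[free] %in% c("latvar", "resid")
  floor_log <- log(1e-8 * mean(diag(S)))

  to_theta <- function(vals) {
    th <- vals[free]
    th[is_var] <- log(pmax(th[is_var], exp(floor_log)))
    th
  }
  to_values <- function(th) {
    vals <- ifelse(pt$free, NA_real_, pt$fixed_value)
    th2 <- th
    th2[is_var] <- exp(th[is_var])
    vals[free] <- th2
    vals
  }
  objective <- function(th) {
    vals <- to_values(th)
    Sigma <- tryCatch(implied_covariance(model, vals),
                      error = function(e) NULL)
    if (is.null(Sigma)) return(1e10)
    sem_fml(S, Sigma, logdetS, p)
  }

  if (is.null(start)) start <- sem_start_values(model, S)
  th0 <- to_theta(start)
  lower <- rep(-Inf, length(th0)); lower[is_var] <- floor_log
  best <- NULL
  for (r in 0:max_restarts) {
    th_try <- if (r == 0) th0 else th0 * (1 + 0.2 * r) + 0.05 * r
    opt <- nlminb(th_try, objective, lower = lower,
                  control = list(iter.max = 1000, eval.max = 2000,
                                 rel.tol = 1e-12))
    if (is.null(best) || opt$objective < best$objective) best <- opt
    g <- num_grad(objective, best$par)
    if (max(abs(g)) < 1e-4 * max(1, abs(best$objective))) break
  }
  opt <- best
  theta <- opt$par
  vals <- to_values(theta)
  Sigma <- implied_covariance(model, vals)
  F_min <- sem_fml(S, Sigma, logdetS, p)
  g <- num_grad(objective, theta)
  # numeric-gradient stationarity is the operative criterion; nlminb's own
  # code can report "false convergence" at an exactly-zero discrepancy
  converged <- F_min < 1e9 &&
    (opt$convergence == 0 || max(abs(g)) < 1e-4 * max(1, F_min))
  heywood <- any(is_var & theta <= floor_log + 1e-6)
  if (heywood)
    warning("Heywood case: residual variance bounded at the positive floor",
            call. = FALSE)

  chi2 <- max(0, (n - 1) * F_min)
  pvalue <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_

  est <- vals
  se_vec <- rep(NA_real_, nrow(pt))
  chi2_scaled <- scaling_factor <- NULL
  if (se != "none" && converged) {
    # natural-parameter objective for the Hessian
    nat_obj <- function(x) {
      vals2 <- ifelse(pt$free, NA_real_, pt$fixed_value)
      vals2[free] <- x
      Sigma2 <- tryCatch(implied_covariance(model, vals2),
                         error = function(e) NULL)
      if (is.null(Sigma2)) return(1e10)
      sem_fml(S, Sigma2, logdetS, p)
    }
    x_hat <- vals[free]
    H <- num_hess(nat_obj, x_hat)
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    pos <- pmax(ev$values, 1e-10)
    Hinv <- ev$vectors %*% (t(ev$vectors) / pos)
    acov <- 2 / (n - 1) * Hinv
    if (se == "robust") {
      if (is.null(data))
        stop("robust standard errors require the raw data", call. = FALSE)
      Z <- as.matrix(data[stats::complete.cases(data[, obs, drop = FALSE]),
                          obs, drop = FALSE])
      Z <- sweep(Z, 2, colMeans(Z))
      nr <- nrow(Z)
      Mi <- t(apply(Z, 1, function(z) vech(tcrossprod(z))))
      Gam <- cov(Mi) * (nr - 1) / nr
      D <- duplication_matrix(p)
      Sig_inv <- solve(Sigma)
      V <- 0.5 * t(D) %*% (Sig_inv %x% Sig_inv) %*% D
      # Delta = d vech(Sigma) / d theta (free, natural scale)
      Delta <- matrix(0, p * (p + 1) / 2, length(free))
      for (i in seq_along(free)) {
        h <- 1e-6 * max(1, abs(x_hat[i]))
        vp <- vm <- vals
        vp[free[i]] <- x_hat[i] + h
        vm[free[i]] <- x_hat[i] - h
        Delta[, i] <- (vech(implied_covariance(model, vp)) -
                         vech(implied_covariance(model, vm))) / (2 * h)
      }
      A <- solve(t(Delta) %*% V %*% Delta)
      acov <- A %*% t(Delta) %*% V %*% Gam %*% V %*% Delta %*% A / (n - 1)
      U <- V - V %*% Delta %*% A %*% t(Delta) %*% V
      if (df > 0) {
        scaling_factor <- sum(diag(U %*% Gam)) / df
        chi2_scaled <- chi2 / max(scaling_factor, 1e-12)
      }
    }
    se_vec[free] <- sqrt(pmax(diag(acov), 0))
  }
  estimates <- cbind(pt[, c("type", "lhs", "rhs", "free")],
                     est = est, se = se_vec)
  estimates$name <- sem_par_names(model)

  fit <- list(model = model, S = S, n = n, estimates = estimates,
              values = vals, sigma_implied = Sigma, F_min = F_min,
              chi2 = chi2, df = df, pvalue = pvalue,
              converged = converged, heywood = heywood,
              chi2_scaled = chi2_scaled, scaling_factor = scaling_factor)
  class(fit) <- "sem_fit"
  fit
}

#' Extract a named parameter estimate from a fit
#' @param fit A `sem_fit`.
#' @param name Parameter name as in `fit$estimates$name`, e.g.
#'   `"path.meat.carcass"`.
#' @return Numeric estimate.
#' @export
sem_estimate <- function(fit, name) {
  i <- match(name, fit$estimates$name)
  if (is.na(i)) stop("no such parameter: ", name, call. = FALSE)
  fit$estimates$est[i]
}

#' Goodness-of-fit indices for a fitted structural equation model
#'
#' Computes GFI, AGFI, RMR, CFI and RMSEA.  The baseline for CFI is the
#' independence model fitted to the same covariance matrix (closed form:
#' `Sigma_b = diag(S)`), unless an explicit baseline chi-square/df pair is
#' given.
#'
#' @param fit A `sem_fit`.
#' @param baseline_chi2,baseline_df Optional baseline statistic.
#' @return Object of class `fit_indices` (list `gfi`, `agfi`, `rmr`,
#'   `cfi`, `rmsea`).  RMSEA is `NA` for a saturated model (df = 0).
#' @export
fit_indices <- function(fit, baseline_chi2 = NULL, baseline_df = NULL) {
  S <- fit$S; Sigma <- fit$sigma_implied
  p <- fit$model$p; n <- fit$n
  if (is.null(baseline_chi2)) {
    F_b <- sum(log(diag(S))) - determinant(S, logarithm = TRUE)$modulus[1]
    baseline_chi2 <- max(0, (n - 1) * F_b)
    baseline_df <- p * (p - 1) / 2
  }
  W <- solve(Sigma) %*% S
  gfi <- 1 - sum(diag((W - diag(p)) %*% (W - diag(p)))) / sum(diag(W %*% W))
  agfi <- if (fit$df > 0)
    1 - (p * (p + 1) / (2 * fit$df)) * (1 - gfi) else NA_real_
  R <- S - Sigma
  rmr <- sqrt(mean(vech(R)^2))
  num <- max(fit$chi2 - fit$df, 0)
  den <- max(baseline_chi2 - baseline_df, fit$chi2 - fit$df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  rmsea <- if (fit$df > 0)
    sqrt(max(fit$chi2 - fit$df, 0) / (fit$df * (n - 1))) else NA_real_
  structure(list(gfi = gfi, agfi = agfi, rmr = rmr, cfi = cfi,
                 rmsea = rmsea,
                 baseline_chi2 = baseline_chi2, baseline_df = baseline_df),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("GFI %.3f  AGFI %.3f  RMR %.3f  CFI %.3f  RMSEA %s\n",
              x$gfi, x$agfi, x$rmr, x$cfi,
              if (is.na(x$rmsea)) "n/a (df = 0)" else sprintf("%.3f", x$rmsea)))
  invisible(x)
}

#' Per-animal factor scores
#'
#' Predicts latent-variable values for each data row from a fitted model.
#' The default regression method returns `E[latent | observed]` under the
#' estimated parameters; Bartlett scores (maximum-likelihood weighting by
#' inverse residual variances) are available as an alternative.  Scores are
#' rescaled so their model-implied variance equals the latent's
#' model-implied variance, keeping them on the latent scale used by the
#' downstream mixed models.
#'
#' @param fit A converged `sem_fit`.
#' @param data Data rows containing the model indicators.
#' @param method `"regression"` or `"bartlett"`.
#' @param standardize Rescale to the model-implied latent variance
#'   (default `TRUE`).
#' @param center Subtract column means before scoring (default `TRUE`).
#' @return Matrix (rows of `data` x latents); rows with missing indicators
#'   are `NA` and counted in attribute `"n_dropped"`.
#' @export
factor_scores <- function(fit, data, method = c("regression", "bartlett"),
                          standardize = TRUE, center = TRUE) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$converged)
    stop("factor_scores requires a converged fit", call. = FALSE)
  obs <- fit$model$observed
  if (!all(obs %in% colnames(data)))
    stop("data lacks indicator column(s): ",
         paste(setdiff(obs, colnames(data)), collapse = ", "), call. = FALSE)
  X <- as.matrix(data[, obs, drop = FALSE])
  ok <- stats::complete.cases(X)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("factor_scores: dropping ", n_dropped,
            " row(s) with missing indicators")
  Xc <- X[ok, , drop = FALSE]
  if (center) Xc <- sweep(Xc, 2, colMeans(Xc))
  m <- sem_matrices(fit$model, fit$values)
  IBi <- solve(diag(nrow(m$B)) - m$B)
  lat_cov <- IBi %*% m$Psi %*% t(IBi)
  Sigma <- fit$sigma_implied
  C <- m$L %*% lat_cov                       # cov(observed, latent)
  if (method == "regression") {
    A <- solve(Sigma, C)                     # p x nl weights
    sc <- Xc %*% A
    v_impl <- diag(t(C) %*% A)
  } else {
    th <- diag(m$Theta)
    if (any(th <= 0))
      stop("Bartlett scores need strictly positive residual variances",
           call. = FALSE)
    Wt <- m$L / th                           # Theta^-1 Lambda
    Minv <- solve(t(m$L) %*% Wt)
    sc <- Xc %*% Wt %*% t(Minv)
    v_impl <- diag(lat_cov + Minv)
  }
  if (standardize) {
    fac <- sqrt(diag(lat_cov) / pmax(v_impl, 1e-300))
    sc <- sweep(sc, 2, fac, `*`)
  }
  out <- matrix(NA_real_, nrow(X), ncol(sc),
                dimnames = list(rownames(data), names(fit$model$latents)))
  out[ok, ] <- sc
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Bootstrap check of model adequacy
#'
#' Resamples data rows with replacement, refits the model on each draw and
#' reports the proportion of draws in which the model is rejected
#' (chi-square p-value below `alpha`) or the optimizer fails to converge.
#'
#' Rows are first put through the Bollen-Stine rotation
#' `Y = Xc S^-1/2 Sigma_hat^1/2`, which makes the empirical covariance
#' satisfy the fitted model exactly, so the bootstrap chi-square is central
#' under the model and the failing proportion estimates the test's actual
#' rejection level.  Without the rotation the statistic inherits the
#' sample's (chance) misfit as noncentrality and the check is grossly
#' anti-conservative.
#'
#' @param data Data rows containing the model indicators.
#' @param model A [sem_model()].
#' @param n_draws Number of bootstrap draws.
#' @param seed Integer seed.
#' @param alpha Rejection level (default 0.05).
#' @param rotate Apply the Bollen-Stine rotation (default `TRUE`).  Set to
#'   `FALSE` to bootstrap the raw rows, in which case the failing
#'   proportion also reflects how far the sample covariance is from the
#'   model (a power/misfit probe rather than a level check).
#' @return The failing proportion, with attributes `n_nonconverged` and
#'   `n_draws`.
#' @export
bootstrap_model_check <- function(data, model, n_draws = 200L, seed = 1L,
                                  alpha = 0.05, rotate = TRUE) {
  stopifnot(n_draws >= 1L)
  obs <- model$observed
  X <- as.matrix(data[, obs, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  base_fit <- fit_ml(cov(X), n, model, se = "none")
  if (rotate) {
    mat_pow <- function(M, pow) {
      e <- eigen((M + t(M)) / 2, symmetric = TRUE)
      e$vectors %*% (t(e$vectors) * e$values^pow)
    }
    Xc <- sweep(X, 2, colMeans(X))
    X <- Xc %*% mat_pow(cov(X), -0.5) %*% mat_pow(base_fit$sigma_implied, 0.5)
    colnames(X) <- obs
  }
  set.seed(seed)
  fails <- 0L; nonconv <- 0L
  for (b in seq_len(n_draws)) {
    idx <- sample.int(n, n, replace = TRUE)
    Sb <- cov(X[idx, , drop = FALSE])
    fb <- tryCatch(fit_ml(Sb, n, model, se = "none",
                          start = base_fit$values, max_restarts = 1L),
                   error = function(e) NULL)
    if (is.null(fb) || !fb$converged) {
      nonconv <- nonconv + 1L
      fails <- fails + 1L
    } else if (!is.na(fb$pvalue) && fb$pvalue < alpha) {
      fails <- fails + 1L
    }
  }
  if (nonconv > n_draws / 2)
    warning("bootstrap_model_check: more than half of the draws failed to ",
            "converge (", nonconv, "/", n_draws, ")", call. = FALSE)
  structure(fails / n_draws, n_nonconverged = nonconv, n_draws = n_draws)
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("sem_fit:", if (x$converged) "converged" else "NOT converged",
      sprintf(" chi2 = %.4f on %d df (p = %s), F = %.6g\n", x$chi2, x$df,
              if (is.na(x$pvalue)) "n/a" else sprintf("%.3f", x$pvalue),
              x$F_min))
  free <- x$estimates[x$estimates$free, ]
  for (i in seq_len(nrow(free)))
    cat(sprintf("  %-28s %8.4f  (se %s)\n", free$name[i], free$est[i],
                if (is.na(free$se[i])) "n/a" else sprintf("%.4f", free$se[i])))
  invisible(x)
}
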