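# Single-trait animal model on latent scores: mixed-model equations,
# EM-REML variance components (with an average-information SE at the
# optimum), bivariate REML for the genetic correlation, and back-solving
# of SNP effects from genomic breeding values.

# Build the records -> animals incidence matrix from names.
incidence_W <- function(y, ids) {
  rec <- names(y)
  if (is.null(rec)) stop("y must be named by animal id", call. = FALSE)
  j <- match(rec, ids)
  if (anyNA(j)) stop("records for animals absent from the relationship ",
                     "matrix: ", paste(rec[is.na(j)][1:5], collapse = ", "),
                     call. = FALSE)
  W <- matrix(0, length(y), length(ids))
  W[cbind(seq_along(y), j)] <- 1
  W
}

as_X <- function(X, n) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X
}

#' Solve the single-trait ssGBLUP mixed-model equations
#'
#' Solves
#' \deqn{\left[\begin{array}{cc} X'X & X'W \\ W'X & W'W + H^{-1}\lambda
#' \end{array}\right]\left[\begin{array}{c} b \\ a \end{array}\right] =
#' \left[\begin{array}{c} X'y \\ W'y \end{array}\right]}
#' where `W` maps records to animals, so animals without records still
#' receive breeding values through their relationships.
#'
#' @param y Named numeric vector of records (names = animal ids).
#' @param X Fixed-effect design matrix (default: intercept only).
#' @param Hinv Inverse relationship matrix over all animals (dimnames set).
#' @param lambda Variance ratio `sigma2_e / sigma2_a` (> 0).
#' @param model_tag Optional label (`"carcass"`, `"meat"`,
#'   `"meat_given_carcass"`, ...).
#' @return Object of class `gblup_solution`: `fixed_solutions`, `gebv`
#'   (named, all animals), `lambda`, `model_tag`.
#' @export
solve_mme <- function(y, X = NULL, Hinv, lambda, model_tag = NULL) {
  stopifnot(lambda > 0)
  ids <- rownames(Hinv)
  W <- incidence_W(y, ids)
  X <- as_X(X, length(y))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("singular fixed-effect block; aliased column(s): ",
         paste(colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]],
               collapse = ", "), call. = FALSE)
  C <- rbind(cbind(crossprod(X), crossprod(X, W)),
             cbind(crossprod(W, X), crossprod(W) + Hinv * lambda))
  rhs <- c(crossprod(X, y), crossprod(W, y))
  sol <- solve(C, rhs)
  nb <- ncol(X)
  out <- list(fixed_solutions = setNames(sol[seq_len(nb)], colnames(X)),
              gebv = setNames(sol[-seq_len(nb)], ids),
              lambda = lambda, model_tag = model_tag)
  class(out) <- "gblup_solution"
  out
}

# One-time spectral factorization that makes each EM-REML iteration O(n_a).
# With S(lambda) = M0 + lambda * Hinv (M0 = W'W absorbed for X), solve the
# generalized eigenproblem M0 U = Hinv U D with U' Hinv U = I; then
#   tr(Hinv S^-1) = sum 1/(d + lambda)
#   a_hat = U (D + lambda)^-1 U' r,   a_hat' Hinv a_hat = sum v^2/(d+lambda)^2
em_reml_precompute <- function(y, X, Hinv) {
  ids <- rownames(Hinv)
  W <- incidence_W(y, ids)
  X <- as_X(X, length(y))
  XtX_inv <- solve(crossprod(X))
  WX <- crossprod(W, X)
  M0 <- crossprod(W) - WX %*% XtX_inv %*% t(WX)
  L <- t(chol((Hinv + t(Hinv)) / 2))          # Hinv = L L'
  Linv_M0 <- forwardsolve(L, M0)
  Bt <- t(forwardsolve(L, t(Linv_M0)))        # L^-1 M0 L^-T
  eg <- eigen((Bt + t(Bt)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- backsolve(t(L), eg$vectors)            # U = L^-T Q
  r <- crossprod(W, y) - WX %*% (XtX_inv %*% crossprod(X, y))
  v <- drop(crossprod(U, r))
  list(W = W, X = X, XtX_inv = XtX_inv, d = d, U = U, v = v, r = r,
       ids = ids, yty = sum(y^2), Xty = crossprod(X, y),
       Wty = crossprod(W, y), y = y)
}

#' EM-REML variance components for the animal model
#'
#' Estimates additive and residual variance for a single-trait animal model
#' `y = Xb + Wa + e`, `a ~ N(0, H sigma2_a)`, by EM-REML.  The expensive
#' part of every iteration is removed by a one-time generalized
#' eigendecomposition, so the iteration cap is cheap to reach.  The
#' standard error of the heritability is obtained from the
#' average-information matrix evaluated at the optimum (delta method).
#'
#' @param y Named numeric vector of records.
#' @param X Fixed-effect design (default intercept).
#' @param Hinv Inverse relationship matrix, dimnames = animal ids.
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative-change convergence tolerance (default 1e-6).
#' @param se Compute the AI-based standard error of h2 (default `TRUE`;
#'   requires one dense solve of `Hinv`).
#' @return Object of class `variance_components`: `sigma2_a`, `sigma2_e`,
#'   `lambda`, `h2`, `h2_se`, `converged`, `iterations`.
#' @export
estimate_variance_components <- function(y, X = NULL, Hinv, max_iter = 500L,
                                         tol = 1e-6, se = TRUE) {
  pre <- em_reml_precompute(y, X, Hinv)
  n <- length(y)
  p <- ncol(pre$X)
  if (n < p + 2) stop("too few records for the fixed-effect design",
                      call. = FALSE)
  na <- length(pre$ids)
  s2a <- s2e <- var(y) / 2
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    lam <- s2e / s2a
    denom <- pre$d + lam
    aHa <- sum(pre$v^2 / denom^2)
    trHS <- sum(1 / denom)
    a_hat <- drop(pre$U %*% (pre$v / denom))
    b_hat <- pre$XtX_inv %*% (pre$Xty - crossprod(pre$X, pre$W %*% a_hat))
    s2a_new <- (aHa + s2e * trHS) / na
    s2e_new <- drop(pre$yty - crossprod(b_hat, pre$Xty) -
                      crossprod(a_hat, pre$Wty)) / (n - p)
    delta <- max(abs(s2a_new - s2a) / max(s2a, 1e-12),
                 abs(s2e_new - s2e) / max(s2e, 1e-12))
    s2a <- max(s2a_new, 1e-12)
    s2e <- max(s2e_new, 1e-12)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM-REML did not reach tolerance ", tol, " within ", max_iter,
            " iterations; returning the last iterate", call. = FALSE)
  h2 <- s2a / (s2a + s2e)
  h2_se <- NA_real_
  if (se) {
    H <- solve(Hinv)
    K <- pre$W %*% H %*% t(pre$W)
    V <- s2a * K + s2e * diag(n)
    Vi <- solve(V)
    ViX <- Vi %*% pre$X
    P <- Vi - ViX %*% solve(crossprod(pre$X, ViX), t(ViX))
    Py <- P %*% pre$y
    KPy <- K %*% Py
    PKPy <- P %*% KPy
    PPy <- P %*% Py
    AI <- matrix(NA_real_, 2, 2)
    AI[1, 1] <- 0.5 * crossprod(KPy, PKPy)
    AI[1, 2] <- AI[2, 1] <- 0.5 * crossprod(Py, PKPy)
    AI[2, 2] <- 0.5 * crossprod(Py, PPy)
    acov <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(acov)) {
      gr <- c(s2e, -s2a) / (s2a + s2e)^2   # d h2 / d (s2a, s2e)
      h2_se <- sqrt(max(drop(t(gr) %*% acov %*% gr), 0))
    }
  }
  structure(list(sigma2_a = s2a, sigma2_e = s2e, lambda = s2e / s2a,
                 h2 = h2, h2_se = h2_se, converged = converged,
                 iterations = it),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("sigma2_a = %.4f  sigma2_e = %.4f  h2 = %.3f%s  (%s, %d iter)\n",
              x$sigma2_a, x$sigma2_e, x$h2,
              if (is.na(x$h2_se)) "" else sprintf(" +/- %.3f", x$h2_se),
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}

#' Genetic correlation between two traits by bivariate REML
#'
#' Fits the bivariate animal model for two traits recorded on the same
#' animals with a common fixed-effect design, maximizing the restricted
#' likelihood directly over the 2x2 genetic and residual covariance
#' matrices (log-Cholesky parameterization, so both stay positive
#' definite).  A single eigendecomposition of `K = W H W'` reduces every
#' likelihood evaluation to O(n) work.
#'
#' @param yA,yB Named record vectors on the same animal set.
#' @param X Common fixed-effect design (default intercept).
#' @param Hinv Inverse relationship matrix, dimnames = animal ids.
#' @param se Compute the SE of the genetic correlation via the numerical
#'   Hessian (default `TRUE`).
#' @return Object of class `genetic_correlation`: `rg`, `rg_se`, `G0`,
#'   `R0`, `h2_A`, `h2_B`, `converged`.
#' @export
estimate_genetic_correlation <- function(yA, yB, X = NULL, Hinv, se = TRUE) {
  if (length(yA) != length(yB) || !identical(names(yA), names(yB)))
    stop("yA and yB must cover the same animals in the same order",
         call. = FALSE)
  ids <- rownames(Hinv)
  W <- incidence_W(yA, ids)
  n <- length(yA)
  X <- as_X(X, n)
  p <- ncol(X)
  H <- solve((Hinv + t(Hinv)) / 2)
  K <- W %*% H %*% t(W)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  dk <- pmax(eg$values, 0)
  Ut <- t(eg$vectors)
  y1 <- drop(Ut %*% yA)
  y2 <- drop(Ut %*% yB)
  Xt <- Ut %*% X

  # theta = (log lg11, lg21, log lg22, log lr11, lr21, log lr22)
  unpack <- function(th) {
    LG <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    LR <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
    list(G0 = tcrossprod(LG), R0 = tcrossprod(LR))
  }
  negloglik <- function(th) {
    vc <- unpack(th)
    g <- vc$G0; r <- vc$R0
    s11 <- dk * g[1, 1] + r[1, 1]
    s12 <- dk * g[1, 2] + r[1, 2]
    s22 <- dk * g[2, 2] + r[2, 2]
    det2 <- s11 * s22 - s12^2
    if (any(det2 <= 0) || any(s11 <= 0)) return(1e10)
    i11 <- s22 / det2; i22 <- s11 / det2; i12 <- -s12 / det2
    # GLS for the stacked fixed effects (trait1 block, trait2 block)
    A11 <- crossprod(Xt, Xt * i11)
    A22 <- crossprod(Xt, Xt * i22)
    A12 <- crossprod(Xt, Xt * i12)
    A <- rbind(cbind(A11, A12), cbind(A12, A22))
    rhs <- c(crossprod(Xt, i11 * y1 + i12 * y2),
             crossprod(Xt, i12 * y1 + i22 * y2))
    chA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(chA)) return(1e10)
    b <- backsolve(chA, forwardsolve(t(chA), rhs))
    r1 <- y1 - drop(Xt %*% b[seq_len(p)])
    r2 <- y2 - drop(Xt %*% b[p + seq_len(p)])
    quad <- sum(r1 * (i11 * r1 + i12 * r2) + r2 * (i12 * r1 + i22 * r2))
    ll <- -0.5 * (sum(log(det2)) + 2 * sum(log(diag(chA))) + quad)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  v1 <- var(yA); v2 <- var(yB)
  th0 <- c(0.5 * log(v1 / 2), 0, 0.5 * log(v2 / 2),
           0.5 * log(v1 / 2), 0, 0.5 * log(v2 / 2))
  opt <- nlminb(th0, negloglik,
                control = list(iter.max = 500, eval.max = 1000))
  vc <- unpack(opt$par)
  G0 <- vc$G0; R0 <- vc$R0
  rg <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  rg_se <- NA_real_
  if (se) {
    Hh <- num_hess(negloglik, opt$par)
    acov <- tryCatch(solve((Hh + t(Hh)) / 2), error = function(e) NULL)
    if (!is.null(acov)) {
      rg_fun <- function(th) {
        v <- unpack(th)
        v$G0[1, 2] / sqrt(v$G0[1, 1] * v$G0[2, 2])
      }
      gr <- num_grad(rg_fun, opt$par)
      rg_se <- sqrt(max(drop(t(gr) %*% acov %*% gr), 0))
    }
  }
  structure(list(rg = rg, rg_se = rg_se, G0 = G0, R0 = R0,
                 h2_A = G0[1, 1] / (G0[1, 1] + R0[1, 1]),
                 h2_B = G0[2, 2] / (G0[2, 2] + R0[2, 2]),
                 converged = opt$convergence == 0,
                 loglik = -opt$objective),
            class = "genetic_correlation")
}

#' @export
print.genetic_correlation <- function(x, ...) {
  cat(sprintf("rg = %.3f%s  (h2_A %.3f, h2_B %.3f)\n", x$rg,
              if (is.na(x$rg_se)) "" else sprintf(" +/- %.3f", x$rg_se),
              x$h2_A, x$h2_B))
  invisible(x)
}

#' Back-solve SNP allele-substitution effects from breeding values
#'
#' Uses the standard identity `u_hat = Zc' G^-1 a_hat / k` with
#' `k = 2 sum p_j (1 - p_j)` the VanRaden scaling; when `G` is the
#' unblended VanRaden matrix of the same `Zc`, the reconstruction
#' `Zc u_hat` returns `a_hat` exactly.
#'
#' @param sol A `gblup_solution` (or a named GEBV vector).
#' @param Zc Centered dosage matrix of the genotyped animals (from
#'   [center_dosages()]; rownames = animal ids).
#' @param G_used The genomic matrix to invert; pass the unblended
#'   [genomic_G()] for exact reconstruction, or the blended matrix when G
#'   is singular (the reconstruction is then approximate).
#' @return Named per-SNP effect vector with attribute `scale_k`.
#' @export
backsolve_snp_effects <- function(sol, Zc, G_used) {
  gebv <- if (inherits(sol, "gblup_solution")) sol$gebv else sol
  ids <- rownames(Zc)
  a <- gebv[ids]
  if (anyNA(a)) stop("GEBVs missing for genotyped animals", call. = FALSE)
  k <- attr(Zc, "scale_k")
  if (is.null(k)) stop("Zc must carry the scale_k attribute", call. = FALSE)
  Gi_a <- tryCatch(solve(G_used, a), error = function(e)
    stop("G is singular; pass the blended matrix (blend_G) instead ",
         "(reconstruction will then be approximate)", call. = FALSE))
  u <- drop(crossprod(Zc, Gi_a)) / k
  names(u) <- colnames(Zc)
  attr(u, "scale_k") <- k
  u
}
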