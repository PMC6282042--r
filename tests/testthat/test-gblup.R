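# gblup module: MME solutions, EM-REML, genetic correlation, back-solving

test_that("infinite shrinkage drives GEBVs to zero and fixed effects to OLS", {
  set.seed(1)
  n <- 30
  ids <- paste0("a", 1:n)
  Hinv <- diag(n); dimnames(Hinv) <- list(ids, ids)
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("int", "x")
  y <- setNames(drop(X %*% c(1, 2)) + rnorm(n), ids)
  sol <- solve_mme(y, X, Hinv, lambda = 1e8)
  expect_lt(max(abs(sol$gebv)), 1e-5)
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(sol$fixed_solutions), unname(ols), tolerance = 1e-5)
})

test_that("identity H with one record per animal is ridge regression", {
  set.seed(2)
  n <- 40
  ids <- paste0("a", 1:n)
  Hinv <- diag(n); dimnames(Hinv) <- list(ids, ids)
  y <- setNames(rnorm(n), ids)
  X <- matrix(1, n, 1)
  lambda <- 3.7
  sol <- solve_mme(y, X, Hinv, lambda)
  # closed form: a = (I + lambda I)^-1 (y - mean-ish GLS intercept)
  b <- mean(y)                      # balanced design: intercept = mean of y
  a_direct <- (y - b) / (1 + lambda)
  expect_equal(unname(sol$gebv), unname(a_direct), tolerance = 1e-8)
})

test_that("pedigree BLUP equals a generic GLS/BLUP oracle (no genotypes)", {
  cfg <- tiny_sim_config(n_founders = 10, n_animals_target = 40,
                         n_sires = 4, n_snps = 50, seed = 5)
  sim <- simulate_dataset(cfg)
  A <- pedigree_A(sim$pedigree)
  Ainv <- solve(A); dimnames(Ainv) <- dimnames(A)
  y <- setNames(sim$latent_A, sim$pedigree$id)
  s2a <- 0.4; s2e <- 0.6
  sol <- solve_mme(y, NULL, Ainv, s2e / s2a)
  # oracle: b = GLS, a = s2a A W' V^-1 (y - X b)
  W <- diag(length(y))
  V <- s2a * W %*% A %*% t(W) + s2e * diag(length(y))
  X <- matrix(1, length(y), 1)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- s2a * A %*% t(W) %*% Vi %*% (y - X %*% b)
  expect_equal(unname(sol$gebv), drop(a), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(sol$fixed_solutions), drop(b), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("GBLUP with H = G reproduces SNP-BLUP exactly", {
  geno <- founder_genotypes(50, 200, seed = 3)
  # sample-frequency centering makes G exactly singular (1'Zc = 0), so the
  # exact equivalence uses the known founder frequencies
  p_true <- attr(geno$dosage, "true_freqs")
  G <- genomic_G(geno, freqs = p_true)
  Zc <- center_dosages(geno, freqs = p_true)
  k <- attr(Zc, "scale_k")
  n <- nrow(Zc); m <- ncol(Zc)
  set.seed(4)
  y <- setNames(drop(Zc %*% rnorm(m, 0, 0.05)) + rnorm(n), rownames(Zc))
  lambda <- 1.5
  # G may be numerically near-singular only if m < n; here m > n, fine
  Ginv <- solve(G)
  dimnames(Ginv) <- dimnames(G)
  sol <- solve_mme(y, NULL, Ginv, lambda)
  # SNP-BLUP with Var(u) = sigma2_a / k: ridge on Zc with lambda * k
  X <- matrix(1, n, 1)
  C <- rbind(cbind(crossprod(X), crossprod(X, Zc)),
             cbind(crossprod(Zc, X), crossprod(Zc) + diag(lambda * k, m)))
  rhs <- c(crossprod(X, y), crossprod(Zc, y))
  u <- solve(C, rhs)[-1]
  gebv_snp <- drop(Zc %*% u)
  expect_lt(max(abs(sol$gebv - gebv_snp)), 1e-8)
})

test_that("GEBV ranking is invariant to adding a constant to y", {
  geno <- founder_genotypes(30, 100, seed = 6)
  qc <- snp_qc(geno)
  G <- blend_G(genomic_G(qc$genotypes), diag(30), 0.98)
  Ginv <- solve(G)
  dimnames(Ginv) <- list(rownames(qc$genotypes$dosage),
                         rownames(qc$genotypes$dosage))
  set.seed(7)
  y <- setNames(rnorm(30), rownames(qc$genotypes$dosage))
  s1 <- solve_mme(y, NULL, Ginv, 1)
  s2 <- solve_mme(y + 100, NULL, Ginv, 1)
  expect_equal(unname(s1$gebv), unname(s2$gebv), tolerance = 1e-6)
})

test_that("EM-REML matches a direct-likelihood oracle on a small instance", {
  cfg <- tiny_sim_config(n_founders = 12, n_animals_target = 60,
                         n_sires = 4, n_snps = 60, seed = 8)
  sim <- simulate_dataset(cfg)
  A <- pedigree_A(sim$pedigree)
  Ainv <- solve(A); dimnames(Ainv) <- dimnames(A)
  y <- setNames(sim$latent_A, sim$pedigree$id)
  vc <- estimate_variance_components(y, NULL, Ainv, se = FALSE, tol = 1e-10,
                                     max_iter = 20000L)
  # oracle: maximize the restricted log-likelihood over (s2a, s2e) directly
  n <- length(y)
  X <- matrix(1, n, 1)
  negll <- function(par) {
    s2a <- exp(par[1]); s2e <- exp(par[2])
    V <- s2a * A + diag(s2e, n)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    b <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - drop(X %*% b)
    0.5 * (2 * sum(log(diag(ch))) + log(det(XtViX)) +
             drop(crossprod(r, Vi %*% r)))
  }
  opt <- optim(log(c(0.5, 0.5)), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  expect_equal(vc$sigma2_a, exp(opt$par[1]), tolerance = 0.02)
  expect_equal(vc$sigma2_e, exp(opt$par[2]), tolerance = 0.02)
})

test_that("EM-REML null simulations keep h2 small", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    cfg <- tiny_sim_config(n_founders = 120, n_animals_target = 800,
                           n_sires = 30, n_snps = 600, n_chromosomes = 6,
                           h2_A = 0, h2_B = 0, beta_causal = 0,
                           rg_target = NULL, seed = 1000L + s)
    sim <- simulate_dataset(cfg)
    qc <- snp_qc(sim$genotypes)
    hs <- make_single_step_Hinv(sim$pedigree, qc$genotypes)
    y <- setNames(sim$latent_A, sim$pedigree$id)
    # at the h2 = 0 boundary EM legitimately hits the iteration cap
    vc <- suppressWarnings(
      estimate_variance_components(y, NULL, hs$Hinv, se = FALSE))
    if (vc$h2 < 0.1) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # >= 90% of seeds
})

test_that("variance components are scale-equivariant", {
  cfg <- tiny_sim_config(n_founders = 40, n_animals_target = 200,
                         n_sires = 8, n_snps = 150, seed = 10)
  sim <- simulate_dataset(cfg)
  qc <- snp_qc(sim$genotypes)
  hs <- make_single_step_Hinv(sim$pedigree, qc$genotypes)
  y <- setNames(sim$latent_A, sim$pedigree$id)
  v1 <- estimate_variance_components(y, NULL, hs$Hinv, se = FALSE)
  v2 <- estimate_variance_components(2 * y, NULL, hs$Hinv, se = FALSE)
  expect_equal(v2$sigma2_a, 4 * v1$sigma2_a, tolerance = 1e-3)
  expect_equal(v2$sigma2_e, 4 * v1$sigma2_e, tolerance = 1e-3)
  expect_equal(v2$h2, v1$h2, tolerance = 1e-5)
})

test_that("genetic correlation: identical traits give rg = 1", {
  cfg <- tiny_sim_config(n_founders = 50, n_animals_target = 250,
                         n_sires = 10, n_snps = 200, seed = 11)
  sim <- simulate_dataset(cfg)
  qc <- snp_qc(sim$genotypes)
  hs <- make_single_step_Hinv(sim$pedigree, qc$genotypes)
  y <- setNames(sim$latent_A, sim$pedigree$id)
  rg <- estimate_genetic_correlation(y, y + 1e-8 * rnorm(length(y)), NULL,
                                     hs$Hinv, se = FALSE)
  expect_lt(abs(rg$rg - 1), 1e-3)
})

test_that("genetic correlation is ~0 for independent genetic effects", {
  rgs <- numeric(0)
  for (s in 1:10) {
    cfg <- tiny_sim_config(n_founders = 80, n_animals_target = 400,
                           n_sires = 16, n_snps = 300, beta_causal = 0,
                           rg_target = NULL, seed = 2000L + s)
    sim <- simulate_dataset(cfg)
    qc <- snp_qc(sim$genotypes)
    hs <- make_single_step_Hinv(sim$pedigree, qc$genotypes)
    rg <- estimate_genetic_correlation(
      setNames(sim$latent_A, sim$pedigree$id),
      setNames(sim$latent_B, sim$pedigree$id), NULL, hs$Hinv, se = FALSE)
    rgs <- c(rgs, rg$rg)
  }
  expect_lt(abs(mean(rgs)), 0.1)
})

test_that("bivariate REML matches a dense direct-likelihood oracle", {
  cfg <- tiny_sim_config(n_founders = 10, n_animals_target = 40,
                         n_sires = 4, n_snps = 80, seed = 12)
  sim <- simulate_dataset(cfg)
  A <- pedigree_A(sim$pedigree)
  Ainv <- solve(A); dimnames(Ainv) <- dimnames(A)
  yA <- setNames(sim$latent_A, sim$pedigree$id)
  yB <- setNames(sim$latent_B, sim$pedigree$id)
  fit <- estimate_genetic_correlation(yA, yB, NULL, Ainv, se = FALSE)
  # oracle: brute-force REML log-likelihood with dense 2n x 2n matrices
  n <- length(yA)
  X2 <- kronecker(diag(2), matrix(1, n, 1))
  yy <- c(yA, yB)
  negll <- function(th) {
    LG <- matrix(c(exp(th[1]), th[2], 0, exp(th[3])), 2, 2)
    LR <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2)
    G0 <- tcrossprod(LG); R0 <- tcrossprod(LR)
    V <- kronecker(G0, A) + kronecker(R0, diag(n))
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X2, Vi %*% X2)
    b <- solve(XtViX, crossprod(X2, Vi %*% yy))
    r <- yy - drop(X2 %*% b)
    0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
             drop(crossprod(r, Vi %*% r)))
  }
  opt <- nlminb(c(log(0.5), 0, log(0.3), log(0.5), 0, log(0.3)), negll,
                control = list(iter.max = 1000))
  LG <- matrix(c(exp(opt$par[1]), opt$par[2], 0, exp(opt$par[3])), 2, 2)
  G0_or <- tcrossprod(LG)
  rg_or <- G0_or[1, 2] / sqrt(G0_or[1, 1] * G0_or[2, 2])
  expect_equal(fit$loglik, -opt$objective, tolerance = 1e-4)
  expect_equal(fit$rg, rg_or, tolerance = 0.02)
})

test_that("back-solved SNP effects reconstruct GEBVs", {
  geno <- founder_genotypes(50, 200, seed = 13)
  p_true <- attr(geno$dosage, "true_freqs")
  G <- genomic_G(geno, freqs = p_true)
  Zc <- center_dosages(geno, freqs = p_true)
  Ginv <- solve(G); dimnames(Ginv) <- dimnames(G)
  set.seed(14)
  y <- setNames(drop(Zc %*% rnorm(ncol(Zc), 0, 0.05)) + rnorm(50),
                rownames(Zc))
  sol <- solve_mme(y, NULL, Ginv, 1.2)
  # zero GEBVs -> zero effects
  z <- sol; z$gebv[] <- 0
  expect_true(all(backsolve_snp_effects(z, Zc, G) == 0))
  # unblended G: exact algebraic identity
  u <- backsolve_snp_effects(sol, Zc, G)
  expect_lt(max(abs(drop(Zc %*% u) - sol$gebv)), 1e-8)
  # blended G: approximate reconstruction, relative error < 0.1
  A22 <- diag(50); dimnames(A22) <- dimnames(G)
  Gb <- blend_G(G, A22, 0.95)
  ub <- backsolve_snp_effects(sol, Zc, Gb)
  rel <- max(abs(drop(Zc %*% ub) - sol$gebv)) / max(abs(sol$gebv))
  expect_lt(rel, 0.1)
})

test_that("singular fixed-effect block is reported with column names", {
  set.seed(15)
  n <- 20
  ids <- paste0("a", 1:n)
  Hinv <- diag(n); dimnames(Hinv) <- list(ids, ids)
  y <- setNames(rnorm(n), ids)
  X <- cbind(int = 1, dup = 1)
  expect_error(solve_mme(y, X, Hinv, 1), "aliased|dup")
})
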