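# kinship module: QC, A, G, blending, single-step H inverse

test_that("snp_qc applies rules in order with first-fail accounting", {
  # 10 animals x 5 SNPs: col1 fixed, col2 rare (MAF 1/20 = 0.05), col3 50%
  # missing, col4-5 clean
  d <- cbind(rep(2L, 10),
             c(1L, rep(0L, 9)),
             c(rep(NA_integer_, 5), 1L, 1L, 0L, 1L, 0L),
             rep(c(0L, 1L, 2L, 1L, 0L), 2),
             rep(c(2L, 1L, 0L, 1L, 1L), 2))
  rownames(d) <- paste0("a", 1:10)
  colnames(d) <- paste0("s", 1:5)
  geno <- structure(list(dosage = d,
                         map = data.frame(snp = colnames(d), chrom = 1,
                                          pos = 1:5 * 1000)),
                    class = "genotype_matrix")
  res <- snp_qc(geno, maf_min = 0.06, callrate_min = 0.9)
  expect_equal(res$report$n_retained, 2L)
  expect_equal(res$report$removed_monomorphic, 1L)
  expect_equal(res$report$removed_maf, 1L)
  expect_equal(res$report$removed_callrate, 1L)
  expect_equal(res$report$n_input_snps,
               with(res$report, n_retained + removed_monomorphic +
                      removed_maf + removed_callrate))
  expect_false(anyNA(res$genotypes$dosage))
})

test_that("clean input passes snp_qc unchanged", {
  geno <- founder_genotypes(50, 40, seed = 2)
  res <- snp_qc(geno)
  expect_equal(res$genotypes$dosage, geno$dosage, ignore_attr = TRUE)
  expect_equal(res$report$n_retained, 40L)
})

test_that("snp_qc erroring when everything fails", {
  d <- matrix(2L, 5, 3, dimnames = list(paste0("a", 1:5), paste0("s", 1:3)))
  geno <- structure(list(dosage = d,
                         map = data.frame(snp = colnames(d), chrom = 1,
                                          pos = 1:3)),
                    class = "genotype_matrix")
  expect_error(snp_qc(geno), "every SNP")
})

test_that("pedigree_A closed forms: founders, trio, full-sib mating", {
  founders <- make_ped(1:3, rep(NA, 3), rep(NA, 3))
  expect_equal(unname(pedigree_A(founders)), diag(3), ignore_attr = TRUE)

  trio <- make_ped(1:3, c(NA, NA, 1), c(NA, NA, 2))
  A <- pedigree_A(trio)
  expect_equal(A["3", "1"], 0.5)
  expect_equal(A["3", "3"], 1)

  # offspring of a full-sib mating: F = 0.25
  fs <- make_ped(1:5, c(NA, NA, 1, 1, 3), c(NA, NA, 2, 2, 4))
  A5 <- pedigree_A(fs)
  expect_equal(A5["5", "5"], 1.25)
  expect_equal(A5["3", "4"], 0.5)
})

test_that("tabular A equals the exhaustive gene-drop enumeration oracle", {
  peds <- list(
    make_ped(1:3, c(NA, NA, 1), c(NA, NA, 2)),
    make_ped(1:5, c(NA, NA, 1, 1, 3), c(NA, NA, 2, 2, 4)),
    # grandparental loop with inbreeding
    make_ped(1:7, c(NA, NA, 1, 1, 3, 3, 5), c(NA, NA, 2, 2, 4, 4, 6)),
    make_ped(1:8, c(NA, NA, NA, 1, 1, 4, 4, 6), c(NA, NA, NA, 2, 3, 5, 5, 7)))
  for (s in 1:12) peds[[length(peds) + 1L]] <- random_small_pedigree(s)
  for (ped in peds) {
    A_tab <- pedigree_A(ped)
    A_enum <- kinship_enum_oracle(ped)
    expect_equal(A_tab, A_enum, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("pedigree cycles are detected", {
  bad <- make_ped(1:3, c(3, NA, 1), c(NA, NA, 2))
  expect_error(pedigree_A(bad), "cycle|ancestor")
})

test_that("genomic_G: duplicates, hand-computed case, diagonal ~ 1", {
  geno <- founder_genotypes(20, 60, seed = 3)
  geno$dosage[2, ] <- geno$dosage[1, ]   # duplicate animals
  G <- genomic_G(geno)
  expect_equal(G[1, 1], G[2, 2])
  expect_equal(G[1, 2], G[1, 1])

  # 3 animals x 4 SNPs by hand
  d <- matrix(c(0, 1, 2,
                2, 1, 0,
                1, 1, 1,
                0, 0, 2), 3, 4,
              dimnames = list(c("x", "y", "z"), paste0("s", 1:4)))
  g2 <- structure(list(dosage = d, map = NULL), class = "genotype_matrix")
  p <- colMeans(d) / 2
  Zc <- sweep(d, 2, 2 * p)
  k <- 2 * sum(p * (1 - p))
  expect_equal(unname(genomic_G(g2)), unname(tcrossprod(Zc) / k),
               ignore_attr = TRUE)

  # equilibrium population: mean diagonal ~ 1
  big <- founder_genotypes(500, 2000, seed = 4)
  Gd <- genomic_G(big)
  expect_lt(abs(mean(diag(Gd)) - 1), 0.05)

  # boundary frequency is an error
  d[, 1] <- 0
  g3 <- structure(list(dosage = d, map = NULL), class = "genotype_matrix")
  expect_error(genomic_G(g3), "frequency 0 or 1")
})

test_that("blend_G limits and positive-definiteness repair", {
  geno <- founder_genotypes(15, 50, seed = 5)
  geno$dosage[2, ] <- geno$dosage[1, ]
  G <- genomic_G(geno)
  A22 <- diag(nrow(G))
  dimnames(A22) <- dimnames(G)
  expect_equal(unname(blend_G(G, A22, 1)), unname(G), ignore_attr = TRUE)
  expect_equal(unname(blend_G(G, A22, 0)), unname(A22), ignore_attr = TRUE)
  expect_lt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
  Gb <- blend_G(G, A22, 0.95)
  expect_gt(min(eigen(Gb, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(blend_G(G, A22, 1.2), "alpha")
})

test_that("H-inverse limits: no genotypes, and G = A22 cancellation", {
  ped <- make_ped(1:6, c(NA, NA, 1, 1, 3, 3), c(NA, NA, 2, 2, 4, 4))
  A <- pedigree_A(ped)
  Ainv <- solve(A)
  dimnames(Ainv) <- dimnames(A)
  expect_equal(unname(build_H_inverse(Ainv, NULL, NULL, character(0))),
               unname(Ainv), ignore_attr = TRUE)
  gids <- c("3", "5")
  A22 <- A[gids, gids]
  H1 <- build_H_inverse(Ainv, solve(A22), solve(A22), gids)
  expect_equal(unname(H1), unname(Ainv), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("H from inverting H^-1 matches the direct-H oracle", {
  cfg <- tiny_sim_config(n_founders = 4, n_generations = 3, n_sires = 2,
                         n_animals_target = 10, n_snps = 80, seed = 21)
  sim <- simulate_dataset(cfg)
  ped <- sim$pedigree
  A <- pedigree_A(ped)
  gids <- as.character(ped$id[7:10])           # 4 genotyped animals
  geno <- sim$genotypes
  geno$dosage <- geno$dosage[gids, , drop = FALSE]
  qc <- snp_qc(geno)
  G <- genomic_G(qc$genotypes)
  A22 <- A[gids, gids]
  Gb <- blend_G(G, A22, 0.95)
  Ainv <- solve(A); dimnames(Ainv) <- dimnames(A)
  Hinv <- build_H_inverse(Ainv, solve(A22), solve(Gb), gids)
  H <- solve(Hinv)

  # direct H construction (block formulas over non-genotyped/genotyped)
  ids <- rownames(A)
  n1 <- setdiff(ids, gids)
  A11 <- A[n1, n1]; A12 <- A[n1, gids]; A22i <- solve(A22)
  H_or <- A
  H_or[gids, gids] <- Gb
  H_or[n1, gids] <- A12 %*% A22i %*% Gb
  H_or[gids, n1] <- t(H_or[n1, gids])
  H_or[n1, n1] <- A11 + A12 %*% A22i %*% (Gb - A22) %*% A22i %*% t(A12)
  expect_equal(unname(H), unname(H_or), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("genotyped ids must be a pedigree subset", {
  ped <- make_ped(1:3, c(NA, NA, 1), c(NA, NA, 2))
  A <- pedigree_A(ped)
  Ainv <- solve(A); dimnames(Ainv) <- dimnames(A)
  expect_error(build_H_inverse(Ainv, diag(1), diag(1), "99"), "subset")
})
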