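# Shared fixtures and independent oracles used across test files.

# quick pedigree constructor (parents listed before offspring)
make_ped <- function(id, sire, dam) {
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = NA_integer_, sex = NA_character_,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# Exact additive-relationship oracle by exhaustive enumeration of
# inheritance vectors (independent of the tabular recursion): every
# non-founder gamete picks one of its parent's two alleles, so a pedigree
# with k non-founders has 4^k equally likely inheritance patterns.  For
# each pattern alleles are traced to founder-allele labels and the kinship
# coefficient is the average probability that randomly drawn alleles from
# i and j share a label.  A = 2 * Phi.
kinship_enum_oracle <- function(ped) {
  n <- nrow(ped)
  id <- as.character(ped$id)
  sire <- match(as.character(ped$sire), id)
  dam <- match(as.character(ped$dam), id)
  nonf <- which(!is.na(sire))
  k <- length(nonf)
  stopifnot(4^k <= 5e5)
  Phi <- matrix(0, n, n)
  pat <- mat <- integer(n)
  n_combo <- 4^k
  for (combo in seq_len(n_combo) - 1L) {
    bits <- combo
    for (i in seq_len(n)) {
      if (is.na(sire[i])) {
        pat[i] <- 2L * i - 1L
        mat[i] <- 2L * i
      }
    }
    for (idx in seq_len(k)) {
      i <- nonf[idx]
      c1 <- bits %% 2L; bits <- bits %/% 2L
      c2 <- bits %% 2L; bits <- bits %/% 2L
      s <- sire[i]; d <- dam[i]
      pat[i] <- if (c1 == 0L) pat[s] else mat[s]
      mat[i] <- if (c2 == 0L) pat[d] else mat[d]
    }
    for (i in seq_len(n)) for (j in i:n) {
      share <- (pat[i] == pat[j]) + (pat[i] == mat[j]) +
        (mat[i] == pat[j]) + (mat[i] == mat[j])
      Phi[i, j] <- Phi[i, j] + share / 4
    }
  }
  Phi <- Phi / n_combo
  Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
  A <- 2 * Phi
  dimnames(A) <- list(id, id)
  A
}

# random valid small pedigree (<= 8 animals, >= 2 founders)
random_small_pedigree <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  nf <- sample(2:min(4, n - 1), 1)
  sire <- dam <- rep(NA_integer_, n)
  for (i in (nf + 1):n) {
    pair <- sample.int(i - 1L, 2L)
    sire[i] <- pair[1]; dam[i] <- pair[2]
  }
  make_ped(seq_len(n), sire, dam)
}

# small default simulation, cheap enough for unit tests
tiny_sim_config <- function(...) {
  args <- list(n_founders = 40, n_generations = 3, n_sires = 10,
               n_animals_target = 150, n_snps = 200, n_chromosomes = 4,
               seed = 42)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(sim_config, args)
}

# minimal multivariate normal sampler (keeps MASS out of the suite)
mvn_sample <- function(n, Sigma) {
  p <- ncol(Sigma)
  matrix(rnorm(n * p), n, p) %*% chol(Sigma)
}

# founder-only genotypes: unrelated animals in linkage equilibrium
founder_genotypes <- function(n, m, seed, maf = c(0.1, 0.45)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m,
              dimnames = list(paste0("a", seq_len(n)),
                              paste0("snp", seq_len(m))))
  attr(d, "true_freqs") <- p
  nchr <- max(1L, m %/% 100L)
  sizes <- rep(m %/% nchr, nchr)
  sizes[seq_len(m %% nchr)] <- sizes[seq_len(m %% nchr)] + 1L
  geno <- list(dosage = d,
               map = data.frame(snp = colnames(d),
                                chrom = rep(seq_len(nchr), sizes),
                                pos = unlist(lapply(sizes, function(k)
                                  100000L + 50000L * (seq_len(k) - 1L)))))
  class(geno) <- "genotype_matrix"
  geno
}
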