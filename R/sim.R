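#' Simulate a multi-generation pedigree with a restricted sire pool
#'
#' Builds a pedigree of `cfg$n_animals_target` animals over
#' `cfg$n_generations` generation layers.  Generation 1 holds the founders
#' (alternating sexes); each later generation is produced by mating a pool
#' of sires drawn from the males of the previous generation to randomly
#' chosen dams of the previous generation.  The sire pool is sized so that
#' exactly `cfg$n_sires` distinct sires have progeny, mimicking herds where
#' a few hundred phenotyped steers descend from a limited set of sires.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame of class `pedigree_table` with columns `id`,
#'   `sire`, `dam` (NA for founders), `generation` and `sex`.
#' @export
simulate_pedigree <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n_off_gens <- cfg$n_generations - 1L
  if (n_off_gens < 1L) {
    ped <- data.frame(id = seq_len(cfg$n_founders), sire = NA_integer_,
                      dam = NA_integer_, generation = 1L,
                      sex = rep_len(c("M", "F"), cfg$n_founders),
                      stringsAsFactors = FALSE)
    class(ped) <- c("pedigree_table", "data.frame")
    return(ped)
  }
  n_off_total <- cfg$n_animals_target - cfg$n_founders
  if (n_off_total < n_off_gens)
    stop("n_animals_target too small for the requested generations",
         call. = FALSE)
  # split offspring and sires over generations, remainders to the early ones
  n_off <- rep(n_off_total %/% n_off_gens, n_off_gens)
  extra <- n_off_total %% n_off_gens
  if (extra > 0L) n_off[seq_len(extra)] <- n_off[seq_len(extra)] + 1L
  n_sire_gen <- rep(cfg$n_sires %/% n_off_gens, n_off_gens)
  extra <- cfg$n_sires %% n_off_gens
  if (extra > 0L) n_sire_gen[seq_len(extra)] <- n_sire_gen[seq_len(extra)] + 1L
  if (any(n_sire_gen < 1L))
    stop("n_sires too small: need at least one sire per offspring generation",
         call. = FALSE)
  if (any(n_sire_gen > n_off))
    stop("n_sires larger than the number of offspring available to sire",
         call. = FALSE)

  id <- seq_len(cfg$n_founders)
  sire <- dam <- rep(NA_integer_, cfg$n_founders)
  generation <- rep(1L, cfg$n_founders)
  sex <- rep_len(c("M", "F"), cfg$n_founders)

  for (g in seq_len(n_off_gens)) {
    prev <- which(generation == g)
    males <- id[prev][sex[prev] == "M"]
    females <- id[prev][sex[prev] == "F"]
    if (length(males) < n_sire_gen[g])
      stop("impossible mating structure: generation ", g, " has ",
           length(males), " males but ", n_sire_gen[g], " sires requested",
           call. = FALSE)
    if (length(females) < 1L)
      stop("impossible mating structure: no dams in generation ", g,
           call. = FALSE)
    pool <- if (length(males) == 1L) males else
      sample(males, n_sire_gen[g])
    n_g <- n_off[g]
    # guarantee every pool sire has progeny, fill the rest at random
    s_g <- c(pool, if (n_g > length(pool))
      pool[sample.int(length(pool), n_g - length(pool), replace = TRUE)])
    s_g <- s_g[sample.int(n_g)]
    d_g <- females[sample.int(length(females), n_g, replace = TRUE)]
    new_id <- max(id) + seq_len(n_g)
    id <- c(id, new_id)
    sire <- c(sire, s_g)
    dam <- c(dam, d_g)
    generation <- c(generation, rep(g + 1L, n_g))
    sex <- c(sex, rep_len(c("M", "F"), n_g))
  }
  ped <- data.frame(id = id, sire = sire, dam = dam,
                    generation = generation, sex = sex,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Gene-drop genotypes through a pedigree
#'
#' Founder alleles are drawn from per-SNP frequencies sampled uniformly
#' within `cfg$maf_range` (founders are in linkage equilibrium); each
#' offspring inherits one uniformly chosen allele per locus from each
#' parent, so the dosages are Mendelian-consistent with the pedigree by
#' construction.  Loci are unlinked: the only LD in the sample is the
#' family structure itself.
#'
#' @param ped A `pedigree_table` (parents must precede offspring).
#' @param cfg A [sim_config()].
#' @param founder_freqs Optional vector of `cfg$n_snps` founder allele
#'   frequencies overriding the uniform draw (values 0 or 1 simulate fixed
#'   loci).
#' @return An object of class `genotype_matrix`: a list with `dosage`
#'   (animals x SNPs matrix in 0/1/2, NA for missing calls) and `map`
#'   (data.frame `snp`, `chrom`, `pos` sorted by chromosome and position).
#' @export
drop_genotypes <- function(ped, cfg, founder_freqs = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 1L)
  m <- cfg$n_snps
  na <- nrow(ped)
  p <- if (is.null(founder_freqs))
    runif(m, cfg$maf_range[1], cfg$maf_range[2]) else rep_len(founder_freqs, m)
  h1 <- matrix(0L, na, m)
  h2 <- matrix(0L, na, m)
  founder <- is.na(ped$sire)
  nf <- sum(founder)
  h1[founder, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  h2[founder, ] <- matrix(rbinom(nf * m, 1L, rep(p, each = nf)), nf, m)
  row_of <- setNames(seq_len(na), ped$id)
  for (i in which(!founder)) {
    s <- row_of[as.character(ped$sire[i])]
    d <- row_of[as.character(ped$dam[i])]
    if (is.na(s) || is.na(d) || s >= i || d >= i)
      stop("pedigree must list parents before offspring", call. = FALSE)
    pick_s <- runif(m) < 0.5
    pick_d <- runif(m) < 0.5
    h1[i, ] <- ifelse(pick_s, h1[s, ], h2[s, ])
    h2[i, ] <- ifelse(pick_d, h1[d, ], h2[d, ])
  }
  dosage <- h1 + h2
  if (cfg$missing_rate > 0) {
    miss <- runif(length(dosage)) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }
  rownames(dosage) <- as.character(ped$id)
  # even split of SNPs over chromosomes, fixed 50 kb spacing
  chrom_sizes <- rep(m %/% cfg$n_chromosomes, cfg$n_chromosomes)
  extra <- m %% cfg$n_chromosomes
  if (extra > 0L) chrom_sizes[seq_len(extra)] <- chrom_sizes[seq_len(extra)] + 1L
  chrom <- rep(seq_len(cfg$n_chromosomes), chrom_sizes)
  pos <- unlist(lapply(chrom_sizes, function(k) 100000L + 50000L * (seq_len(k) - 1L)),
                use.names = FALSE)
  colnames(dosage) <- paste0("snp", seq_len(m))
  geno <- list(dosage = dosage,
               map = data.frame(snp = colnames(dosage), chrom = chrom,
                                pos = pos, stringsAsFactors = FALSE))
  class(geno) <- "genotype_matrix"
  geno
}

#' Check Mendelian consistency of dosages against a pedigree
#'
#' For every offspring/SNP pair with non-missing trio dosages, tests whether
#' the offspring dosage can be formed from one allele of each parent.
#'
#' @param geno A `genotype_matrix`.
#' @param ped The matching `pedigree_table`.
#' @return Number of violating (animal, SNP) pairs.
#' @export
count_mendelian_violations <- function(geno, ped) {
  d <- geno$dosage
  row_of <- setNames(seq_len(nrow(ped)), as.character(ped$id))
  bad <- 0L
  lo <- function(x) ifelse(x >= 1L, ifelse(x == 2L, 1L, 0L), 0L)  # min allele
  hi <- function(x) ifelse(x >= 1L, 1L, 0L)                       # max allele
  for (i in which(!is.na(ped$sire))) {
    s <- d[row_of[as.character(ped$sire[i])], ]
    m <- d[row_of[as.character(ped$dam[i])], ]
    o <- d[i, ]
    ok <- is.na(o) | is.na(s) | is.na(m) |
      (o >= lo(s) + lo(m) & o <= hi(s) + hi(m))
    bad <- bad + sum(!ok)
  }
  bad
}

# scale a vector to an exact sample variance (0 allowed)
scale_to_var <- function(x, v) {
  if (v <= 0) return(numeric(length(x)))
  sx <- stats::sd(x)
  if (sx == 0) stop("cannot rescale a constant vector to positive variance",
                    call. = FALSE)
  (x - mean(x)) * sqrt(v) / sx
}

# residualize x on the columns of M (least squares), keep centering
residualize <- function(x, M) {
  M <- cbind(1, M)
  qr.resid(qr(M), x)
}

# combine planted (q) and polygenic (pg) genetic values so the total has
# exactly the target variance; the planted part is never rescaled.
combine_genic <- function(q, pg, target) {
  if (target <= 0) return(numeric(length(q)))
  vq <- var(q)
  if (vq > target + 1e-12)
    stop("planted QTL variance (", signif(vq, 3),
         ") exceeds the genetic variance budget (", signif(target, 3), ")",
         call. = FALSE)
  if (var(pg) < 1e-300) {
    if (vq < target * 0.99)
      stop("no polygenic variance available to reach the h2 target",
         call. = FALSE)
    return(q - mean(q))
  }
  cv <- cov(q, pg)
  vp <- var(pg)
  disc <- cv^2 + vp * (target - vq)
  cc <- (-cv + sqrt(max(disc, 0))) / vp
  out <- q + cc * pg
  out - mean(out)
}

#' Simulate latent traits, indicators and fixed effects on a genotyped pedigree
#'
#' Generates the full stated world of the analysis: polygenic plus planted
#' QTL genetic values for an upstream latent trait A and a downstream
#' latent trait B linked by the causal path `beta_causal`; environmental
#' deviations; six observed indicator traits (three per latent, classic
#' factor structure with measurement error); and additive year-of-birth and
#' slaughter-age fixed effects on the indicators.
#'
#' Realized variances are calibrated exactly to the configured targets by
#' rescaling the polygenic and environmental draws (planted QTL effects are
#' never rescaled), so a dataset's true heritabilities and genetic
#' correlation equal the configured values up to the planted-QTL sampling
#' wiggle.  Indirect-class QTL touch only the genetics of A; their entire
#' effect on B flows through the causal path.
#'
#' @param ped A `pedigree_table`.
#' @param geno The matching `genotype_matrix`.
#' @param cfg The [sim_config()] used to create both.
#' @return An object of class `sim_data`: list with `pedigree`, `genotypes`,
#'   `tbv_A`, `tbv_B` (true breeding values), `latent_A`, `latent_B`,
#'   `indicators` (data.frame QG/FOR/MARB/JC/TD/CT), `fixed` (data.frame
#'   `animal`, `year`, `slaughter_age`), `qtl` (planted QTL bookkeeping) and
#'   `params` (the derived variance plan).
#' @export
simulate_latent_traits <- function(ped, geno, cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)
  plan <- derive_variance_plan(cfg)
  na <- nrow(ped)
  dos <- geno$dosage
  if (anyNA(dos)) { # impute for trait generation only
    pj <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    dos[idx] <- pj[idx[, 2]]
  }
  pj <- colMeans(dos) / 2
  Zc <- sweep(dos, 2, 2 * pj)
  m <- ncol(Zc)

  # planted QTL: one central SNP per listed window
  qtl <- NULL
  qA <- qB <- numeric(na)
  if (!is.null(cfg$qtl_plan) && nrow(cfg$qtl_plan) > 0) {
    qp <- cfg$qtl_plan
    if ("share" %in% names(qp)) {
      # most informative SNP of the window: share-based architectures are
      # calibrated in variance units, and a common allele carries that
      # variance with the least estimation wobble
      snp_idx <- vapply(qp$window, function(wdw) {
        lo <- (wdw - 1L) * cfg$window_size + 1L
        hi <- min(wdw * cfg$window_size, m)
        het <- pj[lo:hi] * (1 - pj[lo:hi])
        lo + which.max(het) - 1L
      }, 0L)
    } else {
      snp_idx <- pmin((qp$window - 1L) * cfg$window_size +
                        ceiling(cfg$window_size / 2), m)
    }
    # realized dosage variance (family structure inflates it beyond 2pq)
    two_pq <- apply(Zc[, snp_idx, drop = FALSE], 2, var)
    is_A <- qp$class %in% c("direct_A", "pleiotropic", "indirect")
    is_B <- qp$class %in% c("direct_B", "pleiotropic")
    if ("share" %in% names(qp)) {
      # effects expressed as target fractions of the latent's genetic
      # variance; the allele-substitution effect is back-computed from the
      # realized allele frequency so planted shares do not drift with the
      # founder frequency draw
      share_b <- if ("share_b" %in% names(qp))
        ifelse(is.na(qp$share_b), qp$share, qp$share_b) else qp$share
      a_A <- ifelse(is_A, sqrt(qp$share * plan$s2g_A / two_pq), 0)
      a_B <- ifelse(is_B & qp$class != "direct_A",
                    sqrt(ifelse(qp$class == "pleiotropic", share_b,
                                qp$share) * plan$s2g_B_tot / two_pq), 0)
      a_B[!is_B] <- 0
      # family-structure covariance between QTL columns would inflate the
      # planted variance beyond its share budget; orthogonalize the planted
      # components sequentially and recalibrate each to its exact target
      ortho_calibrate <- function(effects, targets) {
        out <- matrix(0, na, length(effects))
        for (j in seq_along(effects)) {
          if (effects[j] == 0 || targets[j] <= 0) next
          v <- Zc[, snp_idx[j]] * effects[j]
          prev <- out[, seq_len(j - 1), drop = FALSE]
          prev <- prev[, colSums(prev^2) > 0, drop = FALSE]
          if (ncol(prev)) v <- residualize(v, prev)
          out[, j] <- scale_to_var(v, targets[j])
        }
        rowSums(out)
      }
      qA <- ortho_calibrate(a_A, qp$share * plan$s2g_A)
      shb <- ifelse(qp$class == "pleiotropic", share_b, qp$share)
      qB <- ortho_calibrate(a_B, shb * plan$s2g_B_tot)
      qtl <- data.frame(window = qp$window, class = qp$class, snp = snp_idx,
                        snp_name = colnames(Zc)[snp_idx],
                        effect_A = a_A, effect_B = a_B)
    } else {
      a_A <- ifelse(is_A, qp$size, 0)
      size_b <- if ("size_b" %in% names(qp))
        ifelse(is.na(qp$size_b), qp$size, qp$size_b) else qp$size
      # effects are configured in latent-SD units
      a_B <- ifelse(qp$class == "direct_B", qp$size,
                    ifelse(qp$class == "pleiotropic", size_b, 0)) *
        sqrt(plan$var_B)
      qA <- drop(Zc[, snp_idx, drop = FALSE] %*% a_A)
      qB <- drop(Zc[, snp_idx, drop = FALSE] %*% a_B)
      qtl <- data.frame(window = qp$window, class = qp$class, snp = snp_idx,
                        snp_name = colnames(Zc)[snp_idx],
                        effect_A = a_A, effect_B = a_B)
    }
  }
  poly_snps <- setdiff(seq_len(m), if (is.null(qtl)) integer(0) else qtl$snp)
  if (cfg$polygenic_fraction < 1)
    poly_snps <- poly_snps[seq_len(max(1L, floor(length(poly_snps) *
                                                   cfg$polygenic_fraction)))]
  Zp <- Zc[, poly_snps, drop = FALSE]
  pgA <- drop(Zp %*% rnorm(length(poly_snps)))
  pgB <- drop(Zp %*% rnorm(length(poly_snps)))

  g_A <- combine_genic(qA, pgA, plan$s2g_A)
  # independent genetic part of B: polygenic piece orthogonalized against
  # g_A so the realized genetic correlation comes from the path (and any
  # planted pleiotropy) alone
  pgB_o <- if (plan$s2g_A > 0 && var(pgB) > 0) residualize(pgB, cbind(g_A)) else pgB
  g_Bd <- combine_genic(qB, pgB_o, plan$s2g_Bd)

  e_A <- rnorm(na)
  e_A <- scale_to_var(if (var(g_A) > 0) residualize(e_A, cbind(g_A, g_Bd)) else e_A,
                      plan$s2e_A)
  e_B <- rnorm(na)
  keep <- cbind(g_A, g_Bd, e_A)
  e_B <- scale_to_var(residualize(e_B, keep), plan$s2e_B)

  latent_A <- g_A + e_A
  latent_B <- cfg$beta_causal * latent_A + g_Bd + e_B
  tbv_A <- g_A
  tbv_B <- cfg$beta_causal * g_A + g_Bd

  # measurement model
  lam <- c(cfg$loadings_A, cfg$loadings_B)
  sds <- cfg$indicator_residual_sds
  if (is.null(sds)) {
    # standardized loading 0.8 per indicator: theta = lambda^2 var * (1/.64 - 1)
    latv <- c(rep(plan$var_A, 3), rep(plan$var_B, 3))
    sds <- sqrt(lam^2 * latv * (1 / 0.64 - 1))
  }
  fep <- cfg$fixed_effect_plan
  year <- sample.int(fep$n_years, na, replace = TRUE)
  year_eff <- rnorm(fep$n_years, 0, fep$year_sd)
  age <- runif(na, fep$age_range[1], fep$age_range[2])
  age_c <- age - mean(fep$age_range)
  shift <- year_eff[year] + fep$age_slope * age_c

  ind <- matrix(NA_real_, na, 6)
  lat <- cbind(latent_A, latent_A, latent_A, latent_B, latent_B, latent_B)
  for (k in 1:6)
    ind[, k] <- lam[k] * lat[, k] + rnorm(na, 0, sds[k]) + shift
  colnames(ind) <- c("QG", "FOR", "MARB", "JC", "TD", "CT")
  ind <- as.data.frame(ind)

  out <- list(pedigree = ped, genotypes = geno,
              tbv_A = setNames(tbv_A, ped$id),
              tbv_B = setNames(tbv_B, ped$id),
              latent_A = setNames(latent_A, ped$id),
              latent_B = setNames(latent_B, ped$id),
              indicators = cbind(data.frame(animal = ped$id), ind),
              fixed = data.frame(animal = ped$id, year = year,
                                 slaughter_age = age),
              qtl = qtl,
              params = c(plan, list(beta_causal = cfg$beta_causal,
                                    residual_sds = sds)),
              config = cfg)
  class(out) <- "sim_data"
  out
}

#' One-call synthetic dataset
#'
#' Convenience wrapper running [simulate_pedigree()], [drop_genotypes()]
#' and [simulate_latent_traits()] with a single configuration.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_data` object.
#' @export
simulate_dataset <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg)
  simulate_latent_traits(ped, geno, cfg)
}

#' @export
print.sim_data <- function(x, ...) {
  cat("sim_data:", nrow(x$pedigree), "animals,", ncol(x$genotypes$dosage),
      "SNPs,", if (is.null(x$qtl)) 0 else nrow(x$qtl), "planted QTL\n")
  cat("  realized h2_A =", signif(var(x$tbv_A) / var(x$latent_A), 3),
      " h2_B =", signif(var(x$tbv_B) / var(x$latent_B), 3), "\n")
  invisible(x)
}
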