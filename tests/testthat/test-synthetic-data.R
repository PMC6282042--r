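# synthetic_data module: pedigree simulation, gene dropping, latent traits

test_that("minimal trio and study-scale pedigrees have the configured shape", {
  trio <- simulate_pedigree(sim_config(n_founders = 2, n_generations = 2,
                                       n_sires = 1, n_animals_target = 3,
                                       seed = 1))
  expect_equal(nrow(trio), 3L)
  expect_equal(sum(is.na(trio$sire)), 2L)
  expect_equal(trio$sire[3], 1L)

  study <- simulate_pedigree(sim_config(n_founders = 300, n_generations = 4,
                                        n_sires = 143,
                                        n_animals_target = 1122, seed = 2))
  expect_equal(nrow(study), 1122L)
  expect_equal(length(unique(stats::na.omit(study$sire))), 143L)
  expect_equal(max(study$generation), 4L)
  # acyclic, parents precede offspring
  expect_true(all(is.na(study$sire) | study$sire < study$id))
})

test_that("impossible mating structures are configuration errors", {
  expect_error(simulate_pedigree(sim_config(n_founders = 4, n_generations = 2,
                                            n_sires = 10,
                                            n_animals_target = 12, seed = 1)),
               "sires|mating")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- tiny_sim_config(seed = 7)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$indicators, s2$indicators)
})

test_that("gene dropping is Mendelian-consistent and fixation propagates", {
  cfg <- tiny_sim_config(seed = 3)
  ped <- simulate_pedigree(cfg)
  geno <- drop_genotypes(ped, cfg, founder_freqs = c(0, 1, rep(0.3, 198)))
  expect_true(all(geno$dosage[, 1] == 0))   # fixed for reference allele
  expect_true(all(geno$dosage[, 2] == 2))   # (2,2) x (2,2) -> 2 everywhere
  expect_equal(count_mendelian_violations(geno, ped), 0L)
  # a corrupted dosage is detected
  bad <- geno
  off <- which(!is.na(ped$sire))[1]
  bad$dosage[off, 2] <- 0L
  expect_gt(count_mendelian_violations(bad, ped), 0L)
})

test_that("map is sorted and missingness honours the configured rate", {
  cfg <- tiny_sim_config(missing_rate = 0.1, seed = 5)
  sim <- simulate_dataset(cfg)
  map <- sim$genotypes$map
  expect_false(is.unsorted(match(map$chrom, unique(map$chrom))))
  expect_true(all(tapply(map$pos, map$chrom, function(x) !is.unsorted(x))))
  miss <- mean(is.na(sim$genotypes$dosage))
  expect_gt(miss, 0.07); expect_lt(miss, 0.13)
})

test_that("realized heritabilities and correlations match the stated world", {
  cfg <- tiny_sim_config(n_founders = 150, n_animals_target = 1200,
                         n_sires = 30, seed = 11)
  sim <- simulate_dataset(cfg)
  expect_lt(abs(var(sim$tbv_A) / var(sim$latent_A) - 0.46), 0.05)
  expect_lt(abs(var(sim$tbv_B) / var(sim$latent_B) - 0.36), 0.05)
  expect_lt(abs(cor(sim$tbv_A, sim$tbv_B) - 0.87), 0.05)
  expect_lt(abs(cov(sim$latent_A, sim$latent_B) / var(sim$latent_A) - 0.28),
            0.05)
})

test_that("degenerate worlds behave: h2 = 0 and beta = 0", {
  null_cfg <- tiny_sim_config(h2_A = 0, h2_B = 0, beta_causal = 0,
                              rg_target = NULL, seed = 13)
  sim <- simulate_dataset(null_cfg)
  expect_true(all(sim$tbv_A == 0))
  expect_true(all(sim$tbv_B == 0))

  nb <- tiny_sim_config(beta_causal = 0, rg_target = NULL,
                        n_founders = 250, n_animals_target = 2000,
                        n_sires = 40, seed = 17)
  sim2 <- simulate_dataset(nb)
  expect_lt(abs(cor(sim2$latent_A, sim2$latent_B)), 0.05)
})

test_that("infeasible variance targets are configuration errors", {
  expect_error(simulate_dataset(tiny_sim_config(h2_B = 0.03, seed = 1,
                                                rg_target = NULL)),
               "negative variance")
  expect_error(tiny_sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(tiny_sim_config(h2_A = 1.2), "heritabilities")
  # rg target without a causal path cannot be generated
  expect_error(simulate_dataset(tiny_sim_config(beta_causal = 0,
                                                rg_target = 0.8, seed = 1)),
               "beta_causal")
})

test_that("planted QTL that exceed the h2 budget error out", {
  qp <- data.frame(window = 1, class = "direct_A", size = 3)
  cfg <- tiny_sim_config(qtl_plan = qp, h2_A = 0.1, rg_target = NULL,
                         seed = 9)
  expect_error(simulate_dataset(cfg), "budget")
})

test_that("indicator covariance converges to the generating SEM Sigma", {
  cfg <- tiny_sim_config(n_founders = 400, n_animals_target = 5000,
                         n_sires = 60, n_snps = 300,
                         fixed_effect_plan = list(n_years = 1, year_sd = 0,
                                                  age_slope = 0,
                                                  age_range = c(500, 500)),
                         seed = 23)
  sim <- simulate_dataset(cfg)
  plan <- sim$params
  m <- carcass_meat_model()
  vals <- sem_parameter_values(
    m,
    "loading.carcass.FOR" = 0.9, "loading.carcass.MARB" = 1.1,
    "loading.meat.TD" = 1.3, "loading.meat.CT" = 1.1,
    "path.meat.carcass" = 0.28,
    "latvar.carcass" = 1,
    "latvar.meat" = plan$var_B - 0.28^2,   # disturbance of latent B
    "resid.QG" = plan$residual_sds[1]^2,
    "resid.FOR" = plan$residual_sds[2]^2,
    "resid.MARB" = plan$residual_sds[3]^2,
    "resid.JC" = plan$residual_sds[4]^2,
    "resid.TD" = plan$residual_sds[5]^2,
    "resid.CT" = plan$residual_sds[6]^2)
  Sigma <- implied_covariance(m, vals)
  S <- cov(sim$indicators[, -1])
  expect_lt(max(abs(S - Sigma[colnames(S), colnames(S)])), 0.05)
})

test_that("genotype and pedigree text formats round-trip", {
  cfg <- tiny_sim_config(seed = 31, missing_rate = 0.05)
  sim <- simulate_dataset(cfg)
  td <- withr::local_tempdir()
  gp <- file.path(td, "geno.tsv")
  write_genotypes(sim$genotypes, gp)
  back <- read_genotypes(gp)
  expect_equal(unname(back$dosage), unname(sim$genotypes$dosage))
  expect_equal(back$map, sim$genotypes$map)
  pp <- file.path(td, "ped.tsv")
  write_pedigree(sim$pedigree, pp)
  expect_equal(read_pedigree(pp)$sire, sim$pedigree$sire)
  vp <- file.path(td, "geno.vcf")
  write_genotypes_vcf(sim$genotypes, vp)
  vback <- read_genotypes_vcf(vp)
  expect_equal(unname(vback$dosage),
               unname(sim$genotypes$dosage))
})
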