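#' Configuration for the synthetic herd generator
#'
#' Bundles every knob of the synthetic-data module: pedigree shape, marker
#' panel, planted QTL architecture, latent-trait variance targets and the
#' measurement model for the six indicator traits.
#'
#' The defaults emulate the statistical structure the downstream analysis
#' assumes for a multibreed beef herd: a four-generation pedigree of about
#' 1,100 animals descending from a limited sire pool, a biallelic SNP panel
#' in founder linkage equilibrium, two latent traits (an upstream "carcass
#' quality" A and a downstream "meat quality" B) linked by a causal path
#' with coefficient `beta_causal = 0.28`, heritabilities 0.46 / 0.36 and a
#' genetic correlation of 0.87, and three indicators per latent.
#'
#' @param n_founders Number of founder animals (generation 1).
#' @param n_generations Total number of generation layers including the
#'   founders; `n_generations - 1` rounds of matings are simulated.
#' @param n_sires Total number of distinct sires with progeny.
#' @param n_animals_target Total pedigree size aimed for; offspring are
#'   split evenly over the non-founder generations.
#' @param n_snps,n_chromosomes Marker panel size and chromosome count.
#' @param maf_range Range (low, high), both in (0, 0.5), from which founder
#'   minor-allele frequencies are drawn uniformly.
#' @param qtl_plan `NULL` or a data.frame with columns `window` (1-based
#'   window index over the whole map), `class` (one of `"direct_A"`,
#'   `"direct_B"`, `"pleiotropic"`, `"indirect"`) and either `size` (allele
#'   substitution effect in latent-SD units; for `"pleiotropic"` an
#'   optional `size_b` gives the effect on B, defaulting to `size`) or
#'   `share` (target fraction of the latent's genetic variance, effect
#'   back-computed from the realized allele frequency; optional `share_b`
#'   for the B side of pleiotropic QTL).  Indirect-class QTL receive an
#'   effect on latent A only; any signal they show on latent B arises
#'   purely through `beta_causal`.
#' @param h2_A,h2_B Target narrow-sense heritabilities of the two latent
#'   traits.
#' @param beta_causal Structural path coefficient of latent B on latent A.
#' @param rg_target Target genetic correlation between the latent traits,
#'   or `NULL`. When numeric and `beta_causal > 0` the generator back-solves
#'   the independent genetic variance of B so that the causal path alone
#'   produces this correlation (no pleiotropic polygenic covariance is
#'   added); when `NULL`, latent B is given unit variance and whatever
#'   correlation the path induces.
#' @param loadings_A,loadings_B Factor loadings of the three indicators of
#'   each latent. The first loading should be 1 so that the latent scale
#'   equals the scale of its marker indicator (the identification used when
#'   refitting the model downstream).
#' @param indicator_residual_sds Six measurement-error SDs (A-block then
#'   B-block) or `NULL` for a default giving each indicator a standardized
#'   loading of 0.8.
#' @param fixed_effect_plan List with `n_years`, `year_sd` (SD of the
#'   year-of-birth level effects), `age_slope` (effect per day of slaughter
#'   age) and `age_range` (days). Fixed effects shift the observed
#'   indicators, not the latents.
#' @param polygenic_fraction Fraction of non-QTL SNPs carrying small
#'   polygenic effects.
#' @param missing_rate Proportion of genotype calls set to missing.
#' @param window_size SNPs per scan window (used to locate planted QTL).
#' @param seed Integer seed; all randomness in the generator derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 120,
                       n_generations = 4,
                       n_sires = 30,
                       n_animals_target = 500,
                       n_snps = 1000,
                       n_chromosomes = 10,
                       maf_range = c(0.10, 0.45),
                       qtl_plan = NULL,
                       h2_A = 0.46,
                       h2_B = 0.36,
                       beta_causal = 0.28,
                       rg_target = 0.87,
                       loadings_A = c(1, 0.9, 1.1),
                       loadings_B = c(1, 1.3, 1.1),
                       indicator_residual_sds = NULL,
                       fixed_effect_plan = list(n_years = 3, year_sd = 0.3,
                                                age_slope = 0.002,
                                                age_range = c(480, 620)),
                       polygenic_fraction = 1,
                       missing_rate = 0,
                       window_size = 20L,
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              n_sires = as.integer(n_sires),
              n_animals_target = as.integer(n_animals_target),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              maf_range = as.numeric(maf_range),
              qtl_plan = qtl_plan,
              h2_A = h2_A, h2_B = h2_B,
              beta_causal = beta_causal,
              rg_target = rg_target,
              loadings_A = loadings_A, loadings_B = loadings_B,
              indicator_residual_sds = indicator_residual_sds,
              fixed_effect_plan = fixed_effect_plan,
              polygenic_fraction = polygenic_fraction,
              missing_rate = missing_rate,
              window_size = as.integer(window_size),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_founders < 2L)
    stop("sim_config: need at least 2 founders", call. = FALSE)
  if (cfg$n_generations < 1L)
    stop("sim_config: n_generations must be >= 1", call. = FALSE)
  mr <- cfg$maf_range
  if (!(length(mr) == 2L && 0 < mr[1] && mr[1] < mr[2] && mr[2] < 0.5))
    stop("sim_config: maf_range must satisfy 0 < low < high < 0.5",
         call. = FALSE)
  for (h in c(cfg$h2_A, cfg$h2_B))
    if (h < 0 || h > 1)
      stop("sim_config: heritabilities must be in [0, 1]", call. = FALSE)
  if (length(cfg$loadings_A) != 3L || length(cfg$loadings_B) != 3L)
    stop("sim_config: three loadings per latent are required", call. = FALSE)
  if (!is.null(cfg$indicator_residual_sds) &&
      length(cfg$indicator_residual_sds) != 6L)
    stop("sim_config: indicator_residual_sds needs six values", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("sim_config: missing_rate must be in [0, 1)", call. = FALSE)
  if (!is.null(cfg$qtl_plan)) {
    qp <- cfg$qtl_plan
    if (!all(c("window", "class") %in% names(qp)) ||
        !any(c("size", "share") %in% names(qp)))
      stop("sim_config: qtl_plan needs columns window, class and size ",
           "or share", call. = FALSE)
    if (!all(qp$class %in% c("direct_A", "direct_B", "pleiotropic",
                             "indirect")))
      stop("sim_config: unknown qtl_plan class", call. = FALSE)
    n_windows <- cfg$n_snps %/% cfg$window_size +
      (cfg$n_snps %% cfg$window_size > 0L)
    if (any(qp$window < 1L | qp$window > n_windows))
      stop("sim_config: qtl_plan window index out of range", call. = FALSE)
    if (anyDuplicated(qp$window))
      stop("sim_config: qtl_plan windows must not overlap", call. = FALSE)
  }
  invisible(cfg)
}

# Solve the latent-trait variance bookkeeping implied by the configured
# targets.  Latent A has unit variance; the scale of latent B depends on
# whether a genetic-correlation target is set (see ?sim_config).
derive_variance_plan <- function(cfg) {
  s2g_A <- cfg$h2_A
  s2e_A <- 1 - cfg$h2_A
  beta <- cfg$beta_causal
  if (!is.null(cfg$rg_target) && cfg$rg_target > 0) {
    if (beta <= 0)
      stop("rg_target > 0 requires beta_causal > 0 (the generator creates ",
           "genetic correlation through the causal path only)", call. = FALSE)
    if (cfg$h2_B <= 0)
      stop("rg_target > 0 requires h2_B > 0", call. = FALSE)
    rg <- cfg$rg_target
    # total genetic SD of B fixed by the path: rg * sd_gB_tot = beta * sd_gA
    s2g_B_tot <- (beta * sqrt(s2g_A) / rg)^2
    var_B <- s2g_B_tot / cfg$h2_B
    s2g_Bd <- s2g_B_tot - beta^2 * s2g_A
    s2e_B <- var_B - beta^2 - s2g_Bd      # beta^2 * var(latent_A) = beta^2
  } else {
    var_B <- 1
    s2g_Bd <- cfg$h2_B - beta^2 * s2g_A
    s2e_B <- (1 - cfg$h2_B) - beta^2 * s2e_A
    s2g_B_tot <- cfg$h2_B
  }
  if (s2g_Bd < -1e-12 || s2e_B < -1e-12)
    stop("sim_config: h2/beta/rg settings imply a negative variance ",
         "component for latent B", call. = FALSE)
  list(s2g_A = s2g_A, s2e_A = s2e_A,
       s2g_Bd = max(s2g_Bd, 0), s2e_B = max(s2e_B, 0),
       s2g_B_tot = s2g_B_tot, var_A = 1, var_B = var_B)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_animals_target, "animals /", x$n_generations,
      "generations,", x$n_snps, "SNPs on", x$n_chromosomes, "chromosomes\n")
  cat("  h2_A =", x$h2_A, " h2_B =", x$h2_B, " beta =", x$beta_causal,
      " rg_target =", if (is.null(x$rg_target)) "NULL" else x$rg_target, "\n")
  cat("  planted QTL:", if (is.null(x$qtl_plan)) 0 else nrow(x$qtl_plan),
      " seed =", x$seed, "\n")
  invisible(x)
}
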