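# End-to-end orchestration: simulate/load -> adjust -> SEM -> kinship ->
# ssGBLUP scans -> window variance -> effect classification, with every
# stage's outputs written to a run directory as plain text.

#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (typically read from a JSON file)
#' with either a `simulation` block (arguments for [sim_config()]) or an
#' `input` block (`pedigree`, `genotypes`, `phenotypes` file paths), plus
#' optional blocks `qc` (`maf_min`, `callrate_min`), `classifier`
#' (thresholds for [classifier_config()]), `blend_alpha`, `sem_spec`
#' (model syntax; default the carcass/meat model), `window_size` and
#' `seed`.
#'
#' @param cfg Configuration list.
#' @return The normalized configuration (defaults filled in).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$simulation) && is.null(cfg$input))
    stop("run config needs a 'simulation' or an 'input' block", call. = FALSE)
  if (!is.null(cfg$input)) {
    need <- c("pedigree", "genotypes", "phenotypes")
    miss <- need[!need %in% names(cfg$input)]
    if (length(miss))
      stop("input block is missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    for (f in unlist(cfg$input[need]))
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$window_size <- if (is.null(cfg$window_size)) 20L else
    as.integer(cfg$window_size)
  cfg$blend_alpha <- if (is.null(cfg$blend_alpha)) 0.95 else cfg$blend_alpha
  if (is.null(cfg$qc)) cfg$qc <- list()
  cfg$qc$maf_min <- if (is.null(cfg$qc$maf_min)) 0.05 else cfg$qc$maf_min
  cfg$qc$callrate_min <- if (is.null(cfg$qc$callrate_min)) 0.9 else
    cfg$qc$callrate_min
  if (is.null(cfg$sem_spec))
    cfg$sem_spec <- "carcass =~ QG + FOR + MARB
                     meat =~ JC + TD + CT
                     meat ~ carcass"
  cls <- cfg$classifier
  cfg$classifier_config <- classifier_config(
    assoc_threshold = if (is.null(cls$assoc_threshold)) 0.05 else
      cls$assoc_threshold,
    strong_threshold = if (is.null(cls$strong_threshold)) 0.15 else
      cls$strong_threshold)
  cfg
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full latent-trait genome-scan pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' input), fixed-effect adjustment of the six indicators, SEM fit and
#' factor scoring, SNP QC and single-step H-inverse construction, EM-REML
#' plus ssGBLUP for three scans (upstream latent A, downstream latent B,
#' and B with the A score as covariate), SNP-effect back-solving, 20-SNP
#' window variance partitioning, and effect classification.  Every stage
#' writes its outputs to `out_dir` as delimited text, and a JSON summary
#' (SEM fit indices, structural coefficient, heritabilities, genetic
#' correlation, class counts, seed and configuration digest) is returned
#' and saved.
#'
#' @param cfg Run configuration list (see [validate_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @return The summary list, invisibly; outputs on disk.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("semscan_run_")) {
  cfg <- validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))
  stage <- "config"
  result <- tryCatch({
    pipeline_log(logcon, stage, "validated")

    stage <- "data"
    if (!is.null(cfg$simulation)) {
      sim_args <- cfg$simulation
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      scfg <- do.call(sim_config, sim_args)
      sim <- simulate_dataset(scfg)
      ped <- sim$pedigree
      geno <- sim$genotypes
      phen <- cbind(sim$indicators, sim$fixed[, c("year", "slaughter_age")])
      manifest <- list(seed = scfg$seed, true_h2_A = scfg$h2_A,
                       true_h2_B = scfg$h2_B,
                       true_beta = scfg$beta_causal,
                       rg_target = scfg$rg_target)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      sim <- NULL
      ped <- read_pedigree(cfg$input$pedigree)
      geno <- read_genotypes(cfg$input$genotypes)
      phen <- as.data.frame(data.table::fread(cfg$input$phenotypes))
    }
    write_pedigree(ped, file.path(out_dir, "pedigree.tsv"))
    data.table::fwrite(phen, file.path(out_dir, "phenotypes.tsv"),
                       sep = "\t")
    pipeline_log(logcon, stage, sprintf("%d animals, %d SNPs, %d records",
                                        nrow(ped), ncol(geno$dosage),
                                        nrow(phen)))

    stage <- "adjust"
    traits <- c("QG", "FOR", "MARB", "JC", "TD", "CT")
    specs <- default_adjustment_specs(traits)
    adj <- adjust_phenotypes(phen, specs)
    rownames(adj) <- phen$animal
    data.table::fwrite(cbind(animal = phen$animal, adj),
                       file.path(out_dir, "adjusted_phenotypes.tsv"),
                       sep = "\t")
    pipeline_log(logcon, stage, "OLS residuals computed")

    stage <- "sem"
    model <- sem_model(cfg$sem_spec)
    cc <- stats::complete.cases(adj)
    S <- cov(adj[cc, , drop = FALSE])
    fit <- fit_ml(S, sum(cc), model, data = adj[cc, , drop = FALSE])
    if (!fit$converged) stop("SEM did not converge")
    idx <- fit_indices(fit)
    scores <- factor_scores(fit, adj)
    lat_names <- names(model$latents)
    data.table::fwrite(fit$estimates, file.path(out_dir, "sem_estimates.tsv"),
                       sep = "\t")
    data.table::fwrite(cbind(data.frame(animal = phen$animal), scores),
                       file.path(out_dir, "factor_scores.tsv"), sep = "\t")
    path_name <- fit$estimates$name[fit$estimates$type == "path"][1]
    pipeline_log(logcon, stage,
                 sprintf("chi2 %.3f (df %d), %s = %.3f", fit$chi2, fit$df,
                         path_name, sem_estimate(fit, path_name)))

    stage <- "kinship"
    qc <- snp_qc(geno, cfg$qc$maf_min, cfg$qc$callrate_min)
    hset <- make_single_step_Hinv(ped, qc$genotypes, cfg$blend_alpha)
    pipeline_log(logcon, stage, sprintf("%d SNPs retained, H over %d animals",
                                        qc$report$n_retained,
                                        nrow(hset$Hinv)))

    stage <- "gblup"
    sA <- setNames(scores[, 1], phen$animal)
    sB <- setNames(scores[, 2], phen$animal)
    keep <- !is.na(sA) & !is.na(sB)
    sA <- sA[keep]; sB <- sB[keep]
    n_rec <- sum(keep)
    X0 <- matrix(1, n_rec, 1, dimnames = list(NULL, "(Intercept)"))
    XB <- cbind(X0, score_A = sA)
    vcA <- estimate_variance_components(sA, X0, hset$Hinv, se = FALSE,
                                        max_iter = 2000L)
    vcB <- estimate_variance_components(sB, X0, hset$Hinv, se = FALSE,
                                        max_iter = 2000L)
    vcBA <- estimate_variance_components(sB, XB, hset$Hinv, se = FALSE,
                                         max_iter = 2000L)
    rg <- estimate_genetic_correlation(sA, sB, X0, hset$Hinv, se = FALSE)
    solA <- solve_mme(sA, X0, hset$Hinv, vcA$lambda, "carcass")
    solB <- solve_mme(sB, X0, hset$Hinv, vcB$lambda, "meat")
    solBA <- solve_mme(sB, XB, hset$Hinv, vcBA$lambda, "meat_given_carcass")
    pipeline_log(logcon, stage,
                 sprintf("h2_A %.3f, h2_B %.3f, rg %.3f", vcA$h2, vcB$h2,
                         rg$rg))

    stage <- "scan"
    Zc <- center_dosages(qc$genotypes)
    G_for_solve <- hset$G
    u <- lapply(list(solA, solB, solBA), function(s) {
      tryCatch(backsolve_snp_effects(s, Zc, G_for_solve),
               error = function(e) backsolve_snp_effects(s, Zc,
                                                         hset$G_blended))
    })
    windows <- make_windows(qc$genotypes$map, cfg$window_size)
    scans <- lapply(u, window_variance, Zc = Zc, windows = windows)
    pipeline_log(logcon, stage, sprintf("%d windows", nrow(windows)))

    stage <- "classify"
    calls <- classify_genome(scans[[1]], scans[[2]], scans[[3]],
                             cfg$classifier_config)
    tab <- calls
    tab$effect_class <- as.character(tab$effect_class)
    data.table::fwrite(tab, file.path(out_dir, "window_calls.tsv"),
                       sep = "\t")
    assoc <- calls[calls$effect_class != "not_associated", , drop = FALSE]
    write_bed(assoc, file.path(out_dir, "associated_regions.bed"))
    counts <- attr(calls, "counts")
    pipeline_log(logcon, stage, paste(names(counts), counts, sep = "=",
                                      collapse = ", "))

    cfg_out <- cfg[setdiff(names(cfg), "classifier_config")]
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    summary <- list(
      semscan_version =
        as.character(utils::packageVersion("semscan")),
      seed = cfg$seed,
      n_animals = nrow(ped), n_records = n_rec,
      n_snps_retained = qc$report$n_retained,
      sem = list(chi2 = fit$chi2, df = fit$df, pvalue = fit$pvalue,
                 structural_coefficient = sem_estimate(fit, path_name),
                 gfi = idx$gfi, agfi = idx$agfi, rmr = idx$rmr,
                 cfi = idx$cfi, rmsea = idx$rmsea),
      heritability = list(A = vcA$h2, B = vcB$h2),
      genetic_correlation = rg$rg,
      class_counts = as.list(counts),
      n_windows = nrow(windows))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    summary$out_dir <- out_dir
    summary$calls <- calls
    summary$scans <- scans
    summary$sim <- sim
    summary$fit <- fit
    summary$variance_components <- list(A = vcA, B = vcB, B_given_A = vcBA)
    summary
  }, error = function(e) {
    rec <- list(stage = stage, error = conditionMessage(e))
    jsonlite::write_json(rec, file.path(out_dir, "error.json"),
                         auto_unbox = TRUE)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
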