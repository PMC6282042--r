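#' Define a fixed-effect adjustment for one trait
#'
#' @param trait Trait column name.
#' @param covariates Character vector of covariate column names.
#' @param categorical Logical vector (recycled) flagging which covariates
#'   are factors; the convention used throughout the package is year of
#'   birth categorical and slaughter age continuous.
#' @return An object of class `adjustment_spec`.
#' @export
adjustment_spec <- function(trait, covariates,
                            categorical = rep(TRUE, length(covariates))) {
  stopifnot(is.character(trait), length(trait) == 1L)
  categorical <- rep_len(categorical, length(covariates))
  structure(list(trait = trait, covariates = covariates,
                 categorical = categorical),
            class = "adjustment_spec")
}

#' Default adjustment specs for a phenotype table
#'
#' Growth traits are corrected for year of birth only; every other trait is
#' adjusted for year of birth (categorical) and slaughter age (continuous).
#'
#' @param traits Character vector of trait columns.
#' @param growth_traits Subset of `traits` treated as growth traits.
#' @param year_col,age_col Covariate column names.
#' @return A list of [adjustment_spec()] objects, one per trait.
#' @export
default_adjustment_specs <- function(traits, growth_traits = character(),
                                     year_col = "year",
                                     age_col = "slaughter_age") {
  lapply(traits, function(tr) {
    if (tr %in% growth_traits)
      adjustment_spec(tr, year_col, TRUE)
    else
      adjustment_spec(tr, c(year_col, age_col), c(TRUE, FALSE))
  })
}

#' Pre-correct observed traits for fixed effects
#'
#' Fits an ordinary least-squares model per trait on the covariates of its
#' [adjustment_spec()] and returns the residuals, which carry zero mean by
#' construction.  Rows with a missing trait value are dropped from that
#' trait's fit (complete-case per trait) and returned as `NA`; missing
#' covariate values on used rows are an error.  Rank-deficient designs
#' (confounded factor levels) are handled by dropping the aliased columns
#' with a warning.
#'
#' @param phenotypes Data.frame holding trait and covariate columns.
#' @param specs A single [adjustment_spec()] or a list of them.
#' @return Data.frame of residuals, one column per trait, same row order as
#'   the input.
#' @export
adjust_phenotypes <- function(phenotypes, specs) {
  if (inherits(specs, "adjustment_spec")) specs <- list(specs)
  out <- lapply(specs, function(sp) {
    if (!sp$trait %in% names(phenotypes))
      stop("trait column not found: ", sp$trait, call. = FALSE)
    missing_cov <- setdiff(sp$covariates, names(phenotypes))
    if (length(missing_cov))
      stop("covariate column(s) not found: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    y <- phenotypes[[sp$trait]]
    use <- !is.na(y)
    if (!any(use))
      stop("trait ", sp$trait, " has no non-missing values", call. = FALSE)
    X <- matrix(1, sum(use), 1, dimnames = list(NULL, "(Intercept)"))
    for (j in seq_along(sp$covariates)) {
      v <- phenotypes[[sp$covariates[j]]][use]
      if (anyNA(v))
        stop("missing covariate values in ", sp$covariates[j],
             " for rows with observed ", sp$trait, call. = FALSE)
      if (sp$categorical[j]) {
        f <- factor(v)
        if (nlevels(f) > 1L) {
          mm <- model.matrix(~f)[, -1, drop = FALSE]
          colnames(mm) <- paste0(sp$covariates[j], levels(f)[-1])
          X <- cbind(X, mm)
        }
      } else {
        X <- cbind(X, as.numeric(v))
        colnames(X)[ncol(X)] <- sp$covariates[j]
      }
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      warning("adjust_phenotypes: dropping aliased column(s) for ",
              sp$trait, ": ", paste(dropped, collapse = ", "),
              call. = FALSE)
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(X)
    }
    r <- rep(NA_real_, length(y))
    r[use] <- qr.resid(qx, y[use])
    r
  })
  names(out) <- vapply(specs, `[[`, "", "trait")
  as.data.frame(out, optional = TRUE)
}
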