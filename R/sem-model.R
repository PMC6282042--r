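#' Specify a latent-variable structural equation model
#'
#' Parses a compact model syntax into a parameter table.  Two operator
#' types are understood, one declaration per line (or separated by `;`):
#'
#' * `latent =~ ind1 + ind2 + ind3` — measurement part (factor loadings);
#' * `latent2 ~ latent1` — structural part (causal path between latents).
#'
#' The model is the classic LISREL system: indicators of exogenous latents
#' follow `x = Lambda_x xi + delta`, indicators of endogenous latents
#' follow `y = Lambda_y eta + epsilon`, and the latents obey
#' `eta = B eta + Gamma xi + zeta`.  Latent disturbances are uncorrelated
#' and indicator residuals are diagonal; the structural part must be
#' acyclic.
#'
#' Scale setting (`identification`):
#' * `"marker"` (default) — first loading of every latent fixed to 1,
#'   latent (disturbance) variances free.  For the 6-indicator, 2-latent,
#'   1-path model this counts q = 13 free parameters, hence df = 8.
#' * `"marker_unit"` — marker loadings *and* unit latent disturbance
#'   variances.  This is the doubly constrained parameterization under
#'   which the final published carcass/meat model counts q = 11 free
#'   parameters and df = 10; it restricts the model (the marker
#'   indicator's common variance is forced to 1) and is provided to
#'   reproduce that parameter count.
#' * `"unit_variance"` — all loadings free, latent disturbance variances
#'   fixed to 1.
#'
#' @param spec Model syntax string.
#' @param identification One of `"marker"`, `"marker_unit"`,
#'   `"unit_variance"`.
#' @return An object of class `sem_model`: list with `latents` (named list
#'   of indicator vectors), `observed`, `paths`, `partable` (parameter
#'   table with columns `type`, `lhs`, `rhs`, `free`, `start`, `fixed_value`)
#'   and counts `p`, `q`.
#' @export
sem_model <- function(spec, identification = c("marker", "marker_unit",
                                               "unit_variance")) {
  identification <- match.arg(identification)
  lines <- unlist(strsplit(spec, "[;\n]"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  latents <- list()
  paths <- data.frame(to = character(), from = character(),
                      stringsAsFactors = FALSE)
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      part <- strsplit(ln, "=~", fixed = TRUE)[[1]]
      lat <- trimws(part[1])
      inds <- trimws(strsplit(part[2], "+", fixed = TRUE)[[1]])
      latents[[lat]] <- c(latents[[lat]], inds)
    } else if (grepl("~", ln, fixed = TRUE)) {
      part <- strsplit(ln, "~", fixed = TRUE)[[1]]
      to <- trimws(part[1])
      froms <- trimws(strsplit(part[2], "+", fixed = TRUE)[[1]])
      paths <- rbind(paths, data.frame(to = to, from = froms,
                                       stringsAsFactors = FALSE))
    } else stop("cannot parse model line: ", ln, call. = FALSE)
  }
  if (!length(latents)) stop("model defines no latent variables", call. = FALSE)
  lat_names <- names(latents)
  if (nrow(paths) &&
      !all(c(paths$to, paths$from) %in% lat_names))
    stop("structural paths must connect declared latent variables",
         call. = FALSE)
  # acyclicity of the structural part
  if (nrow(paths)) {
    order_ok <- FALSE
    remaining <- lat_names
    repeat {
      src <- remaining[vapply(remaining, function(l)
        !any(paths$to == l & paths$from %in% remaining), TRUE)]
      if (!length(src)) break
      remaining <- setdiff(remaining, src)
      if (!length(remaining)) { order_ok <- TRUE; break }
    }
    if (!order_ok) stop("structural model is cyclic", call. = FALSE)
  }
  observed <- unlist(latents, use.names = FALSE)
  if (anyDuplicated(observed))
    stop("each indicator may load on one latent only", call. = FALSE)
  endo <- unique(paths$to)
  fix_first <- identification %in% c("marker", "marker_unit")
  fix_latvar <- identification %in% c("marker_unit", "unit_variance")

  pt <- list()
  for (lat in lat_names) {
    inds <- latents[[lat]]
    for (k in seq_along(inds)) {
      fixed <- fix_first && k == 1L
      pt[[length(pt) + 1L]] <- data.frame(
        type = "loading", lhs = lat, rhs = inds[k], free = !fixed,
        start = 1, fixed_value = if (fixed) 1 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(paths))
    for (i in seq_len(nrow(paths)))
      pt[[length(pt) + 1L]] <- data.frame(
        type = "path", lhs = paths$to[i], rhs = paths$from[i], free = TRUE,
        start = 0, fixed_value = NA_real_, stringsAsFactors = FALSE)
  for (lat in lat_names)
    pt[[length(pt) + 1L]] <- data.frame(
      type = "latvar", lhs = lat, rhs = lat, free = !fix_latvar,
      start = 0.5, fixed_value = if (fix_latvar) 1 else NA_real_,
      stringsAsFactors = FALSE)
  for (v in observed)
    pt[[length(pt) + 1L]] <- data.frame(
      type = "resid", lhs = v, rhs = v, free = TRUE,
      start = 0.5, fixed_value = NA_real_, stringsAsFactors = FALSE)
  partable <- do.call(rbind, pt)
  partable$id <- seq_len(nrow(partable))

  model <- list(latents = latents, observed = observed, paths = paths,
                endogenous = endo,
                exogenous = setdiff(lat_names, endo),
                identification = identification,
                partable = partable,
                p = length(observed), q = sum(partable$free))
  class(model) <- "sem_model"
  model
}

#' Degrees of freedom of a structural equation model
#'
#' Evaluates `df = p (p + 1) / 2 - q`, the number of unique covariance
#' moments minus the number of free parameters, and attaches the
#' identification label: overidentified (`df >= 1`), just-identified
#' (`df == 0`) or underidentified (`df < 0`).
#'
#' @param model A [sem_model()].
#' @return Integer df with attribute `"identification"`.
#' @export
model_degrees_of_freedom <- function(model) {
  stopifnot(inherits(model, "sem_model"))
  df <- model$p * (model$p + 1) / 2 - model$q
  attr(df, "identification") <-
    if (df >= 1) "overidentified" else if (df == 0)
      "just-identified" else "underidentified"
  df
}

# assemble parameter matrices from a full parameter vector (all rows of the
# partable, fixed rows at their fixed values)
sem_matrices <- function(model, values) {
  pt <- model$partable
  lat <- names(model$latents)
  nl <- length(lat)
  p <- model$p
  L <- matrix(0, p, nl, dimnames = list(model$observed, lat))
  Bm <- matrix(0, nl, nl, dimnames = list(lat, lat))
  Psi <- matrix(0, nl, nl, dimnames = list(lat, lat))
  Theta <- matrix(0, p, p, dimnames = list(model$observed, model$observed))
  for (i in seq_len(nrow(pt))) {
    v <- values[i]
    switch(pt$type[i],
           loading = { L[pt$rhs[i], pt$lhs[i]] <- v },
           path = { Bm[pt$lhs[i], pt$rhs[i]] <- v },
           latvar = { Psi[pt$lhs[i], pt$lhs[i]] <- v },
           resid = { Theta[pt$lhs[i], pt$lhs[i]] <- v })
  }
  list(L = L, B = Bm, Psi = Psi, Theta = Theta)
}

#' Model-implied covariance matrix
#'
#' Assembles `Sigma(theta) = Lambda (I - B)^-1 Psi (I - B)^-T Lambda' +
#' Theta` over all latents (exogenous latent variances and endogenous
#' disturbance variances both live on the diagonal of `Psi`).
#'
#' @param model A [sem_model()].
#' @param values Numeric vector over the full parameter table
#'   (`model$partable`), fixed entries included, in table order.  See
#'   [sem_parameter_values()] to build one.
#' @return Symmetric p x p matrix.
#' @export
implied_covariance <- function(model, values) {
  m <- sem_matrices(model, values)
  IB <- diag(nrow(m$B)) - m$B
  if (abs(det(IB)) < 1e-12)
    stop("(I - B) is singular; structural part not invertible", call. = FALSE)
  IBi <- solve(IB)
  lat_cov <- IBi %*% m$Psi %*% t(IBi)
  S <- m$L %*% lat_cov %*% t(m$L) + m$Theta
  (S + t(S)) / 2
}

#' Build a full parameter-value vector for a model
#'
#' Convenience for tests and oracles: returns the vector expected by
#' [implied_covariance()], with fixed parameters at their fixed values and
#' free parameters taken from named arguments of the form
#' `loading.latent.indicator`, `path.to.from`, `latvar.latent`,
#' `resid.indicator`.
#'
#' @param model A [sem_model()].
#' @param ... Named parameter values.
#' @return Numeric vector over `model$partable` rows.
#' @export
sem_parameter_values <- function(model, ...) {
  pt <- model$partable
  vals <- ifelse(pt$free, NA_real_, pt$fixed_value)
  supplied <- list(...)
  key <- sem_par_names(model)
  for (nm in names(supplied)) {
    i <- match(nm, key)
    if (is.na(i)) stop("unknown parameter: ", nm, call. = FALSE)
    vals[i] <- supplied[[nm]]
  }
  if (anyNA(vals))
    stop("missing values for free parameters: ",
         paste(key[is.na(vals)], collapse = ", "), call. = FALSE)
  vals
}

sem_par_names <- function(model) {
  pt <- model$partable
  ifelse(pt$type == "loading", paste("loading", pt$lhs, pt$rhs, sep = "."),
  ifelse(pt$type == "path", paste("path", pt$lhs, pt$rhs, sep = "."),
  ifelse(pt$type == "latvar", paste("latvar", pt$lhs, sep = "."),
         paste("resid", pt$lhs, sep = "."))))
}

#' The final published carcass/meat quality model
#'
#' Two latents: carcass quality measured by QG, FOR and MARB; meat quality
#' measured by JC, TD and CT; one causal path from carcass to meat quality.
#'
#' @param identification Passed to [sem_model()]; `"marker_unit"`
#'   reproduces the published free-parameter count (q = 11, df = 10).
#' @return A [sem_model()].
#' @export
carcass_meat_model <- function(identification = "marker") {
  sem_model("carcass =~ QG + FOR + MARB
             meat =~ JC + TD + CT
             meat ~ carcass", identification = identification)
}

#' @export
print.sem_model <- function(x, ...) {
  cat("sem_model:", length(x$latents), "latent(s),", x$p, "indicators,",
      nrow(x$paths), "path(s);", x$q, "free parameters, df =",
      as.numeric(model_degrees_of_freedom(x)), "\n")
  invisible(x)
}
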