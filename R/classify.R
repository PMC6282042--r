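# Classification of genomic regions into direct, pleiotropic and indirect
# effects by comparing three window scans: the upstream latent trait (A),
# the downstream latent trait (B), and B with the upstream latent score as
# a fixed covariate (B | A).  A region whose B signal survives conditioning
# acts directly on both traits; a region whose B signal disappears affects
# B only through the causal path.

#' Thresholds for the effect classifier
#'
#' @param assoc_threshold Percent of additive variance above which a window
#'   counts as associated with a scan (default 0.05, the inventory
#'   threshold used for the genome-wide region lists).
#' @param strong_threshold Percent above which an association is flagged as
#'   strong (default 0.15, the reporting threshold for headline regions).
#' @param indirect_band Percent pair bracketing the variance expected of
#'   indirect regions in the downstream scan (default 0.1-0.15); reporting
#'   metadata, not part of the classification rule.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(assoc_threshold = 0.05,
                              strong_threshold = 0.15,
                              indirect_band = c(0.1, 0.15)) {
  if (!(assoc_threshold > 0 && assoc_threshold <= strong_threshold))
    stop("need 0 < assoc_threshold <= strong_threshold", call. = FALSE)
  structure(list(assoc_threshold = assoc_threshold,
                 strong_threshold = strong_threshold,
                 indirect_band = indirect_band),
            class = "classifier_config")
}

effect_classes <- c("direct_A_only", "direct_both", "direct_B_only",
                    "indirect_via_A", "not_associated")

#' Classify one window (vectorized over windows)
#'
#' With `t = assoc_threshold`, the rules are:
#' * A >= t, B < t — `direct_A_only`;
#' * A < t, B >= t — `direct_B_only`;
#' * A >= t, B >= t, B|A >= t — `direct_both` (pleiotropic: the downstream
#'   signal survives conditioning on the upstream latent);
#' * A >= t, B >= t, B|A < t — `indirect_via_A` (the downstream signal
#'   disappears once the upstream latent is a covariate);
#' * otherwise `not_associated`.
#'
#' @param pct_A,pct_B,pct_B_given_A Percent additive variance of the window
#'   in the three scans (non-negative; vectors allowed).
#' @param cfg A [classifier_config()].
#' @return Factor of effect classes.
#' @export
classify_window <- function(pct_A, pct_B, pct_B_given_A,
                            cfg = classifier_config()) {
  if (any(c(pct_A, pct_B, pct_B_given_A) < 0))
    stop("window variance percentages must be non-negative", call. = FALSE)
  t <- cfg$assoc_threshold
  cls <- ifelse(pct_A >= t & pct_B < t, "direct_A_only",
         ifelse(pct_A < t & pct_B >= t, "direct_B_only",
         ifelse(pct_A >= t & pct_B >= t & pct_B_given_A >= t, "direct_both",
         ifelse(pct_A >= t & pct_B >= t, "indirect_via_A",
                "not_associated"))))
  factor(cls, levels = effect_classes)
}

#' Classify every window of the genome from the three scans
#'
#' @param scan_A,scan_B,scan_B_given_A `window_table`s (with
#'   `pct_variance`) from [window_variance()] for the three models; their
#'   window definitions must be identical.
#' @param cfg A [classifier_config()].
#' @return Object of class `region_calls`: data.frame of per-window calls
#'   (`window_id`, `chrom`, `start_bp`, `end_bp`, `pct_A`, `pct_B`,
#'   `pct_B_given_A`, `effect_class`, `strong`) plus attribute `counts`
#'   (named vector over the four associated classes and `not_associated`).
#' @export
classify_genome <- function(scan_A, scan_B, scan_B_given_A,
                            cfg = classifier_config()) {
  if (!identical(scan_A$window_id, scan_B$window_id) ||
      !identical(scan_A$window_id, scan_B_given_A$window_id))
    stop("the three scans must share identical window definitions",
         call. = FALSE)
  cls <- classify_window(scan_A$pct_variance, scan_B$pct_variance,
                         scan_B_given_A$pct_variance, cfg)
  strong <- pmax(scan_A$pct_variance, scan_B$pct_variance) >=
    cfg$strong_threshold
  calls <- data.frame(window_id = scan_A$window_id, chrom = scan_A$chrom,
                      start_bp = scan_A$start_bp, end_bp = scan_A$end_bp,
                      pct_A = scan_A$pct_variance,
                      pct_B = scan_B$pct_variance,
                      pct_B_given_A = scan_B_given_A$pct_variance,
                      effect_class = cls, strong = strong,
                      stringsAsFactors = FALSE)
  counts <- table(cls)
  attr(calls, "counts") <- setNames(as.integer(counts), names(counts))
  attr(calls, "n_associated") <-
    sum(cls != "not_associated")
  class(calls) <- c("region_calls", "data.frame")
  calls
}

#' @export
print.region_calls <- function(x, ...) {
  cts <- attr(x, "counts")
  cat("region_calls:", nrow(x), "windows,", attr(x, "n_associated"),
      "associated\n")
  for (nm in names(cts)) cat(sprintf("  %-15s %d\n", nm, cts[[nm]]))
  invisible(x)
}
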