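# Partitioning additive genetic variance into windows of adjacent SNPs.

#' Define non-overlapping windows of adjacent SNPs
#'
#' Cuts each chromosome into consecutive blocks of `size` SNPs in map
#' order.  Windows never span chromosomes; a trailing window with fewer
#' than `size` SNPs is retained and flagged.
#'
#' @param map Data.frame with columns `chrom` and `pos`, sorted by
#'   chromosome then position.
#' @param size SNPs per window (default 20).
#' @return Data.frame of class `window_table` with columns `window_id`
#'   (`"<chrom>w<ordinal>"`), `chrom`, `ordinal`, `start_bp`, `end_bp`,
#'   `n_snps`, `partial`, and a list column `snp_indices` (row indices into
#'   `map`).
#' @export
make_windows <- function(map, size = 20L) {
  stopifnot(all(c("chrom", "pos") %in% names(map)))
  if (is.unsorted(match(map$chrom, unique(map$chrom))) ||
      any(unlist(tapply(map$pos, factor(map$chrom, unique(map$chrom)),
                        is.unsorted))))
    stop("marker map must be sorted by chromosome then position",
         call. = FALSE)
  rows <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    nw <- ceiling(length(idx) / size)
    for (w in seq_len(nw)) {
      sel <- idx[((w - 1L) * size + 1L):min(w * size, length(idx))]
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = paste0(ch, "w", w), chrom = ch, ordinal = w,
        start_bp = min(map$pos[sel]), end_bp = max(map$pos[sel]),
        n_snps = length(sel), partial = length(sel) < size,
        stringsAsFactors = FALSE)
      rows[[length(rows)]]$snp_indices <- I(list(sel))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("window_table", "data.frame")
  out
}

#' Percentage of additive genetic variance per SNP window
#'
#' For each window `w` computes the direct genomic values
#' `g_w = Zc[, w] u[w]` of the genotyped animals and expresses their
#' variance as a percentage of the total additive variance.  The default
#' denominator is `var(Zc u)` — the variance of the whole-genome direct
#' genomic values, under which window percentages of unlinked SNPs sum to
#' ~100 — but a REML `sigma2_a` can be supplied instead.
#'
#' @param u Named per-SNP effect vector (from [backsolve_snp_effects()]).
#' @param Zc Centered dosage matrix.
#' @param windows A `window_table` from [make_windows()].
#' @param sigma2_a_total Denominator variance; default `var(Zc %*% u)`.
#' @return The `windows` table with an added `pct_variance` column.
#' @export
window_variance <- function(u, Zc, windows, sigma2_a_total = NULL) {
  stopifnot(inherits(windows, "window_table"))
  g_all <- drop(Zc %*% u)
  if (is.null(sigma2_a_total)) sigma2_a_total <- var(g_all)
  if (!is.finite(sigma2_a_total) || sigma2_a_total <= 0)
    stop("total additive variance is zero; nothing to partition",
         call. = FALSE)
  pct <- vapply(windows$snp_indices, function(sel) {
    gw <- drop(Zc[, sel, drop = FALSE] %*% u[sel])
    100 * var(gw) / sigma2_a_total
  }, 0)
  out <- windows
  out$pct_variance <- pct
  out
}
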