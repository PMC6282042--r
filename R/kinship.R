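# Relationship matrices (pedigree A, genomic G, combined H) and SNP QC.

#' SNP quality control
#'
#' Applies the three standard filters in a fixed order — monomorphic,
#' minor-allele frequency, call rate — assigning each removed SNP to the
#' first rule it fails, so the report counts always add up.  Missing
#' dosages of retained SNPs are imputed to twice the observed allele
#' frequency (keeping the centered genotype columns mean-zero).
#'
#' @param geno A `genotype_matrix` (dosages 0/1/2, `NA` = no call).
#' @param maf_min Minimum minor-allele frequency (default 0.05).
#' @param callrate_min Minimum proportion of non-missing calls (default 0.9).
#' @return List with `genotypes` (filtered, imputed, numeric dosages) and
#'   `report` (class `qc_report`).
#' @export
snp_qc <- function(geno, maf_min = 0.05, callrate_min = 0.9) {
  d <- geno$dosage
  m <- ncol(d)
  callrate <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mono <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0L || all(x == x[1])
  })
  fail_maf <- !mono & maf < maf_min
  fail_cr <- !mono & !fail_maf & callrate < callrate_min
  keep <- !(mono | fail_maf | fail_cr)
  if (!any(keep)) stop("snp_qc removed every SNP", call. = FALSE)
  d2 <- d[, keep, drop = FALSE]
  storage.mode(d2) <- "double"
  if (anyNA(d2)) {
    pk <- p[keep]
    idx <- which(is.na(d2), arr.ind = TRUE)
    d2[idx] <- 2 * pk[idx[, 2]]
  }
  out <- list(dosage = d2, map = geno$map[keep, , drop = FALSE])
  class(out) <- "genotype_matrix"
  report <- structure(list(n_input_snps = m, n_retained = sum(keep),
                           removed_monomorphic = sum(mono),
                           removed_maf = sum(fail_maf),
                           removed_callrate = sum(fail_cr),
                           maf_min = maf_min, callrate_min = callrate_min),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$n_input_snps, "in,", x$n_retained, "retained (",
      x$removed_monomorphic, "monomorphic,", x$removed_maf,
      paste0("MAF<", x$maf_min, ","), x$removed_callrate,
      paste0("call rate<", x$callrate_min), ")\n")
  invisible(x)
}

# topological order of a pedigree: parents before offspring
pedigree_order <- function(ped) {
  n <- nrow(ped)
  id <- as.character(ped$id)
  sire <- match(as.character(ped$sire), id)
  dam <- match(as.character(ped$dam), id)
  depth <- rep(NA_integer_, n)
  get_depth <- function(i, seen = integer(0)) {
    if (!is.na(depth[i])) return(depth[i])
    if (i %in% seen)
      stop("pedigree cycle: animal ", id[i], " is its own ancestor",
           call. = FALSE)
    s <- sire[i]; d <- dam[i]
    dep <- 0L
    if (!is.na(s)) dep <- max(dep, get_depth(s, c(seen, i)) + 1L)
    if (!is.na(d)) dep <- max(dep, get_depth(d, c(seen, i)) + 1L)
    depth[i] <<- dep
    dep
  }
  for (i in seq_len(n)) get_depth(i)
  order(depth, seq_len(n))
}

#' Pedigree-based (numerator) relationship matrix
#'
#' Tabular (recursive) method with inbreeding: processing animals in
#' parents-first order, `a_ij = 0.5 (a_j,sire(i) + a_j,dam(i))` for j
#' preceding i, and `a_ii = 1 + 0.5 a_sire(i),dam(i)`.  Unknown parents
#' contribute zero.
#'
#' @param ped A `pedigree_table` (any row order; the function sorts
#'   ancestors first and returns the matrix in the input id order).
#' @return Symmetric matrix with dimnames = animal ids and attribute
#'   `kind = "A"`.  Diagonal is `1 + F` with `F` the inbreeding
#'   coefficient.
#' @export
pedigree_A <- function(ped) {
  n <- nrow(ped)
  ord <- pedigree_order(ped)
  id <- as.character(ped$id)[ord]
  sire <- match(as.character(ped$sire)[ord], id)
  dam <- match(as.character(ped$dam)[ord], id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (is.na(s)) 0 else A[s, j]
      row_d <- if (is.na(d)) 0 else A[d, j]
      aij <- 0.5 * (row_s + row_d)
      A[i, j] <- aij
      A[j, i] <- aij
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  A <- A[as.character(ped$id), as.character(ped$id)]
  attr(A, "kind") <- "A"
  A
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Zc Zc' / (2 sum p_j (1 - p_j))` with `Zc` the dosage matrix centered
#' at twice the allele frequencies.
#'
#' @param geno A QC'd `genotype_matrix` (no missing dosages).
#' @param freqs Per-SNP allele frequencies; default = observed sample
#'   frequencies.
#' @return Symmetric matrix over the genotyped animals, attribute
#'   `kind = "G"` plus `scale_k` (the denominator) and `freqs`.
#' @export
genomic_G <- function(geno, freqs = NULL) {
  d <- geno$dosage
  if (anyNA(d)) stop("genomic_G expects imputed dosages (run snp_qc first)",
                     call. = FALSE)
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequency 0 or 1 for a retained SNP; filter monomorphic ",
         "markers first", call. = FALSE)
  Zc <- sweep(d, 2, 2 * freqs)
  k <- 2 * sum(freqs * (1 - freqs))
  G <- tcrossprod(Zc) / k
  attr(G, "kind") <- "G"
  attr(G, "scale_k") <- k
  attr(G, "freqs") <- freqs
  G
}

#' Centered dosage matrix
#'
#' @param geno A QC'd `genotype_matrix`.
#' @param freqs Allele frequencies (default sample frequencies).
#' @return Matrix `Zc = dosages - 2p` with attribute `scale_k`.
#' @export
center_dosages <- function(geno, freqs = NULL) {
  d <- geno$dosage
  if (is.null(freqs)) freqs <- colMeans(d, na.rm = TRUE) / 2
  Zc <- sweep(d, 2, 2 * freqs)
  attr(Zc, "scale_k") <- 2 * sum(freqs * (1 - freqs))
  Zc
}

#' Blend a genomic matrix with its pedigree counterpart
#'
#' `alpha * G + (1 - alpha) * A22` — the standard trick guaranteeing an
#' invertible genomic matrix (default `alpha = 0.95`).
#'
#' @param G Genomic relationship matrix.
#' @param A22 Pedigree relationships among the same (genotyped) animals.
#' @param alpha Weight on `G`, in `[0, 1]`.
#' @return Blended matrix, attribute `kind = "G_blended"`.
#' @export
blend_G <- function(G, A22, alpha = 0.95) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  stopifnot(all(dim(G) == dim(A22)))
  Gb <- alpha * G + (1 - alpha) * A22
  attr(Gb, "kind") <- "G_blended"
  attr(Gb, "scale_k") <- attr(G, "scale_k")
  Gb
}

#' Inverse of the single-step relationship matrix H
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` on the genotyped block
#' (tau = omega = 1).
#'
#' @param Ainv Inverse of the full pedigree relationship matrix (dimnames =
#'   all animal ids).
#' @param A22inv Inverse of the pedigree relationships among genotyped
#'   animals.
#' @param Ginv Inverse of the (blended) genomic matrix, same ordering as
#'   `A22inv`.
#' @param genotyped_ids Ids of the genotyped animals.
#' @return `H^-1` over all animals, attribute `kind = "Hinv"`.
#' @export
build_H_inverse <- function(Ainv, A22inv, Ginv, genotyped_ids) {
  ids <- rownames(Ainv)
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% ids))
    stop("genotyped ids are not a subset of the pedigree ids", call. = FALSE)
  Hinv <- Ainv
  if (length(genotyped_ids)) {
    gi <- match(genotyped_ids, ids)
    Hinv[gi, gi] <- Hinv[gi, gi] + Ginv - A22inv
  }
  attr(Hinv, "kind") <- "Hinv"
  Hinv
}

#' One-call construction of H^-1 from pedigree and genotypes
#'
#' Convenience wrapper: builds A, extracts A22, builds (and blends) G, and
#' assembles the single-step `H^-1`.
#'
#' @param ped A `pedigree_table`.
#' @param geno QC'd `genotype_matrix` for the genotyped subset (rownames =
#'   animal ids).
#' @param alpha Blending weight passed to [blend_G()].
#' @return List `Hinv`, `A`, `G`, `G_blended`, `genotyped_ids`.
#' @export
make_single_step_Hinv <- function(ped, geno = NULL, alpha = 0.95) {
  A <- pedigree_A(ped)
  Ainv <- solve(A)
  dimnames(Ainv) <- dimnames(A)
  if (is.null(geno) || nrow(geno$dosage) == 0L) {
    attr(Ainv, "kind") <- "Hinv"
    return(list(Hinv = Ainv, A = A, G = NULL, G_blended = NULL,
                genotyped_ids = character(0)))
  }
  gids <- rownames(geno$dosage)
  A22 <- A[gids, gids]
  G <- genomic_G(geno)
  Gb <- blend_G(G, A22, alpha)
  Hinv <- build_H_inverse(Ainv, solve(A22), solve(Gb), gids)
  list(Hinv = Hinv, A = A, G = G, G_blended = Gb, genotyped_ids = gids)
}
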