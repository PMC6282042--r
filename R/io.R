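# Plain-text readers/writers for the pipeline's tabular interfaces.
# Pedigree and phenotypes travel as tab-delimited tables; genotypes as
# PLINK-style transposed text (one row per animal: id then dosages) with a
# companion map table, or as a minimal VCF.

#' @rdname semscan_io
#' @param ped,path,geno,map_path Tables and file paths.
#' @export
write_pedigree <- function(ped, path) {
  data.table::fwrite(as.data.frame(ped), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname semscan_io
#' @export
read_pedigree <- function(path) {
  ped <- as.data.frame(data.table::fread(path, sep = "\t"))
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Read and write the package's plain-text data formats
#'
#' `write_genotypes()`/`read_genotypes()` use PLINK-style transposed text:
#' a dosage table with animals as rows (first column `id`, then one 0/1/2
#' column per SNP, `NA` for missing calls) plus a tab-delimited map file
#' with columns `snp`, `chrom`, `pos`.
#'
#' @name semscan_io
#' @export
write_genotypes <- function(geno, path, map_path = paste0(path, ".map")) {
  d <- as.data.frame(geno$dosage)
  d <- cbind(id = rownames(geno$dosage), d)
  data.table::fwrite(d, path, sep = "\t", na = "NA")
  data.table::fwrite(geno$map, map_path, sep = "\t")
  invisible(path)
}

#' @rdname semscan_io
#' @export
read_genotypes <- function(path, map_path = paste0(path, ".map")) {
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  ids <- as.character(d$id)
  d$id <- NULL
  d <- as.matrix(d)
  rownames(d) <- ids
  map <- as.data.frame(data.table::fread(map_path, sep = "\t"))
  stopifnot(all(c("snp", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(d))
  geno <- list(dosage = d, map = map)
  class(geno) <- "genotype_matrix"
  geno
}

#' @rdname semscan_io
#' @export
write_genotypes_vcf <- function(geno, path) {
  d <- geno$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=semscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(d)),
                     collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    calls <- ifelse(is.na(d[, j]), "./.", gt[d[, j] + 1L])
    writeLines(paste(c(geno$map$chrom[j], geno$map$pos[j], geno$map$snp[j],
                       "A", "B", ".", "PASS", ".", "GT", calls),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname semscan_io
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("not a VCF: missing #CHROM header", call. = FALSE)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  parse_row <- function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    gt <- sub(":.*", "", f[-(1:9)])
    dos <- ifelse(gt %in% c("0/0", "0|0"), 0L,
           ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"), 1L,
           ifelse(gt %in% c("1/1", "1|1"), 2L, NA_integer_)))
    list(chrom = f[1], pos = as.integer(f[2]), snp = f[3], dos = dos)
  }
  rows <- lapply(body, parse_row)
  d <- do.call(cbind, lapply(rows, `[[`, "dos"))
  rownames(d) <- ids
  colnames(d) <- vapply(rows, `[[`, "", "snp")
  geno <- list(dosage = d,
               map = data.frame(snp = colnames(d),
                                chrom = vapply(rows, `[[`, "", "chrom"),
                                pos = vapply(rows, `[[`, 0L, "pos"),
                                stringsAsFactors = FALSE))
  class(geno) <- "genotype_matrix"
  geno
}

#' Export genomic regions as a BED file
#'
#' BED uses 0-based, half-open intervals: a window spanning 1-based
#' inclusive positions `[start_bp, end_bp]` is written as
#' `(start_bp - 1, end_bp)`.  Records are sorted by chromosome then start;
#' chromosome names pass through verbatim.
#'
#' @param regions Data.frame with `chrom`, `start_bp`, `end_bp` and
#'   optionally `window_id` (name field) and `effect_class`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED: chrom, start (0-based), end (exclusive), name, class",
             con)
  if (nrow(regions) == 0L) return(invisible(path))
  if (!is.null(regions$window_id) && anyDuplicated(regions$window_id))
    stop("duplicate window ids in BED export", call. = FALSE)
  ord <- order(regions$chrom, regions$start_bp)
  r <- regions[ord, , drop = FALSE]
  name <- if (is.null(r$window_id)) "." else r$window_id
  cls <- if (is.null(r$effect_class)) "." else as.character(r$effect_class)
  writeLines(paste(r$chrom, r$start_bp - 1L, r$end_bp, name, cls,
                   sep = "\t"), con)
  invisible(path)
}

#' Read back a BED file written by [write_bed()]
#' @param path BED path.
#' @return Data.frame with 1-based inclusive `start_bp`, `end_bp`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(), window_id = character(),
                      effect_class = character(), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t"))
  data.frame(chrom = f[, 1], start_bp = as.integer(f[, 2]) + 1L,
             end_bp = as.integer(f[, 3]), window_id = f[, 4],
             effect_class = f[, 5], stringsAsFactors = FALSE)
}
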