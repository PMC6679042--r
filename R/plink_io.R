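# PLINK 1.x binary genotype I/O.
#
# bed v1.00, SNP-major: magic bytes 0x6c 0x1b, mode byte 0x01, then
# ceiling(n/4) bytes per SNP, two bits per sample starting at the low-order
# bits.  Two-bit codes: 00 = homozygous allele-1, 01 = missing, 10 =
# heterozygous, 11 = homozygous allele-2.  Genotypes here count copies of the
# bim's second allele, so 00 -> 0, 10 -> 1, 11 -> 2, 01 -> NA.

.bed_magic <- as.raw(c(0x6c, 0x1b))
.bed_mode_snp_major <- as.raw(0x01)

# code (0..3) -> genotype; index with code + 1
.code_to_geno <- c(0L, NA_integer_, 1L, 2L)
# genotype (0,1,2, NA) -> code
.geno_to_code <- function(g) {
  code <- integer(length(g))
  code[is.na(g)] <- 1L
  code[!is.na(g) & g == 1L] <- 2L
  code[!is.na(g) & g == 2L] <- 3L
  code
}

#' Read a PLINK bed/bim/fam triplet into a genotype panel
#'
#' Accepts either the three file paths or a common prefix. Samples keep fam
#' order; SNPs keep bim order. Every fam sample must appear in the breed
#' table.
#'
#' @param bed_path Path to the .bed file, or a prefix if the other paths are
#'   missing.
#' @param bim_path,fam_path Paths to the .bim and .fam files; default derived
#'   from \code{bed_path}.
#' @param breed_table_path Path to a 2-column sample/breed TSV, or a named
#'   character vector already in memory.
#' @param breed_header Logical, passed to \code{\link{read_breed_table}}.
#' @return A \code{\link{genotype_panel}}.
#' @export
read_panel <- function(bed_path, bim_path = NULL, fam_path = NULL,
                       breed_table_path = NULL, breed_header = FALSE) {
  if (is.null(bim_path) && !file.exists(bed_path)) {
    prefix <- bed_path
    bed_path <- paste0(prefix, ".bed")
  } else {
    prefix <- sub("\\.bed$", "", bed_path)
  }
  bim_path <- bim_path %||% paste0(prefix, ".bim")
  fam_path <- fam_path %||% paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop2("file not found: ", p)

  bim <- read_bim(bim_path)
  fam <- read_fam(fam_path)
  n <- nrow(fam); m <- nrow(bim)

  breed_of <- if (is.character(breed_table_path) && length(breed_table_path) == 1 &&
                  file.exists(breed_table_path)) {
    read_breed_table(breed_table_path, header = breed_header)
  } else if (!is.null(names(breed_table_path))) {
    breed_table_path
  } else if (is.null(breed_table_path)) {
    # fall back to fam family id as the population label
    stats::setNames(fam$fid, fam$iid)
  } else stop2("breed_table_path must be a file path or a named vector")
  missing_b <- setdiff(fam$iid, names(breed_of))
  if (length(missing_b))
    stop2("samples absent from breed table: ", paste(missing_b, collapse = ", "))

  geno <- read_bed_matrix(bed_path, n, m)
  map <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom,
                    pos_bp = bim$pos_bp, allele1 = bim$allele1,
                    allele2 = bim$allele2, stringsAsFactors = FALSE)
  genotype_panel(geno, map, fam$iid, breed_of)
}

read_bed_matrix <- function(bed_path, n, m) {
  sz <- file.info(bed_path)$size
  con <- file(bed_path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 3)
  if (length(header) < 3 || !identical(header[1:2], .bed_magic))
    stop2("not a PLINK bed file (magic bytes absent): ", bed_path)
  if (!identical(header[3], .bed_mode_snp_major))
    stop2("only SNP-major bed files (mode 0x01) are supported")
  bps <- ceiling(n / 4) # bytes per SNP
  expect <- 3 + bps * m
  if (sz != expect)
    stop2("bed size mismatch: expected ", expect, " bytes for ", n,
          " samples x ", m, " SNPs, found ", sz)
  body <- readBin(con, "raw", bps * m)
  ints <- as.integer(body)
  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  if (m == 0 || n == 0) return(geno)
  bytes <- matrix(ints, nrow = bps, ncol = m)
  for (s in 0:3) {
    rows <- (seq_len(bps) - 1L) * 4L + s + 1L
    keep <- rows <= n
    if (!any(keep)) next
    codes <- bitwAnd(bitwShiftR(bytes[keep, , drop = FALSE], 2L * s), 3L)
    geno[rows[keep], ] <- .code_to_geno[codes + 1L]
  }
  geno
}

#' Write a genotype panel as a PLINK bed/bim/fam triplet
#'
#' Inverse of \code{\link{read_panel}}: \code{read_panel(write_panel(p))}
#' reproduces every genotype, position, allele pair and sample id. A breed
#' TSV is written alongside.
#'
#' @param panel A \code{\link{genotype_panel}}.
#' @param out_prefix Output path prefix; \code{.bed}, \code{.bim},
#'   \code{.fam} and \code{.breeds.tsv} are appended.
#' @return Invisibly, the prefix.
#' @export
write_panel <- function(panel, out_prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop2("output directory does not exist: ", dir)
  write_bed_matrix(panel$genotypes, paste0(out_prefix, ".bed"))
  write_bim(panel$map, paste0(out_prefix, ".bim"))
  fam <- data.frame(fid = unname(panel$breed_of), iid = panel$samples,
                    pid = "0", mid = "0", sex = "0", pheno = "-9")
  utils::write.table(fam, paste0(out_prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_breed_table(panel$breed_of, paste0(out_prefix, ".breeds.tsv"))
  invisible(out_prefix)
}

write_bed_matrix <- function(geno, path) {
  n <- nrow(geno); m <- ncol(geno)
  bps <- ceiling(n / 4)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(.bed_magic, .bed_mode_snp_major), con)
  if (m == 0) return(invisible(path))
  codes <- matrix(0L, nrow = bps * 4L, ncol = m)
  if (n > 0) codes[seq_len(n), ] <- matrix(.geno_to_code(geno), nrow = n)
  i1 <- seq(1L, bps * 4L, by = 4L)
  packed <- codes[i1, , drop = FALSE] +
    4L  * codes[i1 + 1L, , drop = FALSE] +
    16L * codes[i1 + 2L, , drop = FALSE] +
    64L * codes[i1 + 3L, , drop = FALSE]
  writeBin(as.raw(packed), con)
  invisible(path)
}

read_bim <- function(path) {
  if (file.info(path)$size == 0)
    return(data.frame(chrom = character(), snp_id = character(),
                      cm = numeric(), pos_bp = integer(),
                      allele1 = character(), allele2 = character(),
                      stringsAsFactors = FALSE))
  bim <- utils::read.table(path, header = FALSE, sep = "",
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chrom", "snp_id", "cm", "pos_bp", "allele1", "allele2")
  bim
}

write_bim <- function(map, path) {
  m <- nrow(map)
  bim <- data.frame(chrom = ifelse(map$chrom == "", "0", map$chrom),
                    snp_id = map$snp_id, cm = rep(0, m),
                    pos_bp = map$pos_bp,
                    allele1 = map$allele1 %||% rep("A", m),
                    allele2 = map$allele2 %||% rep("B", m))
  utils::write.table(bim, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_fam <- function(path) {
  if (file.info(path)$size == 0)
    return(data.frame(fid = character(), iid = character(),
                      stringsAsFactors = FALSE))
  fam <- utils::read.table(path, header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(fam) < 2) stop2("fam file must have at least 2 columns")
  data.frame(fid = fam[[1]], iid = fam[[2]], stringsAsFactors = FALSE)
}
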