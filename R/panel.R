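#' Construct a genotype panel
#'
#' The canonical in-memory container consumed by every other module: a
#' samples-by-SNPs genotype matrix coded as the count of the second (B) allele
#' (0, 1, 2, or \code{NA} for missing), a SNP map, and a breed label per
#' sample.
#'
#' @param genotypes Integer matrix, samples in rows, SNPs in columns. Entries
#'   must be 0, 1, 2 or \code{NA}. Row names (if present) must match
#'   \code{samples}.
#' @param map Data frame with columns \code{snp_id}, \code{chrom} (character;
#'   \code{"0"} or \code{""} mean unplaced), \code{pos_bp} (1-based physical
#'   position) and \code{allele1}, \code{allele2} (single-character codes).
#' @param samples Character vector of unique sample ids, one per matrix row.
#' @param breed_of Named character vector mapping every sample id to a breed
#'   label.
#' @return An object of class \code{genotype_panel}.
#' @export
genotype_panel <- function(genotypes, map, samples, breed_of) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  samples <- as.character(samples)
  if (nrow(genotypes) != length(samples))
    stop2("genotype matrix has ", nrow(genotypes), " rows but ",
          length(samples), " sample ids")
  if (ncol(genotypes) != nrow(map))
    stop2("genotype matrix has ", ncol(genotypes), " columns but map has ",
          nrow(map), " SNPs")
  if (anyDuplicated(samples))
    stop2("duplicate sample ids: ",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(map$snp_id))
    stop2("duplicate SNP ids in map")
  bad <- setdiff(samples, names(breed_of))
  if (length(bad))
    stop2("samples missing from breed table: ", paste(bad, collapse = ", "))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop2("genotypes must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.integer(map$pos_bp)
  map$snp_id <- as.character(map$snp_id)
  rownames(genotypes) <- samples
  colnames(genotypes) <- map$snp_id
  structure(
    list(genotypes = genotypes, map = map, samples = samples,
         breed_of = breed_of[samples]),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  nb <- length(unique(x$breed_of))
  cat("genotype_panel: ", length(x$samples), " samples (", nb, " breed",
      if (nb != 1) "s", "), ", nrow(x$map), " SNPs on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Subset a panel by SNP and/or sample index
#'
#' @param panel A \code{genotype_panel}.
#' @param snps Index vector over SNPs (columns) or NULL to keep all.
#' @param samples Index vector over samples (rows) or NULL to keep all.
#' @return A \code{genotype_panel}.
#' @export
subset_panel <- function(panel, snps = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  si <- if (is.null(snps)) seq_len(nrow(panel$map)) else snps
  ri <- if (is.null(samples)) seq_along(panel$samples) else samples
  genotype_panel(panel$genotypes[ri, si, drop = FALSE],
                 panel$map[si, , drop = FALSE],
                 panel$samples[ri], panel$breed_of)
}

#' Breeds present in a panel, in order of first appearance
#' @param panel A \code{genotype_panel}.
#' @return Character vector of breed labels.
#' @export
panel_breeds <- function(panel) unique(unname(panel$breed_of))

#' Read a sample-to-breed table
#'
#' Two-column whitespace/tab separated file: sample id, breed label.
#'
#' @param path File path.
#' @param header Logical; does the first row hold column names?
#' @return Named character vector (names = sample ids, values = breeds).
#' @export
read_breed_table <- function(path, header = FALSE) {
  tab <- utils::read.table(path, header = header, sep = "",
                           colClasses = "character",
                           col.names = if (!header) c("sample_id", "breed"))
  if (ncol(tab) < 2) stop2("breed table must have two columns")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write a sample-to-breed table
#' @param breed_of Named character vector (sample id -> breed).
#' @param path Output path (TSV, no header).
#' @return Invisibly, the path.
#' @export
write_breed_table <- function(breed_of, path) {
  utils::write.table(data.frame(names(breed_of), unname(breed_of)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
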