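#' SNP quality control for a genotype panel
#'
#' Applies the marker filters used for selection-signature screening, in a
#' fixed order so the report is reproducible: (1) drop unplaced SNPs (chrom
#' \code{"0"} or empty), (2) drop sex-chromosome SNPs, (3) drop SNPs whose
#' missing-genotype rate is strictly greater than \code{max_missing}. A SNP
#' with missing rate exactly at the threshold is retained. Samples are never
#' filtered.
#'
#' @param panel A \code{\link{genotype_panel}}.
#' @param max_missing Maximum tolerated missing-genotype fraction per SNP
#'   (default 0.10; strictly greater is removed).
#' @param drop_chroms Chromosome labels to remove (default sex chromosomes
#'   \code{c("X", "Y")}).
#' @param drop_unplaced Drop SNPs with chromosome \code{"0"} or \code{""}?
#' @return A list with elements \code{panel} (the filtered
#'   \code{genotype_panel}) and \code{report} (a \code{qc_report}).
#' @export
apply_qc <- function(panel, max_missing = 0.10, drop_chroms = c("X", "Y"),
                     drop_unplaced = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(panel$map) == 0) stop2("panel has no SNPs")
  chrom <- panel$map$chrom
  keep <- rep(TRUE, length(chrom))

  unplaced <- drop_unplaced & (chrom == "0" | chrom == "")
  n_unplaced <- sum(keep & unplaced)
  keep <- keep & !unplaced

  sex <- chrom %in% drop_chroms
  n_sex <- sum(keep & sex)
  keep <- keep & !sex

  miss_rate <- colMeans(is.na(panel$genotypes))
  high_miss <- miss_rate > max_missing
  n_miss <- sum(keep & high_miss)
  keep <- keep & !high_miss

  report <- structure(
    list(n_snps_in = length(chrom),
         n_removed_unplaced = n_unplaced,
         n_removed_sex = n_sex,
         n_removed_missingness = n_miss,
         n_snps_out = sum(keep),
         max_missing_rate = max_missing),
    class = "qc_report")
  if (report$n_snps_out == 0)
    warning("QC removed every SNP; returning an empty panel", call. = FALSE)
  out <- subset_panel(panel, snps = which(keep))
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n",
      "  SNPs in:                 ", x$n_snps_in, "\n",
      "  removed (unplaced):      ", x$n_removed_unplaced, "\n",
      "  removed (sex chroms):    ", x$n_removed_sex, "\n",
      "  removed (missing > ", format(x$max_missing_rate), "): ",
      x$n_removed_missingness, "\n",
      "  SNPs out:                ", x$n_snps_out, "\n", sep = "")
  invisible(x)
}
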