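# Candidate-locus statistics: per-breed genotype/allele frequencies, exact
# Hardy-Weinberg test, and gene-annotation intersection with islands.

#' Per-breed genotype counts and frequencies at one SNP
#'
#' @param panel A \code{\link{genotype_panel}}.
#' @param snp_id SNP identifier present in the panel map.
#' @param include_missing Compute fractions over all individuals (TRUE) or
#'   over non-missing genotypes only (default FALSE).
#' @return Data frame, one row per breed: n_hom_ref (genotype 0), n_het,
#'   n_hom_alt (genotype 2), n_missing, the corresponding fractions, and the
#'   alt (second) allele frequency.
#' @export
genotype_frequencies <- function(panel, snp_id, include_missing = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  j <- match(snp_id, panel$map$snp_id)
  if (is.na(j)) stop2("SNP not found in panel map: ", snp_id)
  g <- panel$genotypes[, j]
  out <- do.call(rbind, lapply(panel_breeds(panel), function(b) {
    gb <- g[panel$breed_of == b]
    n0 <- sum(!is.na(gb) & gb == 0L)
    n1 <- sum(!is.na(gb) & gb == 1L)
    n2 <- sum(!is.na(gb) & gb == 2L)
    nm <- sum(is.na(gb))
    denom <- if (include_missing) length(gb) else max(n0 + n1 + n2, 1L)
    af <- if (n0 + n1 + n2 > 0) (n1 + 2 * n2) / (2 * (n0 + n1 + n2)) else NA_real_
    data.frame(breed = b, snp_id = snp_id, n = length(gb),
               n_hom_ref = n0, n_het = n1, n_hom_alt = n2, n_missing = nm,
               f_hom_ref = n0 / denom, f_het = n1 / denom,
               f_hom_alt = n2 / denom, alt_freq = af,
               stringsAsFactors = FALSE)
  }))
  out
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table
#' (probability-mass ordering), under the standard distribution of the
#' heterozygote count given the allele margins.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (missing genotypes are
#'   simply excluded beforehand).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (length(n_hom_ref) == 3 && missing(n_het)) {
    n_het <- n_hom_ref[2]; n_hom_alt <- n_hom_ref[3]; n_hom_ref <- n_hom_ref[1]
  }
  n0 <- as.integer(n_hom_ref); n1 <- as.integer(n_het); n2 <- as.integer(n_hom_alt)
  if (any(c(n0, n1, n2) < 0)) stop2("genotype counts must be non-negative")
  n <- n0 + n1 + n2
  if (n < 1) stop2("at least one non-missing genotype is required")
  n_a <- 2L * n0 + n1           # copies of the rarer-or-not allele A
  n_b <- 2L * n2 + n1
  rare <- min(n_a, n_b)
  # attainable heterozygote counts share the parity of the rare-allele count
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(het = h | allele margins), normalized below
  logp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lgamma(n + 1) - lgamma(homr + 1) - lgamma(h + 1) - lgamma(homc + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n1, hets)
  if (is.na(obs)) stop2("heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Read a gene annotation as intervals
#'
#' @param path BED file (0-based half-open) or 4+-column TSV
#'   (gene, chrom, start, end; 1-based inclusive).
#' @param coords Coordinate convention of the file: \code{"bed"} or
#'   \code{"tsv"}.
#' @return Data frame: gene, chrom, start_bp, end_bp (1-based inclusive).
#' @export
read_gene_annotation <- function(path, coords = c("bed", "tsv")) {
  coords <- match.arg(coords)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (coords == "bed") {
    if (ncol(tab) < 4) stop2("BED annotation needs chrom, start, end, name")
    out <- data.frame(gene = as.character(tab[[4]]),
                      chrom = as.character(tab[[1]]),
                      start_bp = as.integer(tab[[2]]) + 1L,
                      end_bp = as.integer(tab[[3]]),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(tab) < 4) stop2("TSV annotation needs gene, chrom, start, end")
    out <- data.frame(gene = as.character(tab[[1]]),
                      chrom = as.character(tab[[2]]),
                      start_bp = as.integer(tab[[3]]),
                      end_bp = as.integer(tab[[4]]),
                      stringsAsFactors = FALSE)
  }
  if (any(out$start_bp > out$end_bp)) stop2("annotation has start > end")
  out
}

#' Genes intersecting ROH islands
#'
#' A gene is reported for an island iff their intervals share at least 1 bp
#' (the same closed-interval convention as island overlaps). The per-breed
#' gene count is the size of the union of gene symbols over the breed's
#' islands.
#'
#' @param islands Island data frame (breed, chrom, start_bp, end_bp,
#'   island_id).
#' @param annotation Data frame from \code{\link{read_gene_annotation}}.
#' @return List with \code{per_island} (island_id, breed, genes
#'   comma-separated, n_genes) and \code{per_breed} (breed, n_genes).
#' @export
genes_in_islands <- function(islands, annotation) {
  if (nrow(islands) && nrow(annotation) &&
      !any(annotation$chrom %in% islands$chrom) &&
      !any(islands$chrom %in% annotation$chrom))
    stop2("no chromosome labels shared between islands and annotation; ",
          "check naming conventions (islands: ",
          paste(utils::head(unique(islands$chrom), 3), collapse = ","),
          " vs annotation: ",
          paste(utils::head(unique(annotation$chrom), 3), collapse = ","), ")")
  per_island <- do.call(rbind, c(list(
    data.frame(island_id = character(), breed = character(),
               genes = character(), n_genes = integer(),
               stringsAsFactors = FALSE)),
    lapply(seq_len(nrow(islands)), function(k) {
      hit <- annotation$chrom == islands$chrom[k] &
        intervals_overlap(annotation$start_bp, annotation$end_bp,
                          islands$start_bp[k], islands$end_bp[k])
      data.frame(island_id = islands$island_id[k], breed = islands$breed[k],
                 genes = paste(sort(unique(annotation$gene[hit])),
                               collapse = ","),
                 n_genes = length(unique(annotation$gene[hit])),
                 stringsAsFactors = FALSE)
    })))
  per_breed <- do.call(rbind, lapply(unique(islands$breed), function(b) {
    genes <- unlist(strsplit(per_island$genes[per_island$breed == b], ","))
    genes <- genes[genes != ""]
    data.frame(breed = b, n_genes = length(unique(genes)),
               stringsAsFactors = FALSE)
  }))
  list(per_island = per_island,
       per_breed = per_breed %||% data.frame(breed = character(),
                                             n_genes = integer()))
}
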