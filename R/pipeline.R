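# End-to-end orchestration: simulate/ingest -> QC -> ROH -> islands ->
# overlaps -> locus stats -> PCA, with a reproducible run manifest.

#' Pipeline configuration
#'
#' Either \code{design} (a \code{\link{panel_design}} or path to its YAML)
#' for a simulated run, or \code{bed_prefix} + \code{breed_table} for real
#' data. Validation happens here, before any compute.
#'
#' @param design A \code{\link{panel_design}}, or path to a design YAML.
#' @param bed_prefix Prefix of a PLINK bed/bim/fam triplet.
#' @param breed_table Path to the sample/breed TSV (real-data runs).
#' @param params A \code{\link{roh_params}}.
#' @param island_threshold Sharing threshold for islands (strict >).
#' @param max_missing SNP QC missingness threshold.
#' @param annotation Optional path to a gene annotation (BED).
#' @param annotation_coords \code{"bed"} or \code{"tsv"}.
#' @param candidate_snps Optional character vector of SNP ids for the
#'   genotype-frequency / HWE report.
#' @param roh_method \code{"windowed"} or \code{"exact"}.
#' @param pca_k Number of principal components to keep.
#' @param out_dir Output directory (created if absent); NULL disables file
#'   output.
#' @param seed Integer seed (overrides the design's seed when given).
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(design = NULL, bed_prefix = NULL,
                            breed_table = NULL, params = roh_params(),
                            island_threshold = 0.5, max_missing = 0.10,
                            annotation = NULL, annotation_coords = "bed",
                            candidate_snps = NULL,
                            roh_method = c("windowed", "exact"), pca_k = 10,
                            out_dir = NULL, seed = NULL) {
  roh_method <- match.arg(roh_method)
  if (is.null(design) && is.null(bed_prefix))
    stop2("either a design or a bed_prefix is required")
  if (!is.null(design) && !is.null(bed_prefix))
    stop2("give either a design or a bed_prefix, not both")
  if (is.character(design)) {
    if (!file.exists(design)) stop2("design file not found: ", design)
    design <- read_panel_design(design)
  }
  if (!is.null(bed_prefix)) {
    for (ext in c(".bed", ".bim", ".fam"))
      if (!file.exists(paste0(bed_prefix, ext)))
        stop2("missing input file: ", paste0(bed_prefix, ext))
    if (!is.null(breed_table) && !file.exists(breed_table))
      stop2("breed table not found: ", breed_table)
  }
  if (island_threshold < 0 || island_threshold >= 1)
    stop2("island_threshold must lie in [0, 1)")
  if (max_missing < 0 || max_missing > 1)
    stop2("max_missing must lie in [0, 1]")
  if (!is.null(annotation) && !file.exists(annotation))
    stop2("annotation file not found: ", annotation)
  if (!is.null(seed) && !is.null(design)) design$seed <- as.integer(seed)
  structure(list(design = design, bed_prefix = bed_prefix,
                 breed_table = breed_table, params = params,
                 island_threshold = island_threshold,
                 max_missing = max_missing, annotation = annotation,
                 annotation_coords = annotation_coords,
                 candidate_snps = candidate_snps, roh_method = roh_method,
                 pca_k = pca_k, out_dir = out_dir,
                 seed = seed %||% (design$seed %||% NA_integer_)),
            class = "pipeline_config")
}

#' Run the full ROH-island pipeline
#'
#' Stages: input (simulate or read PLINK), SNP QC, ROH calling, S_ROH,
#' per-breed incidence and island calling, cross-breed overlaps,
#' private-island classification, breed summary, optional gene
#' intersection and candidate-locus statistics, IBS-PCA. With
#' \code{out_dir} set, every table is written as TSV/BED along with a JSON
#' run manifest; reruns with the same config are byte-identical.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return An object of class \code{roh_scan} bundling all stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  res <- tryCatch({
    truth <- NULL
    if (!is.null(config$design)) {
      sim <- simulate_panel(config$design)
      panel_raw <- sim$panel; truth <- sim$truth
    } else {
      panel_raw <- read_panel(config$bed_prefix,
                              breed_table_path = config$breed_table)
    }

    stage <- "qc"
    qc <- apply_qc(panel_raw, max_missing = config$max_missing)
    panel <- qc$panel

    stage <- "roh"
    segments <- call_roh(panel, config$params, method = config$roh_method)
    sroh_sum <- sroh(segments, panel)

    stage <- "islands"
    islands <- call_islands_all(segments, panel, config$island_threshold)
    overlaps <- cross_breed_overlaps(islands)
    classes <- classify_private(islands, overlaps)
    breed_summary <- summarize_breeds(classes$islands, sroh_sum)

    stage <- "loci"
    gene_report <- NULL
    if (!is.null(config$annotation)) {
      ann <- read_gene_annotation(config$annotation, config$annotation_coords)
      gene_report <- genes_in_islands(classes$islands, ann)
    }
    locus_report <- NULL
    if (!is.null(config$candidate_snps)) {
      locus_report <- do.call(rbind, lapply(config$candidate_snps, function(s)
        genotype_frequencies(panel, s)))
      locus_report$hwe_p <- vapply(seq_len(nrow(locus_report)), function(i)
        hwe_exact_test(locus_report$n_hom_ref[i], locus_report$n_het[i],
                       locus_report$n_hom_alt[i]), numeric(1))
    }

    stage <- "pca"
    G <- ibs_matrix(panel)
    pca <- pca_from_similarity(G, k = min(config$pca_k, nrow(G)))

    structure(list(config = config, panel = panel, qc_report = qc$report,
                   truth = truth, segments = segments, sroh = sroh_sum,
                   islands = classes$islands, overlaps = overlaps,
                   classification = classes, breed_summary = breed_summary,
                   gene_report = gene_report, locus_report = locus_report,
                   ibs = G, pca = pca),
              class = "roh_scan")
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  if (!is.null(config$out_dir)) write_outputs(res, config$out_dir)
  res
}

write_outputs <- function(scan, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  segs <- scan$segments
  if (nrow(segs)) segs$length_kb <- segs$length_bp / 1000
  tsv(segs, "roh_segments.tsv")
  tsv(scan$sroh$per_sample, "sroh_per_sample.tsv")
  tsv(scan$sroh$per_breed, "sroh_per_breed.tsv")
  tsv(scan$islands, "islands.tsv")
  if (nrow(scan$islands))
    write_bed_intervals(scan$islands, file.path(out_dir, "islands.bed"))
  tsv(scan$overlaps$regions, "overlap_regions.tsv")
  if (nrow(scan$overlaps$regions))
    write_bed_intervals(scan$overlaps$regions,
                        file.path(out_dir, "overlap_regions.bed"))
  tsv(scan$overlaps$membership, "overlap_membership.tsv")
  tsv(scan$breed_summary, "breed_summary.tsv")
  if (!is.null(scan$gene_report)) {
    tsv(scan$gene_report$per_island, "genes_per_island.tsv")
    tsv(scan$gene_report$per_breed, "genes_per_breed.tsv")
  }
  if (!is.null(scan$locus_report)) tsv(scan$locus_report, "locus_report.tsv")
  utils::write.table(format(unclass(scan$ibs), digits = 10),
                     file.path(out_dir, "ibs_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  co <- as.data.frame(scan$pca$coordinates)
  co <- cbind(sample_id = rownames(co),
              breed = unname(scan$panel$breed_of[rownames(co)]), co)
  tsv(co, "pca_coordinates.tsv")
  tsv(data.frame(component = seq_along(scan$pca$variance_fraction),
                 variance_fraction = scan$pca$variance_fraction),
      "pca_variance.tsv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("rohscan")),
    seed = scan$config$seed,
    roh_method = scan$config$roh_method,
    island_threshold = scan$config$island_threshold,
    max_missing = scan$config$max_missing,
    roh_params = unclass(scan$config$params),
    n_samples = length(scan$panel$samples),
    n_snps = nrow(scan$panel$map),
    qc = unclass(scan$qc_report),
    n_segments = nrow(scan$segments),
    n_islands = scan$classification$global$n_total,
    n_private = scan$classification$global$n_private,
    n_overlap_regions = scan$classification$global$n_overlap_regions)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @export
print.roh_scan <- function(x, ...) {
  g <- x$classification$global
  cat("roh_scan of ", length(x$panel$samples), " samples / ",
      length(panel_breeds(x$panel)), " breeds / ", nrow(x$panel$map),
      " SNPs\n", sep = "")
  cat("  ROH segments: ", nrow(x$segments), "\n", sep = "")
  cat("  islands: ", g$n_total, " (", g$n_private, " private, ",
      g$n_in_regions, " in ", g$n_overlap_regions,
      " cross-breed overlap regions)\n", sep = "")
  cat(sprintf("  mean S_ROH across breeds: %.1f Mb\n",
              mean(x$sroh$per_breed$mean_sroh_mb)))
  invisible(x)
}

#' @export
summary.roh_scan <- function(object, ...) {
  cat("Per-breed summary:\n")
  print(object$breed_summary, row.names = FALSE)
  if (nrow(object$overlaps$regions)) {
    cat("\nCross-breed overlap regions:\n")
    print(object$overlaps$regions[, c("region_id", "n_breeds", "breeds")],
          row.names = FALSE)
  }
  invisible(object$breed_summary)
}

#' @export
plot.roh_scan <- function(x, chrom = NULL, range_bp = NULL, genes = NULL, ...) {
  chrom <- chrom %||% (if (nrow(x$islands)) x$islands$chrom[1]
                       else x$panel$map$chrom[1])
  plot_tracks(x$islands, x$overlaps$regions, genes = genes, chrom = chrom,
              range_bp = range_bp, ...)
}
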