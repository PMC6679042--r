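# Multi-breed panel simulator with implanted autozygous tracts.
#
# Background genotypes are drawn per breed from Hardy-Weinberg proportions at
# each SNP's founder allele frequency (no linkage disequilibrium).  Each
# implanted tract carries one founder haplotype drawn from the founder
# frequencies; the chosen carriers of a breed are set homozygous for that
# haplotype across every SNP inside the tract, BEFORE the error/missingness
# perturbation, so genotyping noise can create heterozygotes inside real
# autozygous tracts exactly as on a real array.
#
# All randomness flows through per-(purpose, breed, tract, chromosome)
# sub-seeds derived from the design seed, so breed blocks are independent:
# resizing one breed never changes another breed's genotypes.

#' Specify an autozygous tract to implant
#'
#' @param chrom Chromosome label.
#' @param start_bp,end_bp Tract bounds in bp (1-based, inclusive;
#'   \code{start_bp < end_bp}).
#' @param carriers Named numeric vector: carrier fraction in [0, 1] per breed
#'   label. Breeds not named carry the tract at fraction 0.
#' @return An object of class \code{implant_spec}.
#' @export
implant_tract <- function(chrom, start_bp, end_bp, carriers) {
  if (start_bp >= end_bp) stop2("tract start_bp must be < end_bp")
  if (is.null(names(carriers)) || any(names(carriers) == ""))
    stop2("carriers must be a named vector of per-breed fractions")
  if (any(carriers < 0 | carriers > 1))
    stop2("carrier fractions must lie in [0, 1]")
  structure(list(chrom = as.character(chrom), start_bp = as.integer(start_bp),
                 end_bp = as.integer(end_bp), carriers = carriers),
            class = "implant_spec")
}

#' Design a synthetic multi-breed genotype panel
#'
#' @param breeds Named integer vector: number of individuals per breed label.
#' @param chrom_lengths_bp Named numeric vector: chromosome label -> length in
#'   bp.
#' @param snp_spacing_bp Target mean inter-SNP distance in bp (default 5000,
#'   i.e. array-like density of one SNP per 5 kb).
#' @param allele_freq_range Range of the uniform law for per-SNP founder
#'   allele frequencies (default \code{c(0.05, 0.95)}).
#' @param tracts List of \code{\link{implant_tract}} specs.
#' @param genotype_error_rate Probability that a genotype is replaced by a
#'   uniformly random genotype from \{0, 1, 2\}.
#' @param missing_rate Probability that a genotype is set missing.
#' @param seed Integer base seed.
#' @return An object of class \code{panel_design}.
#' @export
panel_design <- function(breeds, chrom_lengths_bp, snp_spacing_bp = 5000,
                         allele_freq_range = c(0.05, 0.95), tracts = list(),
                         genotype_error_rate = 0, missing_rate = 0, seed = 1) {
  if (is.null(names(breeds)) || any(names(breeds) == ""))
    stop2("breeds must be a named vector of sample sizes")
  if (any(breeds < 1)) stop2("every breed needs at least one individual")
  if (snp_spacing_bp <= 0) stop2("snp_spacing_bp must be positive")
  if (genotype_error_rate < 0 || genotype_error_rate > 1 ||
      missing_rate < 0 || missing_rate > 1)
    stop2("rates must lie in [0, 1]")
  if (is.null(names(chrom_lengths_bp)))
    names(chrom_lengths_bp) <- as.character(seq_along(chrom_lengths_bp))
  for (tr in tracts) {
    if (!inherits(tr, "implant_spec")) stop2("tracts must be implant_tract() specs")
    if (!tr$chrom %in% names(chrom_lengths_bp))
      stop2("tract on unknown chromosome: ", tr$chrom)
    if (tr$end_bp > chrom_lengths_bp[[tr$chrom]])
      stop2("tract [", tr$start_bp, ", ", tr$end_bp,
            "] exceeds chromosome ", tr$chrom, " length")
    unknown <- setdiff(names(tr$carriers), names(breeds))
    if (length(unknown))
      stop2("tract carrier fraction for unknown breed: ",
            paste(unknown, collapse = ", "))
  }
  structure(list(breeds = breeds, chrom_lengths_bp = chrom_lengths_bp,
                 snp_spacing_bp = snp_spacing_bp,
                 allele_freq_range = allele_freq_range, tracts = tracts,
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "panel_design")
}

#' Simulate a genotype panel from a design
#'
#' @param design A \code{\link{panel_design}}.
#' @return List with elements \code{panel} (a \code{\link{genotype_panel}})
#'   and \code{truth} (a \code{truth_set} recording, per implanted tract, its
#'   spec, founder haplotype and carrier sample ids per breed).
#' @export
simulate_panel <- function(design) {
  stopifnot(inherits(design, "panel_design"))
  seed <- design$seed

  # --- shared SNP map (one array map for all breeds) ---
  maps <- lapply(names(design$chrom_lengths_bp), function(ch) {
    len <- design$chrom_lengths_bp[[ch]]
    m <- max(1L, round_half_up(len / design$snp_spacing_bp))
    pos <- with_seed(subseed(seed, "map", ch),
                    sort(sample.int(as.integer(len), m)))
    data.frame(chrom = ch, pos_bp = pos, stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, maps)
  map$snp_id <- sprintf("snp_%s_%d", map$chrom, map$pos_bp)
  map$allele1 <- "A"
  map$allele2 <- "B"
  map <- map[, c("snp_id", "chrom", "pos_bp", "allele1", "allele2")]
  m <- nrow(map)

  freq <- with_seed(subseed(seed, "freq"),
                    stats::runif(m, design$allele_freq_range[1],
                                 design$allele_freq_range[2]))

  # --- per-breed background genotypes under Hardy-Weinberg proportions ---
  breeds <- names(design$breeds)
  geno_blocks <- vector("list", length(breeds))
  sample_ids <- character(0)
  breed_of <- character(0)
  for (bi in seq_along(breeds)) {
    b <- breeds[bi]
    nb <- design$breeds[[b]]
    ids <- sprintf("%s_%03d", b, seq_len(nb))
    g <- with_seed(subseed(seed, "bg", b),
                   matrix(stats::rbinom(nb * m, 2L, rep(freq, each = nb)),
                          nrow = nb))
    rownames(g) <- ids
    geno_blocks[[bi]] <- g
    sample_ids <- c(sample_ids, ids)
    breed_of <- c(breed_of, stats::setNames(rep(b, nb), ids))
  }
  names(geno_blocks) <- breeds

  # --- implant tracts: one founder haplotype, carriers homozygous for it ---
  truth <- vector("list", length(design$tracts))
  for (ti in seq_along(design$tracts)) {
    tr <- design$tracts[[ti]]
    idx <- which(map$chrom == tr$chrom &
                 map$pos_bp >= tr$start_bp & map$pos_bp <= tr$end_bp)
    hap <- with_seed(subseed(seed, "tract", ti),
                     stats::rbinom(length(idx), 1L, freq[idx]))
    carriers <- list()
    for (b in names(tr$carriers)) {
      nb <- design$breeds[[b]]
      n_car <- round_half_up(tr$carriers[[b]] * nb)
      if (n_car == 0) { carriers[[b]] <- character(0); next }
      who <- with_seed(subseed(seed, "tract", ti, "carriers", b),
                       sort(sample.int(nb, n_car)))
      geno_blocks[[b]][who, idx] <- rep(2L * hap, each = n_car)
      carriers[[b]] <- rownames(geno_blocks[[b]])[who]
    }
    truth[[ti]] <- list(spec = tr, snp_idx = idx, snp_ids = map$snp_id[idx],
                        haplotype = hap, carriers = carriers)
  }

  # --- per-breed genotyping error, then missingness ---
  for (b in breeds) {
    g <- geno_blocks[[b]]
    if (design$genotype_error_rate > 0 || design$missing_rate > 0) {
      g <- with_seed(subseed(seed, "noise", b), {
        if (design$genotype_error_rate > 0) {
          err <- stats::runif(length(g)) < design$genotype_error_rate
          g[err] <- sample(0:2, sum(err), replace = TRUE)
        }
        if (design$missing_rate > 0) {
          mis <- stats::runif(length(g)) < design$missing_rate
          g[mis] <- NA_integer_
        }
        g
      })
      geno_blocks[[b]] <- g
    }
  }

  geno <- do.call(rbind, geno_blocks)
  rownames(geno) <- sample_ids
  panel <- genotype_panel(geno, map, sample_ids, breed_of)
  truth <- structure(list(tracts = truth, design = design), class = "truth_set")
  list(panel = panel, truth = truth)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", length(x$tracts), "implanted tract(s)\n")
  for (i in seq_along(x$tracts)) {
    tr <- x$tracts[[i]]
    fr <- paste(sprintf("%s=%.2f", names(tr$spec$carriers),
                        tr$spec$carriers), collapse = ", ")
    cat(sprintf("  [%d] chr%s:%d-%d (%d SNPs) carriers: %s\n", i,
                tr$spec$chrom, tr$spec$start_bp, tr$spec$end_bp,
                length(tr$snp_idx), fr))
  }
  invisible(x)
}

#' Expected ROH-island incidence of an implanted tract
#'
#' Analytic helper for recovery tests: the expected per-SNP incidence inside
#' an implanted tract equals the breed's carrier fraction plus the expected
#' background ROH coverage. For default designs (no linkage disequilibrium,
#' intermediate allele frequencies) the chance that background genotypes form
#' a run of more than 80 consecutive homozygous SNPs is astronomically small,
#' so background coverage is approximated as 0.
#'
#' @param spec An \code{\link{implant_tract}} spec.
#' @param breed Breed label.
#' @param design The \code{\link{panel_design}} (used only to validate the
#'   breed label).
#' @return Expected incidence fraction in [0, 1].
#' @export
expected_incidence <- function(spec, breed, design) {
  stopifnot(inherits(spec, "implant_spec"))
  if (!breed %in% names(design$breeds)) stop2("unknown breed: ", breed)
  unname(if (breed %in% names(spec$carriers)) spec$carriers[[breed]] else 0)
}

#' Read / write a panel design as YAML
#'
#' @param path File path.
#' @return \code{read_panel_design}: a \code{\link{panel_design}}.
#' @export
read_panel_design <- function(path) {
  y <- yaml::read_yaml(path)
  tracts <- lapply(y$tracts %||% list(), function(tr)
    implant_tract(tr$chrom, tr$start_bp, tr$end_bp, unlist(tr$carriers)))
  panel_design(breeds = unlist(y$breeds),
               chrom_lengths_bp = unlist(y$chrom_lengths_bp),
               snp_spacing_bp = y$snp_spacing_bp %||% 5000,
               allele_freq_range = unlist(y$allele_freq_range %||% c(0.05, 0.95)),
               tracts = tracts,
               genotype_error_rate = y$genotype_error_rate %||% 0,
               missing_rate = y$missing_rate %||% 0,
               seed = y$seed %||% 1)
}

#' @rdname read_panel_design
#' @param design A \code{\link{panel_design}}.
#' @return \code{write_panel_design}: invisibly, the path.
#' @export
write_panel_design <- function(design, path) {
  y <- list(breeds = as.list(design$breeds),
            chrom_lengths_bp = as.list(design$chrom_lengths_bp),
            snp_spacing_bp = design$snp_spacing_bp,
            allele_freq_range = design$allele_freq_range,
            tracts = lapply(design$tracts, function(tr)
              list(chrom = tr$chrom, start_bp = tr$start_bp,
                   end_bp = tr$end_bp, carriers = as.list(tr$carriers))),
            genotype_error_rate = design$genotype_error_rate,
            missing_rate = design$missing_rate,
            seed = design$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Write a truth set as TSV
#'
#' One row per (tract, breed): tract coordinates, carrier fraction and the
#' comma-separated carrier sample ids.
#'
#' @param truth A \code{truth_set} from \code{\link{simulate_panel}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_set <- function(truth, path) {
  rows <- list()
  for (i in seq_along(truth$tracts)) {
    tr <- truth$tracts[[i]]
    for (b in names(tr$spec$carriers)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tract = i, chrom = tr$spec$chrom, start_bp = tr$spec$start_bp,
        end_bp = tr$spec$end_bp, breed = b,
        carrier_fraction = unname(tr$spec$carriers[[b]]),
        carriers = paste(tr$carriers[[b]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tract = integer(), chrom = character(), start_bp = integer(),
               end_bp = integer(), breed = character(),
               carrier_fraction = numeric(), carriers = character())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The shipped demonstration design
#'
#' A 12-breed panel of 30 individuals each over five 20-Mb chromosomes at
#' 5 kb SNP spacing (~20,000 SNPs), with ten implanted 2-Mb autozygous
#' tracts — five private to one breed at carrier fraction 0.8, three shared
#' by two breeds and two shared by three breeds — plus four decoy tracts at
#' carrier fractions at or below 0.4, which sit below the >50% sharing
#' threshold and must not produce islands. Tracts are 2 Mb (four times the
#' minimum segment length) so that a segment split by a chance cluster of
#' missing calls still leaves both halves callable. Genotyping noise: error
#' rate 0.002, missing rate 0.01.
#'
#' @param seed Integer base seed for the simulation.
#' @return A \code{\link{panel_design}}.
#' @export
demo_design <- function(seed = 20190628) {
  breeds <- stats::setNames(rep(30L, 12), sprintf("breed%02d", 1:12))
  chroms <- stats::setNames(rep(20e6, 5), as.character(1:5))
  tracts <- list(
    # five private tracts
    implant_tract("1", 2.0e6, 4.0e6, c(breed01 = 0.8)),
    implant_tract("1", 7.0e6, 9.0e6, c(breed02 = 0.8)),
    implant_tract("2", 2.0e6, 4.0e6, c(breed03 = 0.8)),
    implant_tract("2", 7.0e6, 9.0e6, c(breed04 = 0.8)),
    implant_tract("3", 2.0e6, 4.0e6, c(breed05 = 0.8)),
    # three tracts shared by two breeds
    implant_tract("3", 7.0e6, 9.0e6, c(breed06 = 0.8, breed07 = 0.8)),
    implant_tract("4", 2.0e6, 4.0e6, c(breed08 = 0.8, breed09 = 0.8)),
    implant_tract("4", 7.0e6, 9.0e6, c(breed10 = 0.8, breed11 = 0.8)),
    # two tracts shared by three breeds
    implant_tract("5", 2.0e6, 4.0e6,
                  c(breed01 = 0.8, breed02 = 0.8, breed03 = 0.8)),
    implant_tract("5", 7.0e6, 9.0e6,
                  c(breed04 = 0.8, breed05 = 0.8, breed06 = 0.8)),
    # four decoys at or below the sharing threshold
    implant_tract("1", 13.0e6, 15.0e6, c(breed07 = 0.4)),
    implant_tract("2", 13.0e6, 15.0e6, c(breed08 = 0.3)),
    implant_tract("3", 13.0e6, 15.0e6, c(breed12 = 0.4)),
    implant_tract("4", 13.0e6, 15.0e6, c(breed12 = 0.3))
  )
  panel_design(breeds = breeds, chrom_lengths_bp = chroms,
               snp_spacing_bp = 5000, tracts = tracts,
               genotype_error_rate = 0.002, missing_rate = 0.01, seed = seed)
}
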