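# Run-of-homozygosity calling.
#
# Segment constraints (all applied to every reported segment):
#   * length_bp = end_bp - start_bp        >= min_length_bp (500 kb)
#   * homozygous SNPs (n - het - missing)  >= min_hom_snps (81, "more than 80")
#   * heterozygotes in segment             <= max_het_in_segment (1)
#   * missing genotypes in segment         <= max_missing_in_segment (2)
#   * mean density length_bp / n_snps      <= min_density_bp_per_snp (50 kb)
#   * every inter-SNP gap inside           <= max_gap_bp (100 kb)
#
# The exact caller is the normative semantics: a greedy left-to-right scan
# emitting maximal runs under the hereditary constraints (gap, het, missing),
# then filtering by the threshold constraints (length, count, density).  The
# windowed caller reproduces the overlapping-window screen of PLINK v1.x and
# hands its candidate runs to the exact machinery, so its output always
# satisfies the same invariants.

#' ROH calling parameters
#'
#' Defaults are the segment constraints used for 670k-array horse data:
#' minimum one SNP per 50 kb, maximum gap 100 kb, minimum segment length
#' 500 kb with more than 80 homozygous SNPs, and at most one heterozygote
#' and two missing genotypes per segment. Window-level fields reproduce
#' PLINK 1.x defaults and only affect \code{\link{call_roh_windowed}}.
#'
#' @param min_length_bp Minimum segment length in bp (end - start).
#' @param min_hom_snps Minimum count of homozygous SNPs in a segment
#'   (81 = "more than 80").
#' @param max_het_in_segment Maximum heterozygotes tolerated per segment.
#' @param max_missing_in_segment Maximum missing genotypes per segment.
#' @param min_density_bp_per_snp Maximum mean bp per SNP inside a segment.
#' @param max_gap_bp Maximum distance between consecutive segment SNPs.
#' @param window_snps Sliding-window size in SNPs.
#' @param window_max_het Maximum heterozygotes for a window to count as a hit.
#' @param window_max_missing Maximum missing calls for a hit window.
#' @param window_hit_threshold Minimum fraction of hit windows covering a SNP
#'   for the SNP to enter a candidate run.
#' @param strict_gt If TRUE, read "greater than 500 kb" literally
#'   (length_bp > min_length_bp); default FALSE uses >= as PLINK's
#'   \code{--homozyg-kb} does.
#' @return An object of class \code{roh_params}.
#' @export
roh_params <- function(min_length_bp = 500000, min_hom_snps = 81,
                       max_het_in_segment = 1, max_missing_in_segment = 2,
                       min_density_bp_per_snp = 50000, max_gap_bp = 100000,
                       window_snps = 50, window_max_het = 1,
                       window_max_missing = 5, window_hit_threshold = 0.05,
                       strict_gt = FALSE) {
  p <- list(min_length_bp = min_length_bp, min_hom_snps = min_hom_snps,
            max_het_in_segment = max_het_in_segment,
            max_missing_in_segment = max_missing_in_segment,
            min_density_bp_per_snp = min_density_bp_per_snp,
            max_gap_bp = max_gap_bp, window_snps = window_snps,
            window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            window_hit_threshold = window_hit_threshold,
            strict_gt = strict_gt)
  num <- unlist(p[setdiff(names(p), "strict_gt")])
  if (any(num < 0)) stop2("ROH parameters must be non-negative")
  if (p$window_hit_threshold <= 0 || p$window_hit_threshold > 1)
    stop2("window_hit_threshold must lie in (0, 1]")
  structure(p, class = "roh_params")
}

#' @export
print.roh_params <- function(x, ...) {
  cat("roh_params: length >=", x$min_length_bp, "bp, hom SNPs >=",
      x$min_hom_snps, ", het <=", x$max_het_in_segment, ", missing <=",
      x$max_missing_in_segment, "\n  density <=", x$min_density_bp_per_snp,
      "bp/SNP, gap <=", x$max_gap_bp, "bp; window", x$window_snps,
      "SNPs (het <=", x$window_max_het, ", missing <=",
      x$window_max_missing, "), hit threshold", x$window_hit_threshold, "\n")
  invisible(x)
}

.check_sorted_map <- function(map) {
  ok <- tapply(map$pos_bp, map$chrom, function(p) !is.unsorted(p, strictly = TRUE))
  if (!all(ok))
    stop2("SNP map must be strictly sorted by position within chromosome")
}

.empty_segments <- function() {
  data.frame(sample_id = character(), chrom = character(),
             start_bp = integer(), end_bp = integer(), n_snps = integer(),
             n_het = integer(), n_missing = integer(), length_bp = integer(),
             stringsAsFactors = FALSE)
}

.segment_row <- function(chrom, pos, het, mis, i, j) {
  n <- j - i + 1L
  data.frame(chrom = chrom, start_bp = pos[i], end_bp = pos[j], n_snps = n,
             n_het = sum(het[i:j]), n_missing = sum(mis[i:j]),
             length_bp = pos[j] - pos[i], stringsAsFactors = FALSE)
}

# Greedy maximal-run scan over one gap-free block of one chromosome.
# het/mis are logical vectors over the block; pos the positions.  Returns a
# data.frame of candidate runs (before threshold filtering).
.scan_block <- function(pos, het, mis, max_het, max_mis) {
  m <- length(pos)
  ch <- cumsum(het); cm <- cumsum(mis)
  hpos <- which(het); mpos <- which(mis)
  runs_i <- integer(0); runs_j <- integer(0)
  s <- 1L
  while (s <= m) {
    h0 <- if (s > 1L) ch[s - 1L] else 0L
    m0 <- if (s > 1L) cm[s - 1L] else 0L
    # last index j with at most max_het hets and max_mis missing in [s..j]:
    # one before the (h0 + max_het + 1)-th het overall, similarly for missing
    nh <- h0 + max_het + 1L
    nm <- m0 + max_mis + 1L
    j <- m
    if (nh <= length(hpos)) j <- min(j, hpos[nh] - 1L)
    if (nm <= length(mpos)) j <- min(j, mpos[nm] - 1L)
    if (j < s) { # s itself overflows an allowance of zero
      s <- s + 1L
      next
    }
    runs_i <- c(runs_i, s); runs_j <- c(runs_j, j)
    s <- j + 1L
  }
  list(i = runs_i, j = runs_j)
}

.passes_thresholds <- function(pos, het, mis, i, j, params) {
  n <- j - i + 1L
  len <- pos[j] - pos[i]
  nhet <- sum(het[i:j]); nmis <- sum(mis[i:j])
  hom <- n - nhet - nmis
  len_ok <- if (params$strict_gt) len > params$min_length_bp else
    len >= params$min_length_bp
  len_ok && hom >= params$min_hom_snps &&
    (len / n) <= params$min_density_bp_per_snp
}

# Exact caller over one chromosome given positions and genotype codes.
.call_exact_chrom <- function(chrom, pos, g, params) {
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  blocks_end <- c(which(diff(pos) > params$max_gap_bp), length(pos))
  blocks_start <- c(1L, utils::head(blocks_end, -1L) + 1L)
  out <- list()
  for (b in seq_along(blocks_start)) {
    lo <- blocks_start[b]; hi <- blocks_end[b]
    idx <- lo:hi
    runs <- .scan_block(pos[idx], het[idx], mis[idx],
                        params$max_het_in_segment,
                        params$max_missing_in_segment)
    for (r in seq_along(runs$i)) {
      i <- runs$i[r] + lo - 1L; j <- runs$j[r] + lo - 1L
      if (.passes_thresholds(pos, het, mis, i, j, params))
        out[[length(out) + 1L]] <- .segment_row(chrom, pos, het, mis, i, j)
    }
  }
  if (length(out)) do.call(rbind, out) else .empty_segments()[-1]
}

#' Call ROH in one individual with the exact (reference) caller
#'
#' Greedy left-to-right scan for maximal SNP runs respecting the gap,
#' heterozygote and missing allowances, then filtered by the length,
#' homozygous-count and density thresholds. Deterministic; a heterozygote
#' that could close either of two adjacent runs attaches to the left one.
#'
#' @param genotype_row Integer vector of genotypes (0/1/2/NA) in map order.
#' @param snp_map Data frame with \code{chrom} and \code{pos_bp}, sorted by
#'   position within chromosome.
#' @param params A \code{\link{roh_params}}.
#' @return Data frame of segments (chrom, start_bp, end_bp, n_snps, n_het,
#'   n_missing, length_bp).
#' @export
call_roh_exact <- function(genotype_row, snp_map, params = roh_params()) {
  .check_sorted_map(snp_map)
  out <- lapply(unique(snp_map$chrom), function(ch) {
    sel <- snp_map$chrom == ch
    .call_exact_chrom(ch, snp_map$pos_bp[sel], genotype_row[sel], params)
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (length(out)) do.call(rbind, out) else .empty_segments()[-1]
}

#' Call ROH in one individual with the overlapping-window screen
#'
#' Reproduces the PLINK 1.x sliding-window approach: every window of
#' \code{window_snps} consecutive SNPs containing at most
#' \code{window_max_het} heterozygotes and \code{window_max_missing} missing
#' calls is a hit; each SNP's hit proportion is taken over all windows
#' covering it, and SNPs at or above \code{window_hit_threshold} form
#' candidate runs, which are then trimmed, split and filtered by the exact
#' caller's segment machinery. A chromosome with fewer SNPs than one window
#' falls back to the exact caller.
#'
#' @inheritParams call_roh_exact
#' @return Data frame of segments, same columns as
#'   \code{\link{call_roh_exact}}; every row satisfies all segment
#'   constraints.
#' @export
call_roh_windowed <- function(genotype_row, snp_map, params = roh_params()) {
  .check_sorted_map(snp_map)
  w <- params$window_snps
  out <- lapply(unique(snp_map$chrom), function(ch) {
    sel <- snp_map$chrom == ch
    pos <- snp_map$pos_bp[sel]; g <- genotype_row[sel]
    m <- length(pos)
    if (m < w) return(.call_exact_chrom(ch, pos, g, params))
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    # rolling window sums over all m - w + 1 windows
    csh <- c(0L, cumsum(het)); csm <- c(0L, cumsum(mis))
    nw <- m - w + 1L
    wh <- csh[(w + 1L):(m + 1L)] - csh[1:nw]
    wm <- csm[(w + 1L):(m + 1L)] - csm[1:nw]
    hit <- as.integer(wh <= params$window_max_het &
                      wm <= params$window_max_missing)
    # SNP i is covered by windows starting in [max(1, i-w+1), min(i, nw)]
    csh2 <- c(0L, cumsum(hit))
    lo <- pmax(1L, seq_len(m) - w + 1L)
    hi <- pmin(seq_len(m), nw)
    n_cover <- hi - lo + 1L
    n_hit <- csh2[hi + 1L] - csh2[lo]
    cand <- (n_hit / n_cover) >= params$window_hit_threshold
    if (!any(cand)) return(.empty_segments()[-1])
    # maximal runs of candidate SNPs -> exact segment calling inside each
    r <- rle(cand)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    segs <- list()
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      s <- .call_exact_chrom(ch, pos[idx], g[idx], params)
      if (nrow(s)) segs[[length(segs) + 1L]] <- s
    }
    if (length(segs)) do.call(rbind, segs) else .empty_segments()[-1]
  })
  out <- out[vapply(out, nrow, 1L) > 0]
  if (length(out)) do.call(rbind, out) else .empty_segments()[-1]
}

#' Call ROH for every individual in a panel
#'
#' @param panel A \code{\link{genotype_panel}} (map must be sorted by
#'   position within chromosome).
#' @param params A \code{\link{roh_params}}.
#' @param method \code{"windowed"} (default, PLINK-style screen) or
#'   \code{"exact"}.
#' @return Data frame of segments with columns sample_id, breed, chrom,
#'   start_bp, end_bp, n_snps, n_het, n_missing, length_bp.
#' @export
call_roh <- function(panel, params = roh_params(),
                     method = c("windowed", "exact")) {
  stopifnot(inherits(panel, "genotype_panel"))
  method <- match.arg(method)
  fn <- if (method == "windowed") call_roh_windowed else call_roh_exact
  .check_sorted_map(panel$map)
  out <- lapply(seq_along(panel$samples), function(i) {
    s <- fn(panel$genotypes[i, ], panel$map, params)
    if (!nrow(s)) return(NULL)
    cbind(data.frame(sample_id = panel$samples[i],
                     breed = unname(panel$breed_of[[panel$samples[i]]]),
                     stringsAsFactors = FALSE), s)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out)) do.call(rbind, out) else .empty_segments()
}

#' Independently re-validate called segments against the segment constraints
#'
#' Post-hoc check used by the test-suite and available to users: re-derives
#' every constraint from the raw genotypes rather than trusting the caller's
#' bookkeeping.
#'
#' @param segments Data frame of segments with at least sample_id, chrom,
#'   start_bp, end_bp.
#' @param panel The \code{\link{genotype_panel}} the segments were called on.
#' @param params A \code{\link{roh_params}}.
#' @return Logical vector, one entry per segment row; TRUE if the segment
#'   satisfies every constraint.
#' @export
validate_segments <- function(segments, panel, params = roh_params()) {
  if (!nrow(segments)) return(logical(0))
  vapply(seq_len(nrow(segments)), function(k) {
    seg <- segments[k, ]
    sel <- which(panel$map$chrom == seg$chrom &
                 panel$map$pos_bp >= seg$start_bp &
                 panel$map$pos_bp <= seg$end_bp)
    if (!length(sel)) return(FALSE)
    g <- panel$genotypes[seg$sample_id, sel]
    pos <- panel$map$pos_bp[sel]
    nhet <- sum(!is.na(g) & g == 1L)
    nmis <- sum(is.na(g))
    n <- length(sel)
    len <- pos[n] - pos[1]
    len_ok <- if (params$strict_gt) len > params$min_length_bp else
      len >= params$min_length_bp
    len_ok &&
      (n - nhet - nmis) >= params$min_hom_snps &&
      nhet <= params$max_het_in_segment &&
      nmis <= params$max_missing_in_segment &&
      (len / n) <= params$min_density_bp_per_snp &&
      (n == 1L || max(diff(pos)) <= params$max_gap_bp)
  }, logical(1))
}

#' Genome length covered by ROH, per sample and per breed
#'
#' Sums segment lengths per individual (in Mb, bp / 1e6) and averages over
#' all sampled individuals of each breed — including individuals with no
#' segments, which contribute 0 to the mean.
#'
#' @param segments Segment data frame from \code{\link{call_roh}}.
#' @param panel The \code{\link{genotype_panel}} (supplies the full sample
#'   and breed lists).
#' @return An object of class \code{sroh_summary}: list with
#'   \code{per_sample} (sample_id, breed, sroh_mb) and \code{per_breed}
#'   (breed, n, mean_sroh_mb).
#' @export
sroh <- function(segments, panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (nrow(segments)) {
    bad <- setdiff(unique(segments$sample_id), panel$samples)
    if (length(bad))
      stop2("segments for samples without breed label: ",
            paste(bad, collapse = ", "))
  }
  per_sample <- data.frame(sample_id = panel$samples,
                           breed = unname(panel$breed_of),
                           sroh_mb = 0, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    sums <- tapply(segments$length_bp, segments$sample_id, sum) / 1e6
    per_sample$sroh_mb[match(names(sums), per_sample$sample_id)] <- sums
  }
  means <- tapply(per_sample$sroh_mb, per_sample$breed, mean)
  ns <- tapply(per_sample$sroh_mb, per_sample$breed, length)
  ord <- unique(per_sample$breed)
  per_breed <- data.frame(breed = ord, n = as.integer(ns[ord]),
                          mean_sroh_mb = as.numeric(means[ord]),
                          stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample, per_breed = per_breed),
            class = "sroh_summary")
}

#' @export
print.sroh_summary <- function(x, ...) {
  cat("S_ROH per breed (Mb):\n")
  print(x$per_breed, row.names = FALSE)
  invisible(x)
}
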