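# ROH-island detection and cross-breed overlap analysis.
#
# An island is a maximal map-contiguous run of SNPs whose incidence — the
# fraction of ALL genotyped individuals of a breed whose ROH covers the SNP —
# is strictly greater than the sharing threshold (default 0.5, "more than
# 50%").  Islands are runs over map order and are not split at physical
# gaps: gap control already happened at segment calling.

#' Per-SNP ROH incidence track for one breed
#'
#' For every SNP, the fraction of the breed's individuals with an ROH
#' segment covering it. Each individual contributes at most 1 per SNP even
#' if handed overlapping segments; the denominator is the full breed sample
#' size, not just ROH carriers.
#'
#' @param segments Segment data frame (needs sample_id, chrom, start_bp,
#'   end_bp), called on the same SNP map as \code{panel}.
#' @param panel A \code{\link{genotype_panel}}.
#' @param breed Breed label with at least one sample in the panel.
#' @return An object of class \code{incidence_track}: data frame with
#'   columns snp_id, chrom, pos_bp, n_covered, incidence, plus attributes
#'   \code{breed} and \code{n_breed}.
#' @export
incidence_track <- function(segments, panel, breed) {
  stopifnot(inherits(panel, "genotype_panel"))
  members <- panel$samples[panel$breed_of == breed]
  if (!length(members)) stop2("breed has no samples in panel: ", breed)
  n_b <- length(members)
  covered <- integer(nrow(panel$map))
  segs <- segments[segments$sample_id %in% members, , drop = FALSE]
  if (nrow(segs)) {
    for (id in unique(segs$sample_id)) {
      own <- segs[segs$sample_id == id, , drop = FALSE]
      hit <- logical(nrow(panel$map))
      for (k in seq_len(nrow(own)))
        hit <- hit | (panel$map$chrom == own$chrom[k] &
                      panel$map$pos_bp >= own$start_bp[k] &
                      panel$map$pos_bp <= own$end_bp[k])
      covered <- covered + hit
    }
  }
  out <- data.frame(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                    pos_bp = panel$map$pos_bp, n_covered = covered,
                    incidence = covered / n_b, stringsAsFactors = FALSE)
  attr(out, "breed") <- breed
  attr(out, "n_breed") <- n_b
  class(out) <- c("incidence_track", "data.frame")
  out
}

#' Call ROH islands from an incidence track
#'
#' Maximal map-contiguous runs of SNPs with incidence strictly greater than
#' the threshold. Island coordinates are the positions of the run's first
#' and last SNP; runs are not broken by physical gaps. A SNP at exactly the
#' threshold never enters an island ("more than 50%" is strict).
#'
#' @param track An \code{\link{incidence_track}}.
#' @param threshold Sharing threshold (default 0.5).
#' @return Data frame of islands: breed, chrom, start_bp, end_bp, n_snps,
#'   peak_incidence, length_bp, single_snp flag.
#' @export
call_islands <- function(track, threshold = 0.5) {
  if (threshold < 0 || threshold >= 1) stop2("threshold must lie in [0, 1)")
  breed <- attr(track, "breed")
  out <- list()
  for (ch in unique(track$chrom)) {
    t_ch <- track[track$chrom == ch, , drop = FALSE]
    over <- t_ch$incidence > threshold
    if (!any(over)) next
    r <- rle(over)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        breed = breed, chrom = ch,
        start_bp = t_ch$pos_bp[starts[k]], end_bp = t_ch$pos_bp[ends[k]],
        n_snps = length(idx),
        peak_incidence = max(t_ch$incidence[idx]),
        length_bp = t_ch$pos_bp[ends[k]] - t_ch$pos_bp[starts[k]],
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(breed = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(), n_snps = integer(),
               peak_incidence = numeric(), length_bp = integer(),
               stringsAsFactors = FALSE)
  tab$single_snp <- tab$n_snps == 1L
  tab
}

#' Call islands for every breed in a panel
#'
#' @param segments Segment data frame from \code{\link{call_roh}}.
#' @param panel A \code{\link{genotype_panel}}.
#' @param threshold Sharing threshold (default 0.5, strict).
#' @return Data frame of islands over all breeds, with an \code{island_id}
#'   column.
#' @export
call_islands_all <- function(segments, panel, threshold = 0.5) {
  out <- lapply(panel_breeds(panel), function(b)
    call_islands(incidence_track(segments, panel, b), threshold))
  tab <- do.call(rbind, out)
  if (nrow(tab))
    tab$island_id <- sprintf("%s:chr%s:%d-%d", tab$breed, tab$chrom,
                             tab$start_bp, tab$end_bp)
  else tab$island_id <- character(0)
  tab
}

#' Cross-breed overlap regions of ROH islands
#'
#' Builds, per chromosome, the interval-overlap graph whose edges join
#' islands of DIFFERENT breeds sharing at least 1 bp (closed intervals;
#' abutting intervals with zero shared positions are not joined). Same-breed
#' islands are never joined directly but can land in one component through a
#' third breed. Connected components spanning at least two breeds become
#' overlap regions; no minimum overlap length is applied.
#'
#' @param islands Island data frame from \code{\link{call_islands_all}}.
#' @return List with \code{regions} (data frame: region_id, chrom, start_bp,
#'   end_bp union extent, isect_start_bp, isect_end_bp intersection-style
#'   bounds of the pairwise overlaps, n_breeds, breeds) and
#'   \code{membership} (island_id -> region_id map).
#' @export
cross_breed_overlaps <- function(islands) {
  empty <- list(regions = data.frame(region_id = character(),
                                     chrom = character(), start_bp = integer(),
                                     end_bp = integer(),
                                     isect_start_bp = integer(),
                                     isect_end_bp = integer(),
                                     n_breeds = integer(), breeds = character(),
                                     stringsAsFactors = FALSE),
                membership = data.frame(island_id = character(),
                                        region_id = character(),
                                        stringsAsFactors = FALSE))
  if (!nrow(islands)) return(empty)
  n <- nrow(islands)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(islands$chrom)) {
    idx <- which(islands$chrom == ch)
    if (length(idx) < 2) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (islands$breed[i] == islands$breed[j]) next
        if (intervals_overlap(islands$start_bp[i], islands$end_bp[i],
                              islands$start_bp[j], islands$end_bp[j]))
          parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  regions <- list(); membership <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    breeds <- unique(islands$breed[members])
    if (length(breeds) < 2) next
    ch <- islands$chrom[members[1]]
    # intersection-style bounds: envelope of the pairwise shared spans
    isect_s <- NA_integer_; isect_e <- NA_integer_
    for (a in seq_along(members)[-length(members)]) {
      for (b in (a + 1):length(members)) {
        i <- members[a]; j <- members[b]
        if (islands$breed[i] == islands$breed[j]) next
        s <- max(islands$start_bp[i], islands$start_bp[j])
        e <- min(islands$end_bp[i], islands$end_bp[j])
        if (s <= e) {
          isect_s <- min(isect_s, s, na.rm = TRUE)
          isect_e <- max(isect_e, e, na.rm = TRUE)
        }
      }
    }
    rid <- sprintf("chr%s:%d-%d", ch, min(islands$start_bp[members]),
                   max(islands$end_bp[members]))
    regions[[length(regions) + 1L]] <- data.frame(
      region_id = rid, chrom = ch,
      start_bp = min(islands$start_bp[members]),
      end_bp = max(islands$end_bp[members]),
      isect_start_bp = isect_s, isect_end_bp = isect_e,
      n_breeds = length(breeds),
      breeds = paste(sort(breeds), collapse = ","),
      stringsAsFactors = FALSE)
    membership[[length(membership) + 1L]] <- data.frame(
      island_id = islands$island_id[members], region_id = rid,
      stringsAsFactors = FALSE)
  }
  if (!length(regions)) return(empty)
  regions <- do.call(rbind, regions)
  ord <- order(regions$chrom, regions$start_bp)
  list(regions = regions[ord, , drop = FALSE],
       membership = do.call(rbind, membership))
}

#' Classify islands as private or shared
#'
#' An island is private ("breed-specific") iff it belongs to no cross-breed
#' overlap region.
#'
#' @param islands Island data frame from \code{\link{call_islands_all}}.
#' @param overlaps Result of \code{\link{cross_breed_overlaps}} on the same
#'   island set.
#' @return List with \code{islands} (input plus \code{private} flag and
#'   \code{region_id}), \code{per_breed} (breed, n_islands, n_private,
#'   private_chroms) and \code{global} (n_total, n_private, n_in_regions,
#'   n_overlap_regions).
#' @export
classify_private <- function(islands, overlaps) {
  membership <- overlaps$membership
  bad <- setdiff(membership$island_id, islands$island_id)
  if (length(bad))
    stop2("overlap regions reference unknown islands: ",
          paste(bad, collapse = ", "))
  islands$region_id <- membership$region_id[match(islands$island_id,
                                                  membership$island_id)]
  islands$private <- is.na(islands$region_id)
  per_breed <- do.call(rbind, lapply(unique(islands$breed), function(b) {
    sub <- islands[islands$breed == b, , drop = FALSE]
    priv <- sub[sub$private, , drop = FALSE]
    data.frame(breed = b, n_islands = nrow(sub), n_private = nrow(priv),
               private_chroms = paste(unique(priv$chrom[order(
                 suppressWarnings(as.numeric(priv$chrom)), priv$chrom)]),
                 collapse = ","),
               stringsAsFactors = FALSE)
  }))
  global <- list(n_total = nrow(islands), n_private = sum(islands$private),
                 n_in_regions = sum(!islands$private),
                 n_overlap_regions = nrow(overlaps$regions))
  if (global$n_private + global$n_in_regions != global$n_total)
    stop2("island classification does not conserve counts")
  list(islands = islands, per_breed = per_breed, global = global)
}

#' Per-breed summary table of S_ROH and islands
#'
#' One row per breed: mean S_ROH (Mb), summed island length (Mb), island
#' count, private-island count and the chromosomes carrying private islands.
#'
#' @param islands Island data frame with \code{private} flag (from
#'   \code{\link{classify_private}}) or without (all treated as
#'   unclassified).
#' @param sroh_summary An \code{\link{sroh}} result.
#' @return Data frame, one row per breed.
#' @export
summarize_breeds <- function(islands, sroh_summary) {
  stopifnot(inherits(sroh_summary, "sroh_summary"))
  breeds <- sroh_summary$per_breed$breed
  do.call(rbind, lapply(breeds, function(b) {
    sub <- islands[islands$breed == b, , drop = FALSE]
    priv <- if ("private" %in% names(sub)) sub[sub$private, , drop = FALSE]
            else sub[0, , drop = FALSE]
    data.frame(
      breed = b,
      mean_sroh_mb = sroh_summary$per_breed$mean_sroh_mb[
        sroh_summary$per_breed$breed == b],
      sum_islands_mb = sum(sub$length_bp) / 1e6,
      n_islands = nrow(sub),
      n_private = nrow(priv),
      private_chroms = paste(unique(priv$chrom), collapse = ","),
      stringsAsFactors = FALSE)
  }))
}

#' Export islands or regions as BED
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention: \code{bed_start = start_bp - 1},
#' \code{bed_end = end_bp}.
#'
#' @param intervals Data frame with chrom, start_bp, end_bp and optionally
#'   breed / region_id used as the name column.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed_intervals <- function(intervals, path) {
  name <- intervals$island_id %||% intervals$region_id %||%
    intervals$breed %||% rep(".", nrow(intervals))
  bed <- data.frame(chrom = intervals$chrom,
                    start = intervals$start_bp - 1L,
                    end = intervals$end_bp,
                    name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
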