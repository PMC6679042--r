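# Incidence tracks, island calling, cross-breed overlaps, private islands.

# helper: segment row
seg <- function(id, chrom, s, e, breed = "P") {
  data.frame(sample_id = id, breed = breed, chrom = chrom, start_bp = s,
             end_bp = e, n_snps = 0L, n_het = 0L, n_missing = 0L,
             length_bp = e - s, stringsAsFactors = FALSE)
}

# helper: island row in the call_islands_all shape
isl <- function(breed, chrom, s, e) {
  data.frame(breed = breed, chrom = chrom, start_bp = s, end_bp = e,
             n_snps = 10L, peak_incidence = 0.8, length_bp = e - s,
             single_snp = FALSE,
             island_id = sprintf("%s:chr%s:%d-%d", breed, chrom, s, e),
             stringsAsFactors = FALSE)
}

test_that("incidence counts covering individuals over the full breed size", {
  # breed of 10; 6 individuals with one ROH covering SNPs 100..200
  pos <- spaced_pos(300, by = 5000)
  p <- make_panel(matrix(0L, 10, 300), pos)
  segs <- do.call(rbind, lapply(sprintf("s%02d", 1:6), function(id)
    seg(id, "1", pos[100], pos[200])))
  tr <- incidence_track(segs, p, "P")
  expect_equal(tr$incidence[100:200], rep(0.6, 101))
  expect_equal(tr$incidence[c(1:99, 201:300)], rep(0, 199))
})

test_that("no segments gives an all-zero track; empty breed errors", {
  p <- make_panel(matrix(0L, 4, 10), spaced_pos(10, by = 1000))
  tr <- incidence_track(seg("s01", "1", 1, 2)[0, ], p, "P")
  expect_true(all(tr$incidence == 0))
  expect_error(incidence_track(seg("s01", "1", 1, 2)[0, ], p, "Q"),
               "no samples")
})

test_that("overlapping segments of one individual count once, matching brute force", {
  pos <- spaced_pos(50, by = 10000)
  p <- make_panel(matrix(0L, 5, 50), pos)
  segs <- rbind(seg("s01", "1", pos[10], pos[30]),
                seg("s01", "1", pos[20], pos[40]),  # overlaps the first
                seg("s02", "1", pos[15], pos[25]))
  tr <- incidence_track(segs, p, "P")
  expect_equal(max(tr$n_covered), 2)            # never 3 from s01 double-count
  expect_equal(tr$incidence, incidence_oracle(segs, p, "P"))
})

test_that("islands are maximal supra-threshold runs with strict > 0.5", {
  pos <- spaced_pos(300, by = 5000)
  p <- make_panel(matrix(0L, 10, 300), pos)
  # 6/10 over SNPs 100..200 -> island; exactly 5/10 elsewhere -> none
  segs6 <- do.call(rbind, lapply(sprintf("s%02d", 1:6), function(id)
    seg(id, "1", pos[100], pos[200])))
  tr <- incidence_track(segs6, p, "P")
  islands <- call_islands(tr)
  expect_equal(nrow(islands), 1)
  expect_equal(islands$start_bp, pos[100])
  expect_equal(islands$end_bp, pos[200])
  expect_equal(islands$n_snps, 101)
  segs5 <- do.call(rbind, lapply(sprintf("s%02d", 1:5), function(id)
    seg(id, "1", pos[100], pos[200])))
  expect_equal(nrow(call_islands(incidence_track(segs5, p, "P"))), 0)
})

test_that("threshold strictness at n in {4, 10, 20} via simulated carriers", {
  for (n in c(4L, 10L, 20L)) {
    half <- n / 2L
    for (extra in 0:1) {
      d <- panel_design(breeds = stats::setNames(n, "B"),
                        chrom_lengths_bp = c("1" = 5e6), snp_spacing_bp = 5000,
                        tracts = list(implant_tract("1", 2e6, 3e6,
                                                    stats::setNames((half + extra) / n, "B"))),
                        seed = 1000 + n)
      sim <- simulate_panel(d)
      segs <- call_roh(sim$panel, method = "windowed")
      islands <- call_islands(incidence_track(segs, sim$panel, "B"))
      if (extra == 0) {
        expect_equal(nrow(islands), 0, info = paste("n =", n))
      } else {
        expect_equal(nrow(islands), 1, info = paste("n =", n))
        gap <- max(diff(sim$panel$map$pos_bp))
        expect_lte(abs(islands$start_bp - 2e6), gap)
        expect_lte(abs(islands$end_bp - 3e6), gap)
      }
    }
  }
})

test_that("cross-breed overlap joins islands sharing at least 1 bp", {
  islands <- rbind(isl("A", "1", 148400000L, 148600000L),
                   isl("B", "1", 148440000L, 148520000L))
  ov <- cross_breed_overlaps(islands)
  expect_equal(nrow(ov$regions), 1)
  expect_equal(ov$regions$start_bp, 148400000L)   # union extent
  expect_equal(ov$regions$end_bp, 148600000L)
  expect_equal(ov$regions$isect_start_bp, 148440000L)
  expect_equal(ov$regions$isect_end_bp, 148520000L)
  expect_equal(ov$regions$breeds, "A,B")
})

test_that("abutting islands (end x, start x+1) do not overlap", {
  islands <- rbind(isl("A", "1", 100L, 200L), isl("B", "1", 201L, 300L))
  expect_equal(nrow(cross_breed_overlaps(islands)$regions), 0)
  # sharing a single position does overlap
  islands2 <- rbind(isl("A", "1", 100L, 200L), isl("B", "1", 200L, 300L))
  expect_equal(nrow(cross_breed_overlaps(islands2)$regions), 1)
})

test_that("transitive overlap chains collapse into one region", {
  # A-B overlap, B-C overlap, A-C disjoint -> single {A,B,C} region
  islands <- rbind(isl("A", "2", 100L, 200L),
                   isl("B", "2", 150L, 320L),
                   isl("C", "2", 300L, 400L))
  ov <- cross_breed_overlaps(islands)
  expect_equal(nrow(ov$regions), 1)
  expect_equal(ov$regions$breeds, "A,B,C")
  expect_equal(ov$regions$start_bp, 100L)
  expect_equal(ov$regions$end_bp, 400L)
  # matches the exhaustive BFS oracle
  comp <- overlap_components_oracle(islands)
  expect_equal(length(unique(comp)), 1)
})

test_that("same-breed islands never join directly", {
  islands <- rbind(isl("A", "1", 100L, 200L), isl("A", "1", 150L, 250L))
  expect_equal(nrow(cross_breed_overlaps(islands)$regions), 0)
})

test_that("random instances match the component oracle and conserve counts", {
  set.seed(42)
  for (rep in 1:30) {
    k <- sample(2:14, 1)
    islands <- do.call(rbind, lapply(seq_len(k), function(i) {
      s <- sample.int(1000, 1)
      isl(sample(LETTERS[1:4], 1), sample(c("1", "2"), 1), s,
          s + sample.int(300, 1))
    }))
    islands$island_id <- sprintf("i%02d", seq_len(k)) # force uniqueness
    ov <- cross_breed_overlaps(islands)
    cls <- classify_private(islands, ov)
    expect_equal(cls$global$n_private + cls$global$n_in_regions,
                 cls$global$n_total)
    # oracle: islands are non-private iff their BFS component holds >= 2 breeds
    comp <- overlap_components_oracle(islands)
    shared_oracle <- vapply(seq_len(k), function(i) {
      members <- which(comp == comp[i])
      length(unique(islands$breed[members])) >= 2
    }, logical(1))
    expect_equal(!cls$islands$private, shared_oracle)
    expect_equal(cls$global$n_overlap_regions,
                 length(unique(comp[shared_oracle])))
  }
})

test_that("island calling is invariant to sample and breed order", {
  d <- panel_design(breeds = c(A = 10, B = 8), chrom_lengths_bp = c("1" = 5e6),
                    snp_spacing_bp = 5000,
                    tracts = list(implant_tract("1", 2e6, 3e6, c(A = 0.7, B = 0.75))),
                    seed = 55)
  sim <- simulate_panel(d)
  segs <- call_roh(sim$panel, method = "windowed")
  islands <- call_islands_all(segs, sim$panel)
  # shuffle samples and segment rows
  set.seed(1)
  perm <- sample(length(sim$panel$samples))
  p2 <- subset_panel(sim$panel, samples = perm)
  segs2 <- segs[sample(nrow(segs)), ]
  islands2 <- call_islands_all(segs2, p2)
  key <- function(x) x[order(x$breed, x$chrom, x$start_bp),
                       c("breed", "chrom", "start_bp", "end_bp", "n_snps")]
  expect_equal(key(islands2), key(islands), ignore_attr = TRUE)
})

test_that("classify_private flags integrity violations", {
  islands <- isl("A", "1", 100L, 200L)
  ov <- list(regions = data.frame(region_id = "r1", chrom = "1",
                                  start_bp = 1L, end_bp = 2L,
                                  isect_start_bp = 1L, isect_end_bp = 2L,
                                  n_breeds = 2L, breeds = "A,B"),
             membership = data.frame(island_id = "ghost", region_id = "r1"))
  expect_error(classify_private(islands, ov), "unknown islands")
})

test_that("breed summary reports island totals consistent with classification", {
  islands <- rbind(isl("A", "1", 1000000L, 1600000L),
                   isl("A", "2", 1000000L, 2400000L),
                   isl("B", "1", 1500000L, 1700000L))
  ov <- cross_breed_overlaps(islands)
  cls <- classify_private(islands, ov)
  p <- make_panel(matrix(0L, 2, 2), c(1e6, 2e6), breeds = c("A", "B"))
  no_segs <- data.frame(sample_id = character(), breed = character(),
                        chrom = character(), start_bp = integer(),
                        end_bp = integer(), n_snps = integer(),
                        n_het = integer(), n_missing = integer(),
                        length_bp = integer())
  s <- sroh(no_segs, p)
  tab <- summarize_breeds(cls$islands, s)
  expect_equal(tab$n_islands[tab$breed == "A"], 2)
  expect_equal(tab$sum_islands_mb[tab$breed == "A"], 2.0)
  expect_equal(tab$n_private[tab$breed == "A"], 1)   # chr2 island is private
  expect_equal(tab$private_chroms[tab$breed == "A"], "2")
  expect_equal(sum(tab$n_islands), cls$global$n_total)
})
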