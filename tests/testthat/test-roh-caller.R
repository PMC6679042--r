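# ROH calling: exact reference caller, windowed screen, S_ROH.

test_that("a clean homozygous run is called as one segment", {
  # 200 homozygous SNPs every 5 kb: span 995 kb, all constraints pass
  pos <- spaced_pos(200, from = 1e6, by = 5000)
  segs <- call_roh_exact(rep(2L, 200), make_map(pos))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 200)
  expect_equal(segs$length_bp, 995000)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[200])
  expect_equal(segs$n_het, 0)
})

test_that("an all-heterozygous chromosome yields no segments", {
  pos <- spaced_pos(200, by = 5000)
  expect_equal(nrow(call_roh_exact(rep(1L, 200), make_map(pos))), 0)
  expect_equal(nrow(call_roh_windowed(rep(1L, 200), make_map(pos))), 0)
})

test_that("a 150 kb gap splits the run and both halves are rejected", {
  pos <- c(spaced_pos(100, from = 1e6, by = 5000),
           spaced_pos(100, from = 1e6 + 99 * 5000 + 150000, by = 5000))
  segs <- call_roh_exact(rep(2L, 200), make_map(pos))
  expect_equal(nrow(segs), 0)
})

test_that("each segment constraint accepts/rejects exactly at its boundary", {
  for (case in roh_boundary_cases()) {
    segs <- call_roh_exact(case$geno, make_map(case$pos))
    segs_w <- call_roh_windowed(case$geno, make_map(case$pos))
    if (case$accept) {
      expect_equal(nrow(segs), 1, info = case$name)
      expect_equal(segs$n_snps, length(case$geno), info = case$name)
      expect_equal(segs$start_bp, case$pos[1], info = case$name)
      expect_equal(segs$end_bp, case$pos[length(case$pos)], info = case$name)
    } else {
      expect_equal(nrow(segs), 0, info = case$name)
    }
    # the windowed screen must agree on these benign geometries
    expect_equal(nrow(segs_w), nrow(segs), info = case$name)
  }
})

test_that("strict_gt dialect excludes runs at exactly the minimum length", {
  pos <- spaced_pos(81, span = 500000)
  map <- make_map(pos)
  expect_equal(nrow(call_roh_exact(rep(2L, 81), map)), 1)
  expect_equal(nrow(call_roh_exact(rep(2L, 81), map,
                                   roh_params(strict_gt = TRUE))), 0)
})

test_that("windowed caller equals exact caller on benign inputs", {
  # all-homozygous 1 Mb chromosome of 201 SNPs
  pos <- spaced_pos(201, from = 1e6, by = 5000)
  map <- make_map(pos)
  g <- rep(2L, 201)
  expect_equal(call_roh_windowed(g, map), call_roh_exact(g, map))
  # single isolated heterozygote
  g[100] <- 1L
  expect_equal(call_roh_windowed(g, map), call_roh_exact(g, map))
})

test_that("chromosomes shorter than one window fall back to the exact caller", {
  pos <- spaced_pos(30, span = 600000) # 30 SNPs < window of 50
  map <- make_map(pos)
  g <- rep(0L, 30)
  expect_equal(call_roh_windowed(g, map), call_roh_exact(g, map))
})

test_that("an unsorted map is a precondition error", {
  map <- make_map(c(3e6, 1e6, 2e6))
  expect_error(call_roh_exact(rep(2L, 3), map), "sorted")
})

test_that("every windowed segment passes the independent validator", {
  set.seed(301)
  for (rep in 1:40) {
    m <- sample(100:1200, 1)
    het_rate <- runif(1, 0, 0.3)
    g <- ifelse(runif(m) < het_rate, 1L, 2L)
    g[runif(m) < 0.02] <- NA
    pos <- sort(sample.int(m * 8000, m))
    panel <- make_panel(matrix(g, 1), pos)
    segs <- call_roh(panel, method = "windowed")
    if (nrow(segs)) expect_true(all(validate_segments(segs, panel)))
    segs_e <- call_roh(panel, method = "exact")
    if (nrow(segs_e)) expect_true(all(validate_segments(segs_e, panel)))
  }
})

test_that("segments never overlap within an individual", {
  set.seed(302)
  for (rep in 1:20) {
    m <- 800
    g <- ifelse(runif(m) < 0.05, 1L, 2L)
    pos <- sort(sample.int(6e6, m))
    segs <- call_roh_exact(g, make_map(pos))
    if (nrow(segs) > 1) {
      segs <- segs[order(segs$start_bp), ]
      expect_true(all(diff(segs$start_bp) > 0))
      expect_true(all(utils::head(segs$end_bp, -1) < utils::tail(segs$start_bp, -1)))
    }
  }
})

test_that("raising the length threshold never adds segments", {
  set.seed(303)
  for (rep in 1:10) {
    m <- 600
    g <- ifelse(runif(m) < 0.03, 1L, 0L)
    pos <- sort(sample.int(5e6, m))
    map <- make_map(pos)
    base <- call_roh_exact(g, map, roh_params(min_length_bp = 400000))
    strict <- call_roh_exact(g, map, roh_params(min_length_bp = 700000))
    expect_lte(nrow(strict), nrow(base))
    if (nrow(strict))
      expect_true(all(strict$length_bp >= 700000))
  }
})

test_that("tightening the heterozygote allowance never lengthens total S_ROH", {
  set.seed(304)
  for (rep in 1:10) {
    m <- 800
    g <- ifelse(runif(m) < 0.04, 1L, 2L)
    pos <- sort(sample.int(6e6, m))
    map <- make_map(pos)
    loose <- call_roh_exact(g, map, roh_params(max_het_in_segment = 1))
    tight <- call_roh_exact(g, map, roh_params(max_het_in_segment = 0))
    expect_lte(sum(tight$length_bp), sum(loose$length_bp))
  }
})

test_that("implanted tracts are recovered in every carrier without noise", {
  d <- panel_design(breeds = c(A = 12), chrom_lengths_bp = c("1" = 5e6),
                    snp_spacing_bp = 5000,
                    tracts = list(implant_tract("1", 2e6, 3e6, c(A = 0.75))),
                    seed = 88)
  sim <- simulate_panel(d)
  segs <- call_roh(sim$panel, method = "windowed")
  tr <- sim$truth$tracts[[1]]
  gaps <- diff(sim$panel$map$pos_bp)
  max_gap <- max(gaps)
  for (id in tr$carriers$A) {
    own <- segs[segs$sample_id == id, , drop = FALSE]
    covering <- own[own$start_bp <= tr$spec$start_bp + max_gap &
                    own$end_bp >= tr$spec$end_bp - max_gap, , drop = FALSE]
    expect_gte(nrow(covering), 1)
  }
})

test_that("S_ROH sums per sample and averages per breed over everyone", {
  p <- make_panel(matrix(0L, 2, 2), c(1e6, 2e6), breeds = c("B1", "B1"))
  segs <- data.frame(sample_id = "s01", breed = "B1", chrom = "1",
                     start_bp = 1e6, end_bp = 2e6, n_snps = 100L, n_het = 0L,
                     n_missing = 0L,
                     length_bp = c(600000, 1400000))
  segs$sample_id <- "s01"
  s <- sroh(segs, p)
  expect_equal(s$per_sample$sroh_mb[s$per_sample$sample_id == "s01"], 2.0)
  # sample with no segments contributes 0 to the mean denominator
  expect_equal(s$per_sample$sroh_mb[s$per_sample$sample_id == "s02"], 0.0)
  expect_equal(s$per_breed$mean_sroh_mb, 1.0)
  expect_equal(s$per_breed$n, 2L)
})

test_that("segments for unlabeled samples raise an error in sroh", {
  p <- make_panel(matrix(0L, 1, 2), c(1e6, 2e6))
  segs <- data.frame(sample_id = "ghost", breed = "P", chrom = "1",
                     start_bp = 1e6, end_bp = 2e6, n_snps = 10L, n_het = 0L,
                     n_missing = 0L, length_bp = 1e6)
  expect_error(sroh(segs, p), "without breed label")
})
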