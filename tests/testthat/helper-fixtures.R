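# Fixture builders and independent oracles used across test files.

# A one-chromosome panel from an explicit genotype matrix and positions.
make_panel <- function(geno, pos, chrom = "1", breeds = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  samples <- sprintf("s%02d", seq_len(n))
  if (is.null(breeds)) breeds <- rep("P", n)
  map <- data.frame(snp_id = sprintf("snp%04d", seq_along(pos)),
                    chrom = rep(chrom, length.out = length(pos)),
                    pos_bp = as.integer(pos),
                    allele1 = rep("A", length(pos)),
                    allele2 = rep("B", length(pos)), stringsAsFactors = FALSE)
  genotype_panel(geno, map, samples, stats::setNames(breeds, samples))
}

make_map <- function(pos, chrom = "1") {
  data.frame(snp_id = sprintf("snp%04d", seq_along(pos)),
             chrom = rep(chrom, length.out = length(pos)),
             pos_bp = as.integer(pos), allele1 = "A", allele2 = "B",
             stringsAsFactors = FALSE)
}

random_panel <- function(n = 5, m = 20, miss = 0.1) {
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  g[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  pos <- sort(sample.int(1e6, m))
  make_panel(g, pos, breeds = sample(c("X", "Y2"), n, replace = TRUE))
}

# --- HWE oracle: Wigginton-style ratio recurrence, an independent route ----
# Starts from the maximal attainable heterozygote count and walks down two at
# a time using the exact probability ratio
#   P(h-2) / P(h) = h (h - 1) / (4 * homr(h-2) * homc(h-2))
hwe_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  rare <- min(2 * n0 + n1, 2 * n2 + n1)
  hets <- seq.int(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  names(probs) <- hets
  h_max <- hets[length(hets)]
  probs[length(probs)] <- 1
  if (length(hets) > 1) {
    for (k in rev(seq_along(hets))[-1]) {
      h <- hets[k + 1]
      homr <- (rare - (h - 2)) / 2
      homc <- n - (h - 2) - homr
      probs[k] <- probs[k + 1] * h * (h - 1) / (4 * homr * homc)
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(n1)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# --- connected-components oracle: exhaustive pair enumeration + BFS --------
overlap_components_oracle <- function(islands) {
  n <- nrow(islands)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (islands$chrom[i] != islands$chrom[j]) next
    if (islands$breed[i] == islands$breed[j]) next
    if (max(islands$start_bp[i], islands$start_bp[j]) <=
        min(islands$end_bp[i], islands$end_bp[j])) adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Brute-force per-SNP incidence: stab every (individual, SNP) pair directly.
incidence_oracle <- function(segments, panel, breed) {
  members <- panel$samples[panel$breed_of == breed]
  sapply(seq_len(nrow(panel$map)), function(i) {
    ch <- panel$map$chrom[i]; p <- panel$map$pos_bp[i]
    covered <- vapply(members, function(id) {
      own <- segments[segments$sample_id == id & segments$chrom == ch, ,
                      drop = FALSE]
      any(own$start_bp <= p & own$end_bp >= p)
    }, logical(1))
    sum(covered) / length(members)
  })
}

# Evenly spaced integer positions from `from` spanning `span` bp over m SNPs.
spaced_pos <- function(m, from = 1e6, span = NULL, by = NULL) {
  if (is.null(by)) by <- span / (m - 1)
  as.integer(round(from + (seq_len(m) - 1) * by))
}

# --- segment-constraint boundary fixtures ----------------------------------
# Each case: one individual, one chromosome; `accept` says whether the whole
# run must be called as a single segment covering all SNPs.  Geometries are
# chosen so that when the full run is infeasible, every sub-run fails a
# threshold too and the caller must return nothing.
roh_boundary_cases <- function() {
  hom <- function(m) rep(2L, m)
  list(
    # minimum length: 81 hom SNPs spanning 499 kb vs 500 kb
    list(name = "length 499kb", geno = hom(81),
         pos = spaced_pos(81, span = 499000), accept = FALSE),
    list(name = "length 500kb", geno = hom(81),
         pos = spaced_pos(81, span = 500000), accept = TRUE),
    # homozygous-SNP count: 80 vs 81 ("more than 80")
    list(name = "80 hom snps", geno = hom(80),
         pos = spaced_pos(80, span = 600000), accept = FALSE),
    list(name = "81 hom snps", geno = hom(81),
         pos = spaced_pos(81, span = 600000), accept = TRUE),
    # heterozygote allowance: 1 vs 2 (adjacent center hets so every sub-run
    # with <= 1 het spans less than 500 kb)
    list(name = "1 het", geno = { g <- hom(200); g[100] <- 1L; g },
         pos = spaced_pos(200, span = 505000), accept = TRUE),
    list(name = "2 hets", geno = { g <- hom(200); g[100:101] <- 1L; g },
         pos = spaced_pos(200, span = 505000), accept = FALSE),
    # missing allowance: 2 vs 3
    list(name = "2 missing", geno = { g <- hom(200); g[100:101] <- NA; g },
         pos = spaced_pos(200, span = 505000), accept = TRUE),
    list(name = "3 missing", geno = { g <- hom(200); g[100:102] <- NA; g },
         pos = spaced_pos(200, span = 505000), accept = FALSE),
    # gap rule: 99 kb vs 101 kb between two 100-SNP blocks
    list(name = "99kb gap",
         geno = hom(200),
         pos = c(spaced_pos(100, from = 1e6, by = 4000),
                 spaced_pos(100, from = 1e6 + 99 * 4000 + 99000, by = 4000)),
         accept = TRUE),
    list(name = "101kb gap",
         geno = hom(200),
         pos = c(spaced_pos(100, from = 1e6, by = 4000),
                 spaced_pos(100, from = 1e6 + 99 * 4000 + 101000, by = 4000)),
         accept = FALSE),
    # density: 81 SNPs at 49 kb vs 51 kb spacing (both gaps < 100 kb)
    list(name = "density 49kb/SNP", geno = hom(81),
         pos = spaced_pos(81, by = 49000), accept = TRUE),
    list(name = "density 51kb/SNP", geno = hom(81),
         pos = spaced_pos(81, by = 51000), accept = FALSE)
  )
}
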