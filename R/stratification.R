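# Population stratification: pairwise identity-by-state and PCA.

#' Pairwise identity-by-state matrix
#'
#' For each sample pair, the mean over SNPs non-missing in BOTH samples of
#' (shared allele count / 2): genotypes equal contribute 1, differing by one
#' allele 0.5, opposite homozygotes 0. Computed with indicator-matrix
#' products so large panels stay fast.
#'
#' @param panel A \code{\link{genotype_panel}} with at least 2 samples.
#' @return An object of class \code{ibs_matrix}: symmetric numeric matrix
#'   with entries in [0, 1] and sample ids as dimnames.
#' @export
ibs_matrix <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- length(panel$samples)
  if (n < 2) stop2("IBS needs at least 2 samples")
  g <- panel$genotypes
  obs <- !is.na(g)
  i0 <- (obs & g == 0L) + 0; i1 <- (obs & g == 1L) + 0; i2 <- (obs & g == 2L) + 0
  n_shared <- tcrossprod(obs + 0)                 # SNPs non-missing in both
  d2 <- tcrossprod(i0, i2); d2 <- d2 + t(d2)      # |g_i - g_j| = 2 pairs
  d1 <- tcrossprod(i1, i0 + i2); d1 <- d1 + t(d1) # |g_i - g_j| = 1 pairs
  zero <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)
  if (nrow(zero))
    stop2("sample pair with no shared non-missing SNPs: ",
          panel$samples[zero[1, 1]], " / ", panel$samples[zero[1, 2]])
  G <- (2 * n_shared - d1 - 2 * d2) / (2 * n_shared)
  dimnames(G) <- list(panel$samples, panel$samples)
  class(G) <- c("ibs_matrix", class(G))
  G
}

#' Principal components from a similarity matrix
#'
#' Classical multidimensional-scaling construction: the similarity matrix is
#' double-centered and eigendecomposed; coordinates are eigenvectors scaled
#' by the square root of their (non-negative) eigenvalues, and each
#' component's variance fraction is its eigenvalue over the sum of positive
#' eigenvalues. Negative eigenvalues (possible when centering a similarity
#' that is not positive semi-definite) are dropped from the normalization.
#' Signs are fixed so each component's largest-magnitude loading is
#' positive.
#'
#' @param G Symmetric similarity matrix (e.g. \code{\link{ibs_matrix}}).
#' @param k Number of components (default all).
#' @return An object of class \code{ibs_pca}: list with \code{coordinates}
#'   (samples x k), \code{variance_fraction} (length k, non-increasing),
#'   \code{eigenvalues}.
#' @export
pca_from_similarity <- function(G, k = NULL) {
  G <- unclass(G)
  if (!isSymmetric(G, tol = 1e-8)) stop2("similarity matrix must be symmetric")
  n <- nrow(G)
  k <- k %||% n
  centered <- scale(t(scale(t(G), scale = FALSE)), scale = FALSE)
  eig <- eigen((centered + t(centered)) / 2, symmetric = TRUE)
  lam <- eig$values
  pos <- pmax(lam, 0)
  total <- sum(pos)
  kk <- min(k, n)
  coords <- eig$vectors[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(pos[seq_len(kk)]), kk)
  # sign convention: largest |loading| positive
  for (j in seq_len(kk)) {
    col <- coords[, j]
    if (length(col) && col[which.max(abs(col))] < 0) coords[, j] <- -col
  }
  vf <- if (total > 0) pos[seq_len(kk)] / total else rep(0, kk)
  if (k > n) { # pad degenerate request with zero components
    coords <- cbind(coords, matrix(0, n, k - n))
    vf <- c(vf, rep(0, k - n))
  }
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  structure(list(coordinates = coords, variance_fraction = vf,
                 eigenvalues = lam), class = "ibs_pca")
}

#' @export
print.ibs_pca <- function(x, ...) {
  k <- min(5, ncol(x$coordinates))
  cat("ibs_pca:", nrow(x$coordinates), "samples,", ncol(x$coordinates),
      "components\n  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "),
      if (ncol(x$coordinates) > k) "...", "\n")
  invisible(x)
}

#' Scatterplot of PCA coordinates colored by breed
#'
#' @param x An \code{ibs_pca}.
#' @param breed_of Named character vector sample -> breed.
#' @param pcs Length-2 integer vector: which components to plot.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, a list describing the plotted layout (one entry per
#'   breed with its coordinates), used by tests.
#' @export
plot_pca <- function(x, breed_of, pcs = c(1, 2), ...) {
  stopifnot(inherits(x, "ibs_pca"), length(pcs) == 2)
  co <- x$coordinates[, pcs, drop = FALSE]
  breeds <- unique(unname(breed_of[rownames(co)]))
  cols <- grDevices::hcl.colors(max(3, length(breeds)), "Dark 3")
  lab <- function(i) sprintf("PC%d (%.1f%%)", pcs[i],
                             100 * x$variance_fraction[pcs[i]])
  graphics::plot(co, col = cols[match(breed_of[rownames(co)], breeds)],
                 pch = 19, xlab = lab(1), ylab = lab(2), ...)
  graphics::legend("topright", legend = breeds,
                   col = cols[seq_along(breeds)], pch = 19, cex = 0.7)
  invisible(lapply(stats::setNames(breeds, breeds), function(b)
    co[breed_of[rownames(co)] == b, , drop = FALSE]))
}
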