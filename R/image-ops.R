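#' Low-level image operators
#'
#' Small, dependency-free raster primitives used by both the fixture
#' renderer and the quantification pipeline: separable Gaussian blur,
#' variance-of-Laplacian sharpness, Otsu thresholding, 4-connected
#' component labelling and binary dilation.  Images are plain numeric
#' matrices indexed (row, col), 0-based coordinates at the API surface.
#'
#' @name image-ops
#' @keywords internal
NULL

# Banded row-stochastic Gaussian convolution matrix.  Row normalisation
# (rather than kernel truncation) keeps flat fields exactly flat at the
# image border, so background estimates are unbiased near edges.
gauss_band <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (d in seq(-r, r)) {
    j <- idx + d
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- k[d + r + 1L]
  }
  K / rowSums(K)
}

blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  gauss_band(nrow(img), sigma) %*% img %*% t(gauss_band(ncol(img), sigma))
}

# Variance of the 4-neighbour Laplacian over the image interior.  Invariant
# to affine intensity maps up to the positive gain squared, so the argmax
# over planes is gain/offset independent.
laplacian_var <- function(img) {
  n <- nrow(img); m <- ncol(img)
  if (n < 3L || m < 3L) return(0)
  core <- img[2:(n - 1), 2:(m - 1)]
  lap <- img[1:(n - 2), 2:(m - 1)] + img[3:n, 2:(m - 1)] +
    img[2:(n - 1), 1:(m - 2)] + img[2:(n - 1), 3:m] - 4 * core
  var(as.vector(lap))
}

# Otsu's between-class-variance threshold on a 256-bin histogram.
# Returns NA for a constant image (degenerate: nothing to separate).
otsu_threshold <- function(img, n_bins = 256L) {
  x <- as.vector(img)
  lo <- min(x); hi <- max(x)
  # treat numerically constant images (e.g. float residue after blurring a
  # flat field) as degenerate: nothing to separate
  if (hi - lo <= 1e-8 * max(1, abs(hi))) return(NA_real_)
  bin <- pmin(n_bins, 1L + as.integer((x - lo) / (hi - lo) * n_bins))
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

# 4-connected component labelling by iterative flood fill; labels are then
# renumbered row-major by centroid so ordering is deterministic.
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  stack <- integer(length(fg))
  cur <- 0L
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% n) + 1L
      cc <- ((p - 1L) %/% n) + 1L
      nbr <- c(if (r > 1L) p - 1L, if (r < n) p + 1L,
               if (cc > 1L) p - n, if (cc < m) p + n)
      for (q in nbr) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  relabel_rowmajor(lab)
}

relabel_rowmajor <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  cent <- t(vapply(ids, function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- lab
  for (k in seq_along(ord)) out[lab == ids[ord[k]]] <- k
  out
}

# Binary dilation with a disk of radius r (shift-and-OR; r is small).
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  for (dr in seq(-r, r)) {
    for (dc in seq(-r, r)) {
      if (dr == 0 && dc == 0) next
      if (dr * dr + dc * dc > r * r) next
      rs <- max(1L, 1L + dr):min(n, n + dr)
      cs <- max(1L, 1L + dc):min(m, m + dc)
      out[rs, cs] <- out[rs, cs] | mask[rs - dr, cs - dc]
    }
  }
  out
}

# Pearson correlation between two equally sized patches; NA when either is
# constant (undefined, used as a "cannot refine" signal by the stitcher).
patch_ncc <- function(a, b) {
  va <- as.vector(a); vb <- as.vector(b)
  if (sd(va) == 0 || sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}
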