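#' PCA denoising of an MRI slice stack
#'
#' Treats the volume as a slices-by-pixels matrix (slices as
#' observations), centres it pixel-wise, computes the principal
#' components of the slice stack, and reconstructs the stack from the
#' leading components only. Weak components — background noise and
#' ringing ripples uncorrelated across slices — are discarded while the
#' dominant structural modes shared across slices are retained. Negative
#' reconstructed intensities are clamped to zero.
#'
#' Exactly one of \code{variance_fraction} (smallest number of
#' components whose cumulative variance reaches the fraction) or
#' \code{n_components} must be given.
#'
#' @param volume an [MRIVolume-class].
#' @param variance_fraction fraction of total variance to retain, in
#'   (0, 1]. Default 0.99.
#' @param n_components number of leading components to retain.
#' @return A denoised [MRIVolume-class] with the same grid and spacing;
#'   the number of retained components is recorded in
#'   \code{meta$pca_components_retained}.
#' @examples
#' vol <- MRIVolume(array(abs(rnorm(16 * 16 * 8)), c(16, 16, 8)), c(1, 1, 1))
#' pcaDenoise(vol, n_components = 2)
#' @export
pcaDenoise <- function(volume, variance_fraction = NULL,
                       n_components = NULL) {
  stopifnot(is(volume, "MRIVolume"))
  if (is.null(variance_fraction) && is.null(n_components))
    variance_fraction <- 0.99
  if (!is.null(variance_fraction) && !is.null(n_components))
    stop("give exactly one of variance_fraction or n_components")
  src <- intensities(volume)
  d <- dim(src)
  ns <- d[3]
  if (!is.null(n_components)) {
    n_components <- as.integer(n_components)
    if (n_components < 1L) stop("n_components must be >= 1")
    if (n_components > ns)
      stop("too many components: n_components exceeds the slice count")
  } else if (variance_fraction <= 0 || variance_fraction > 1) {
    stop("variance_fraction must be in (0, 1]")
  }

  X <- t(matrix(src, ncol = ns))            # slices x pixels
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)

  # eigendecomposition of the slice Gram matrix (ns x ns)
  G <- tcrossprod(Xc)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)

  if (!is.null(n_components)) {
    m <- n_components
  } else {
    tot <- sum(ev)
    m <- if (tot == 0) 1L else which(cumsum(ev) / tot >= variance_fraction - 1e-12)[1]
  }
  U <- eg$vectors[, seq_len(m), drop = FALSE]
  Xhat <- U %*% crossprod(U, Xc)
  Xhat <- sweep(Xhat, 2L, mu, `+`)
  out <- array(t(Xhat), d)
  out[out < 0] <- 0
  meta <- volume@meta
  if (is.null(meta)) meta <- list()
  meta$pca_components_retained <- as.integer(m)
  MRIVolume(out, voxelSpacing(volume), meta)
}
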