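# Mattes mutual-information similarity between two images on a common grid.
# The joint histogram is built with first-order (linear) Parzen windows on
# both axes, i.e. each sample spreads its mass bilinearly over the four
# neighbouring (fixed-bin, moving-bin) cells, which smooths the histogram
# and makes the measure differentiable in the moving intensities.

#' Negative Mattes mutual information between two images
#'
#' Returns `zeta = -MI <= 0`; smaller (more negative) means better aligned.
#' When either image is constant the mutual information is defined as 0 and
#' the result carries attribute `degenerate = TRUE`.
#'
#' @param fixed,moving [raster2d()] images on the same grid.
#' @param bins number of histogram bins per axis (>= 8, default 32).
#' @return scalar `zeta` (negative mutual information, in nats).
#' @export
mattes_mi <- function(fixed, moving, bins = 32L) {
  if (!identical(dim(fixed), dim(moving)))
    stop("images must share a grid")
  if (bins < 8L) stop("bins must be >= 8")
  r <- .mi_core(fixed$values, moving$values, bins, want_grad = FALSE)
  out <- r$zeta
  attr(out, "degenerate") <- r$degenerate
  out
}

# Core MI computation on plain matrices.  With want_grad = TRUE also returns
# the per-pixel derivative of zeta with respect to the moving intensity.
.mi_core <- function(fv, mv, bins, want_grad = FALSE) {
  f <- as.vector(fv); m <- as.vector(mv)
  n <- length(f)
  fr <- range(f); mr <- range(m)
  if (fr[2] - fr[1] <= 0 || mr[2] - mr[1] <= 0) {
    return(list(zeta = 0, degenerate = TRUE,
                dzeta_dm = if (want_grad) matrix(0, nrow(fv), ncol(fv))))
  }
  wf <- (fr[2] - fr[1]) / (bins - 1)
  wm <- (mr[2] - mr[1]) / (bins - 1)
  bf <- (f - fr[1]) / wf            # continuous bin coordinate, 0..bins-1
  bm <- (m - mr[1]) / wm
  i0 <- pmin(floor(bf), bins - 2); fi <- pmin(pmax(bf - i0, 0), 1)
  j0 <- pmin(floor(bm), bins - 2); fj <- pmin(pmax(bm - j0, 0), 1)
  i0 <- as.integer(i0) + 1L; j0 <- as.integer(j0) + 1L  # 1-based bin index

  jh <- matrix(0, bins, bins)       # rows: fixed bins, cols: moving bins
  add <- function(ii, jj, ww) {
    idx <- (jj - 1L) * bins + ii
    s <- rowsum(ww, idx)
    jh[as.integer(rownames(s))] <<- jh[as.integer(rownames(s))] + s
  }
  add(i0,      j0,      (1 - fi) * (1 - fj))
  add(i0 + 1L, j0,      fi * (1 - fj))
  add(i0,      j0 + 1L, (1 - fi) * fj)
  add(i0 + 1L, j0 + 1L, fi * fj)
  p <- jh / n
  pf <- rowSums(p); pm <- colSums(p)
  L <- matrix(0, bins, bins)        # log p/(pf pm), 0 where p = 0
  nz <- p > 0                       # safe: clamped weights keep jh >= 0
  L[nz] <- log(p[nz] / (outer(pf, pm)[nz]))
  mi <- sum(p[nz] * L[nz])
  out <- list(zeta = -mi, degenerate = FALSE)
  if (want_grad) {
    # dMI/dm(x): only the two moving-side Parzen weights depend on m(x)
    idxA <- cbind(i0, j0); idxB <- cbind(i0 + 1L, j0)
    idxC <- cbind(i0, j0 + 1L); idxD <- cbind(i0 + 1L, j0 + 1L)
    dmi <- ((1 - fi) * (L[idxC] - L[idxA]) + fi * (L[idxD] - L[idxB])) /
      (n * wm)
    out$dzeta_dm <- matrix(-dmi, nrow(fv), ncol(fv))
  }
  out
}
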