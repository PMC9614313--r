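# Single-atlas segmentation (SAIS), multi-atlas label propagation, and
# label fusion (STAPLE expectation-maximization and a majority-vote
# baseline).

# Single-pass nearest-neighbour label propagation through the composition
# "deformable field then affine" (both pull-back): atlas labels are read at
# mu(x + u(x)) so labels are resampled exactly once.
.propagate_labels <- function(atlas_labels, mu, field, subject) {
  g <- .pixel_grid(subject)
  if (is.null(field)) {
    PX <- g$X; PY <- g$Y
  } else {
    u <- if (inherits(field, "dispfield2d")) field else field$forward
    PX <- g$X + u$dx; PY <- g$Y + u$dy
  }
  sc <- .source_coords(mu, PX, PY)
  px <- .phys_to_px(atlas_labels, sc$PX, sc$PY)
  d <- dim(subject)
  v <- cpp_sample_nearest(atlas_labels$labels, as.vector(px$sx),
                          as.vector(px$sy), 0L)
  labelmap2d(matrix(v, d[1], d[2]), subject$spacing, subject$origin)
}

#' Single-atlas image segmentation (SAIS)
#'
#' Registers the atlas to the subject (affine, then the chosen deformable
#' engine) and propagates the atlas labels through the composed transform
#' with nearest-neighbour interpolation in a single resampling pass.
#'
#' @param subject subject image ([raster2d()]).
#' @param atlas_image atlas intensity image ([raster2d()]).
#' @param atlas_labels atlas label map ([labelmap2d()]), same grid as
#'   `atlas_image`.
#' @param engine `"sdd"` (default) or `"ffd"`.
#' @param config a [registration_config()].
#' @return a [labelmap2d()] on the subject grid with attributes
#'   `affine`, `field` (the estimated transforms) and `warnings`.
#' @export
segment_single_atlas <- function(subject, atlas_image, atlas_labels,
                                 engine = c("sdd", "ffd"),
                                 config = registration_config()) {
  engine <- match.arg(engine)
  if (!identical(dim(atlas_image), dim(atlas_labels)))
    stop("atlas image and labels must share a grid")
  warns <- character(0)
  wh <- function(w) { warns <<- c(warns, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  mu <- withCallingHandlers(register_affine(subject, atlas_image, config),
                            warning = wh)
  pre <- warp_image(atlas_image, mu)
  fld <- withCallingHandlers(
    if (engine == "sdd") register_sdd(subject, pre, config)$forward
    else register_ffd(subject, pre, config),
    warning = wh)
  out <- .propagate_labels(atlas_labels, mu, fld, subject)
  attr(out, "affine") <- mu
  attr(out, "field") <- fld
  attr(out, "warnings") <- warns
  out
}

#' STAPLE label fusion (expectation-maximization)
#'
#' Simultaneous truth and performance level estimation over K propagated
#' label maps.  Rater performance is modeled per class in one-vs-rest form:
#' sensitivity `p[k,l] = Pr(e_k = l | truth = l)` with the residual mass
#' spread uniformly over the other labels, which yields an exact EM whose
#' observed-data log-likelihood is non-decreasing at every iteration;
#' specificity `q[k,l] = Pr(e_k != l | truth != l)` is re-estimated from
#' the posteriors each M-step.  The fused label is the per-pixel posterior
#' arg-max with ties broken toward the lowest label code.
#'
#' @param decisions integer matrix, pixels x raters, of label codes; or a
#'   list of [labelmap2d()] on a common grid.
#' @param priors optional named class priors; default the relative label
#'   frequencies across all raters.
#' @param init_p initial sensitivity for all raters/classes (default 0.9).
#' @param tol EM stops when the largest change in `p` or `q` drops below
#'   this (default 1e-5).
#' @param max_iter maximum EM iterations (default 100).
#' @return list of class `staple_fit`: `labels` (fused; a [labelmap2d()]
#'   when the input was one), `p`, `q` (raters x classes matrices),
#'   `posterior` (pixels x classes), `priors`, `log_likelihood` (trace),
#'   `iterations`, `converged`.
#' @export
staple_fuse <- function(decisions, priors = NULL, init_p = 0.9,
                        tol = 1e-5, max_iter = 100L) {
  ref <- NULL
  if (is.list(decisions) && !is.matrix(decisions)) {
    ref <- decisions[[1]]
    dims <- lapply(decisions, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      stop("all label maps must share a grid")
    decisions <- do.call(cbind, lapply(decisions,
                                       function(l) as.vector(l$labels)))
  }
  decisions <- as.matrix(decisions)
  K <- ncol(decisions)
  if (K < 2L) stop("STAPLE needs at least 2 raters")
  classes <- sort(unique(as.vector(decisions)))
  L <- length(classes)
  if (L < 2L) stop("need at least 2 distinct label codes")
  n <- nrow(decisions)

  # indicator array: for rater k, D1[[k]][x, l] = 1 if e_k(x) = class l
  D1 <- lapply(seq_len(K), function(k)
    outer(decisions[, k], classes, `==`) * 1)
  constant_rater <- vapply(seq_len(K), function(k)
    length(unique(decisions[, k])) == 1L, logical(1))

  if (is.null(priors)) {
    priors <- vapply(seq_along(classes), function(l)
      mean(decisions == classes[l]), numeric(1))
  }
  priors <- priors / sum(priors)

  p <- matrix(init_p, K, L)
  q <- matrix(init_p, K, L)
  ll_trace <- numeric(0)
  converged <- FALSE
  eps <- 1e-12

  for (iter in seq_len(max_iter)) {
    # E-step: posterior W[x, l] by Bayes' rule
    logW <- matrix(rep(log(priors + eps), each = n), n, L)
    for (k in seq_len(K)) {
      pk <- pmin(pmax(p[k, ], eps), 1 - eps)
      hit <- D1[[k]]
      miss_w <- matrix(rep(log((1 - pk) / (L - 1)), each = n), n, L)
      hit_w <- matrix(rep(log(pk), each = n), n, L)
      logW <- logW + hit * hit_w + (1 - hit) * miss_w
    }
    mx <- apply(logW, 1, max)
    Wu <- exp(logW - mx)
    rs <- rowSums(Wu)
    W <- Wu / rs
    ll <- sum(mx + log(rs))
    ll_trace <- c(ll_trace, ll)

    # M-step
    p_new <- p; q_new <- q
    colW <- colSums(W)
    for (k in seq_len(K)) {
      agree <- colSums(W * D1[[k]])
      p_new[k, ] <- agree / pmax(colW, eps)
      q_new[k, ] <- (colSums((1 - W) * (1 - D1[[k]]))) /
        pmax(n - colW, eps)
    }
    # degenerate raters (constant decision maps) are clamped
    p_new[constant_rater, ] <- pmin(pmax(p_new[constant_rater, ], 0.01), 0.99)
    q_new[constant_rater, ] <- pmin(pmax(q_new[constant_rater, ], 0.01), 0.99)

    delta <- max(abs(p_new - p), abs(q_new - q))
    p <- p_new; q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # fused label: posterior arg-max, ties to the lowest code
  fused_idx <- max.col(W, ties.method = "first")
  fused <- classes[fused_idx]
  labels_out <- fused
  if (!is.null(ref))
    labels_out <- labelmap2d(matrix(fused, nrow(ref$labels),
                                    ncol(ref$labels)),
                             ref$spacing, ref$origin)
  dimnames(p) <- dimnames(q) <- list(paste0("rater", seq_len(K)),
                                     paste0("class", classes))
  structure(list(labels = labels_out, p = p, q = q, posterior = W,
                 priors = stats::setNames(priors, paste0("class", classes)),
                 classes = classes, log_likelihood = ll_trace,
                 iterations = length(ll_trace), converged = converged),
            class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("<staple_fit> %d raters, %d classes, %d EM iterations (%s)\n",
              nrow(x$p), length(x$classes), x$iterations,
              if (x$converged) "converged" else "cap reached"))
  cat("sensitivity (p):\n"); print(round(x$p, 3))
  invisible(x)
}

#' Tidy a STAPLE fit
#'
#' One row per rater x class with estimated sensitivity and specificity.
#' @param x a `staple_fit`.
#' @param ... unused.
#' @export
tidy.staple_fit <- function(x, ...) {
  tibble::tibble(
    rater = rep(seq_len(nrow(x$p)), times = ncol(x$p)),
    class = rep(x$classes, each = nrow(x$p)),
    sensitivity = as.vector(x$p),
    specificity = as.vector(x$q))
}

#' Glance at a STAPLE fit
#' @param x a `staple_fit`.
#' @param ... unused.
#' @export
glance.staple_fit <- function(x, ...) {
  tibble::tibble(raters = nrow(x$p), classes = length(x$classes),
                 iterations = x$iterations, converged = x$converged,
                 log_likelihood = x$log_likelihood[x$iterations])
}

#' Majority-vote label fusion
#'
#' Baseline fusion: per-pixel modal label, ties broken toward the lowest
#' code.
#'
#' @inheritParams staple_fuse
#' @return fused labels (a [labelmap2d()] when the input was a list of
#'   label maps, otherwise an integer vector).
#' @export
fuse_majority <- function(decisions) {
  ref <- NULL
  if (is.list(decisions) && !is.matrix(decisions)) {
    ref <- decisions[[1]]
    decisions <- do.call(cbind, lapply(decisions,
                                       function(l) as.vector(l$labels)))
  }
  classes <- sort(unique(as.vector(decisions)))
  counts <- vapply(classes, function(cl) rowSums(decisions == cl),
                   numeric(nrow(decisions)))
  fused <- classes[max.col(counts, ties.method = "first")]
  if (!is.null(ref))
    labelmap2d(matrix(fused, nrow(ref$labels), ncol(ref$labels)),
               ref$spacing, ref$origin)
  else fused
}

#' Multi-atlas image segmentation (MAIS)
#'
#' Runs [segment_single_atlas()] for every atlas, assembles the pixels x
#' raters decision matrix, and fuses with STAPLE (default) or majority
#' vote.  If fewer than two per-atlas segmentations succeed, the best
#' available single result is returned with a warning.
#'
#' @param subject subject image ([raster2d()]).
#' @param atlases list of atlases, each a list with elements `image`
#'   ([raster2d()]) and `labels` ([labelmap2d()]).
#' @param engine `"sdd"` or `"ffd"`.
#' @param fusion `"staple"` (default) or `"majority"`.
#' @param config a [registration_config()].
#' @return a [labelmap2d()] with attributes `per_atlas` (list of propagated
#'   maps), `staple` (the `staple_fit`, when used) and `warnings`.
#' @export
segment_multi_atlas <- function(subject, atlases,
                                engine = c("sdd", "ffd"),
                                fusion = c("staple", "majority"),
                                config = registration_config()) {
  engine <- match.arg(engine)
  fusion <- match.arg(fusion)
  if (length(atlases) < 2L) stop("MAIS needs at least 2 atlases")
  warns <- character(0)
  maps <- vector("list", length(atlases))
  for (i in seq_along(atlases)) {
    maps[[i]] <- tryCatch(
      segment_single_atlas(subject, atlases[[i]]$image,
                           atlases[[i]]$labels, engine, config),
      error = function(e) { warns <<- c(warns, conditionMessage(e)); NULL })
  }
  ok <- !vapply(maps, is.null, logical(1))
  if (sum(ok) < 2L) {
    warning("fewer than 2 per-atlas segmentations succeeded; ",
            "returning the best single result")
    out <- maps[ok][[1]]
    attr(out, "per_atlas") <- maps[ok]
    attr(out, "warnings") <- warns
    return(out)
  }
  maps <- maps[ok]
  fit <- NULL
  fused <- if (fusion == "staple") {
    fit <- staple_fuse(maps)
    fit$labels
  } else fuse_majority(maps)
  attr(fused, "per_atlas") <- maps
  attr(fused, "staple") <- fit
  attr(fused, "warnings") <- warns
  fused
}

#' Fixed-threshold density-based segmentation baseline
#'
#' Classifies each pixel by density band alone (no spatial model): air
#' below the SAT band, then SAT, muscle, trabecular and cortical bone in
#' increasing density order.  Serves as the conventional model-based
#' comparator in motion-resilience experiments.
#'
#' @param image a [raster2d()].
#' @param cuts increasing numeric vector of 4 band edges separating
#'   air | SAT | muscle | trabecular | cortical.
#' @return a [labelmap2d()].
#' @export
segment_threshold <- function(image, cuts = c(25, 65, 190, 700)) {
  if (is.unsorted(cuts)) stop("cuts must be increasing")
  v <- image$values
  band <- findInterval(v, cuts)       # 0..4: air, sat, muscle, tb, cb
  code <- c(tissue_codes[["air"]], tissue_codes[["sat"]],
            tissue_codes[["muscle"]], tissue_codes[["trabecular"]],
            tissue_codes[["cortical"]])[band + 1L]
  labelmap2d(matrix(code, nrow(v), ncol(v)), image$spacing, image$origin)
}
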