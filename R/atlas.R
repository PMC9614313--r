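# Statistical atlas construction by iterative group registration and
# averaging: affine alignment to a chosen reference in the first iteration,
# nonlinear refinement against the evolving average thereafter.

#' Build a statistical atlas by iterative group averaging
#'
#' Iteration 1 affinely registers every subject to the chosen reference and
#' averages; iteration 2 onwards nonlinearly registers every subject's
#' affinely aligned image to the current average and re-averages (the
#' affine stage is not repeated).  Pixels a subject maps from outside its
#' field of view are excluded from that pixel's mean.  The mean-squared
#' change between successive templates is recorded per iteration.
#'
#' @param subjects list of [raster2d()] images sharing grid conventions.
#' @param K number of iterations (>= 1, default 5).
#' @param reference_index subject used as the initial reference (default 1).
#' @param engine nonlinear engine, `"sdd"` (default) or `"ffd"`.
#' @param config a [registration_config()].
#' @return list of class `statistical_atlas`: `atlas` ([raster2d()]),
#'   `provenance` (tibble: iteration, mean_sq_change), `reference_index`,
#'   `engine`, and `excluded` (indices dropped after registration failure).
#' @export
build_statistical_atlas <- function(subjects, K = 5L, reference_index = 1L,
                                    engine = c("sdd", "ffd"),
                                    config = registration_config()) {
  engine <- match.arg(engine)
  if (K < 1L) stop("K must be >= 1")
  n <- length(subjects)
  if (n < 1L) stop("need at least one subject")
  if (n == 1L)
    return(structure(list(atlas = subjects[[1]],
                          provenance = tibble::tibble(iteration = integer(0),
                                                      mean_sq_change = numeric(0)),
                          reference_index = 1L, engine = engine,
                          excluded = integer(0)),
                     class = "statistical_atlas"))
  ref <- subjects[[reference_index]]
  excluded <- integer(0)

  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      mu <- register_affine(ref, subjects[[i]], config)
      w <- .warp_through(subjects[[i]], mu, NULL, ref)
      list(img = w$img, mask = w$mask, mu = mu)
    }, error = function(e) NULL)
    if (is.null(res)) excluded <- c(excluded, i) else aligned[[i]] <- res
  }
  keep <- setdiff(seq_len(n), excluded)
  if (length(excluded))
    warning("excluded subject(s) after registration failure: ",
            paste(excluded, collapse = ", "))
  if (length(keep) < 2L)
    stop("fewer than 2 subjects survived affine registration")

  template <- .masked_mean(lapply(aligned[keep], `[[`, "img"),
                           lapply(aligned[keep], `[[`, "mask"), ref)
  prov <- tibble::tibble(iteration = 1L, mean_sq_change = NA_real_)

  if (K >= 2L) for (it in 2:K) {
    imgs <- vector("list", length(keep)); msks <- vector("list", length(keep))
    for (j in seq_along(keep)) {
      i <- keep[j]
      if (engine == "sdd") {
        reg <- register_sdd(template, aligned[[i]]$img, config)
        tr <- reg$forward
      } else {
        tr <- register_ffd(template, aligned[[i]]$img, config)
      }
      # resample the original subject once through the composed transform
      w <- .warp_through(subjects[[i]], aligned[[i]]$mu, tr, ref)
      imgs[[j]] <- w$img
      msks[[j]] <- w$mask
    }
    new_template <- .masked_mean(imgs, msks, ref)
    change <- mean((new_template$values - template$values)^2)
    prov <- dplyr::bind_rows(prov,
                             tibble::tibble(iteration = it,
                                            mean_sq_change = change))
    template <- new_template
  }
  structure(list(atlas = template, provenance = prov,
                 reference_index = reference_index, engine = engine,
                 excluded = excluded),
            class = "statistical_atlas")
}

#' @export
print.statistical_atlas <- function(x, ...) {
  cat(sprintf("<statistical_atlas> %d x %d px (%s engine)\n",
              ncol(x$atlas$values), nrow(x$atlas$values), x$engine))
  print(x$provenance)
  invisible(x)
}

# Warp a source image onto ref's grid through "deformable field then
# affine" (both pull-back) in a single bilinear resampling pass; also
# returns the valid-FOV mask (sample point inside the source grid).
.warp_through <- function(src, mu, field, ref) {
  g <- .pixel_grid(ref)
  if (is.null(field)) { PX <- g$X; PY <- g$Y }
  else { PX <- g$X + field$dx; PY <- g$Y + field$dy }
  sc <- .source_coords(mu, PX, PY)
  px <- .phys_to_px(src, sc$PX, sc$PY)
  d <- dim(ref)
  vals <- matrix(cpp_sample_bilinear(src$values, as.vector(px$sx),
                                     as.vector(px$sy), 0), d[1], d[2])
  mask <- px$sx >= 0 & px$sx <= ncol(src$values) - 1 &
          px$sy >= 0 & px$sy <= nrow(src$values) - 1
  list(img = raster2d(vals, ref$spacing, ref$origin), mask = mask)
}

.masked_mean <- function(imgs, masks, ref) {
  acc <- matrix(0, nrow(ref$values), ncol(ref$values))
  cnt <- matrix(0, nrow(ref$values), ncol(ref$values))
  for (j in seq_along(imgs)) {
    acc <- acc + imgs[[j]]$values * masks[[j]]
    cnt <- cnt + masks[[j]]
  }
  raster2d(ifelse(cnt > 0, acc / pmax(cnt, 1), 0), ref$spacing, ref$origin)
}

#' Label a statistical atlas from a labeled reference
#'
#' Propagates a labeled reference template's tissue codes into atlas space
#' with nearest-neighbour interpolation (replacing the manual contouring
#' step of a clinical workflow).
#'
#' @param atlas the statistical atlas image ([raster2d()]).
#' @param reference_labels [labelmap2d()] of the labeled reference.
#' @param reference_to_atlas pull-back transform defined on the atlas grid
#'   that maps atlas coordinates into reference coordinates (an
#'   [affine2d()] or [dispfield2d()]); required.
#' @return a [labelmap2d()] on the atlas grid.
#' @export
label_statistical_atlas <- function(atlas, reference_labels,
                                    reference_to_atlas) {
  if (missing(reference_to_atlas) || is.null(reference_to_atlas))
    stop("a reference-to-atlas transform is required")
  out <- warp_labels(reference_labels, reference_to_atlas)
  labelmap2d(out$labels, atlas$spacing, atlas$origin)
}

#' Register a labeled reference to an atlas and propagate its labels
#'
#' Convenience wrapper: affine + nonlinear registration of the reference
#' image onto the atlas, then [label_statistical_atlas()] through the
#' composed transform.
#'
#' @param atlas statistical atlas image ([raster2d()]).
#' @param reference_image,reference_labels the labeled reference pair.
#' @param engine `"sdd"` or `"ffd"`.
#' @param config a [registration_config()].
#' @return a [labelmap2d()] on the atlas grid.
#' @export
label_atlas_from_reference <- function(atlas, reference_image,
                                       reference_labels,
                                       engine = c("sdd", "ffd"),
                                       config = registration_config()) {
  engine <- match.arg(engine)
  mu <- register_affine(atlas, reference_image, config)
  pre <- warp_image(reference_image, mu)
  tr <- if (engine == "sdd") register_sdd(atlas, pre, config)$forward
        else register_ffd(atlas, pre, config)
  .propagate_labels(reference_labels, mu, tr, atlas)
}
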