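# Tissue quantification: cross-sectional area and mean density per tissue,
# coefficient of variation of the root-mean-squared difference, and
# age-trend regression over cohort records.

#' Cross-sectional area of a tissue
#'
#' Pixel count times the squared pixel spacing; an absent tissue has CSA 0.
#'
#' @param labels a [labelmap2d()].
#' @param tissue tissue code (0-4) or name in [tissue_codes].
#' @param spacing pixel spacing in mm (default: the label map's).
#' @return CSA in mm^2.
#' @export
tissue_csa <- function(labels, tissue, spacing = NULL) {
  code <- if (is.character(tissue)) tissue_codes[[tissue]] else as.integer(tissue)
  if (!code %in% 0:4) stop("invalid tissue code")
  sp <- spacing %||% labels$spacing
  sum(labels$labels == code) * sp^2
}

#' Mean density of a tissue
#'
#' Arithmetic mean of the image intensities over the tissue's pixels; `NA`
#' (missing) when the tissue is absent.
#'
#' @param image a [raster2d()].
#' @param labels the matching [labelmap2d()].
#' @param tissue tissue code or name.
#' @return mean calibrated density, or `NA`.
#' @export
tissue_density <- function(image, labels, tissue) {
  code <- if (is.character(tissue)) tissue_codes[[tissue]] else as.integer(tissue)
  sel <- labels$labels == code
  if (!any(sel)) return(NA_real_)
  mean(image$values[sel])
}

#' Quantify all tissues of a segmented scan
#'
#' @param image a [raster2d()].
#' @param labels the matching [labelmap2d()].
#' @return tibble with columns `tissue`, `csa_mm2`, `density`.
#' @export
quantify_tissues <- function(image, labels) {
  codes <- setdiff(sort(unique(as.vector(labels$labels))), 0L)
  purrr::map_dfr(codes, function(tc)
    tibble::tibble(tissue = .tissue_name(tc),
                   csa_mm2 = tissue_csa(labels, tc),
                   density = tissue_density(image, labels, tc)))
}

#' Quantify a cohort of segmented scans
#'
#' @param cohort tibble as returned by [generate_cohort()] (columns `id`,
#'   `age`, `sex`, `site`, list-columns `image`, `labels`); a `pred_labels`
#'   list-column, when present, is used instead of the ground-truth labels.
#' @return tibble of quantification records, one row per subject x tissue:
#'   `id`, `age`, `sex`, `site`, `tissue`, `csa_mm2`, `density`.
#' @export
quantify_cohort <- function(cohort) {
  labs <- if ("pred_labels" %in% names(cohort)) cohort$pred_labels
          else cohort$labels
  purrr::map_dfr(seq_len(nrow(cohort)), function(i)
    quantify_tissues(cohort$image[[i]], labs[[i]]) |>
      dplyr::mutate(id = cohort$id[i], age = cohort$age[i],
                    sex = cohort$sex[i], site = cohort$site[i],
                    .before = 1))
}

#' Coefficient of variation of the root-mean-squared difference
#'
#' `CV-RMSD = sqrt(mean((y - yhat)^2)) / mean(y)`; invariant under common
#' positive rescaling of `y` and `yhat`.
#'
#' @param y observed values.
#' @param yhat predicted/fitted values (same length).
#' @return non-negative scalar.
#' @export
cv_rmsd <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  mu <- mean(y)
  if (mu == 0) stop("CV-RMSD is undefined when mean(y) = 0")
  sqrt(mean((y - yhat)^2)) / mu
}

#' Age-trend regression of a tissue property
#'
#' Ordinary least squares of the chosen property on age, per stratum
#' (total, male, female), reporting slope, intercept, R^2, CV-RMSD of the
#' fit, the two-sided slope p-value, and n.  R^2 is the squared Pearson
#' correlation by default; a squared-Spearman option is provided.
#'
#' @param records quantification records (see [quantify_cohort()]): needs
#'   columns `age`, `sex`, `tissue`, and the property column.
#' @param property property column name, `"csa_mm2"` or `"density"`.
#' @param tissue tissue name to analyse (e.g. `"muscle"`).
#' @param strata which strata to fit (default all three).
#' @param cor_method `"pearson"` (default) or `"spearman"` for R^2.
#' @return object of class `age_trend` with a `results` tibble (one row per
#'   stratum: `stratum`, `slope`, `intercept`, `r_squared`, `cv_rmsd`,
#'   `p_value`, `n`) and the underlying `lm` fits.
#' @export
regress_age <- function(records, property, tissue = NULL,
                        strata = c("total", "male", "female"),
                        cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  if (!is.null(tissue))
    records <- dplyr::filter(records, .data$tissue == !!tissue)
  if (!property %in% names(records)) stop("unknown property: ", property)
  fits <- list()
  rows <- purrr::map_dfr(strata, function(st) {
    d <- if (st == "total") records
         else dplyr::filter(records, .data$sex == st)
    d <- d[is.finite(d[[property]]) & is.finite(d$age), ]
    if (nrow(d) < 3L) stop("stratum '", st, "' has fewer than 3 records")
    if (stats::sd(d$age) == 0) stop("zero age variance in stratum '", st, "'")
    fit <- stats::lm(stats::reformulate("age", property), data = d)
    fits[[st]] <<- fit
    sm <- summary(fit)
    r2 <- if (cor_method == "pearson") stats::cor(d$age, d[[property]])^2
          else stats::cor(d$age, d[[property]], method = "spearman")^2
    tibble::tibble(stratum = st,
                   slope = coef(fit)[["age"]],
                   intercept = coef(fit)[["(Intercept)"]],
                   r_squared = r2,
                   cv_rmsd = cv_rmsd(d[[property]], stats::fitted(fit)),
                   p_value = sm$coefficients["age", "Pr(>|t|)"],
                   n = nrow(d))
  })
  structure(list(results = rows, fits = fits, property = property,
                 tissue = tissue, cor_method = cor_method),
            class = "age_trend")
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf("<age_trend> %s%s (R^2: squared %s correlation)\n",
              x$property,
              if (!is.null(x$tissue)) paste0(" of ", x$tissue) else "",
              x$cor_method))
  print(x$results)
  invisible(x)
}

#' Tidy an age-trend fit
#'
#' One row per stratum with the regression summary (broom-style).
#' @param x an `age_trend` object.
#' @param ... unused.
#' @export
tidy.age_trend <- function(x, ...) x$results

#' Glance at an age-trend fit
#' @param x an `age_trend` object.
#' @param ... unused.
#' @export
glance.age_trend <- function(x, ...) {
  tot <- dplyr::filter(x$results, .data$stratum == "total")
  if (nrow(tot) == 0L) tot <- x$results[1, ]
  tibble::tibble(r_squared = tot$r_squared, cv_rmsd = tot$cv_rmsd,
                 p_value = tot$p_value, n = tot$n)
}

#' Scatter plot with fitted age trends
#'
#' @param object an `age_trend` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.age_trend <- function(object, ...) {
  dfs <- purrr::imap_dfr(object$fits, function(f, st)
    tibble::tibble(stratum = st, age = f$model$age,
                   y = f$model[[object$property]]))
  ggplot2::ggplot(dfs, ggplot2::aes(.data$age, .data$y,
                                    colour = .data$stratum)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "age (years)", y = object$property) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
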