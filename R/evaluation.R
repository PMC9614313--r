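# Segmentation scoring (Dice, sensitivity, precision), rank-sum testing,
# and motion-stratified performance comparison.  Tabular throughout:
# performance records are tibbles, one row per subject x tissue x method.

#' Overlap metrics between a predicted and a reference mask
#'
#' For tissue code `tissue`: `DSC = 2|P&R| / (|P| + |R|)`,
#' `TPR = |P&R| / |R|` (sensitivity), `PR = |P&R| / |P|` (precision).
#' Empty-denominator cases are returned as `NA` (missing), not 0.
#'
#' @param pred,ref [labelmap2d()] on the same grid.
#' @param tissue tissue code (1-4) or name in [tissue_codes].
#' @return named numeric vector `c(dsc, tpr, pr)`.
#' @export
overlap_metrics <- function(pred, ref, tissue) {
  if (!identical(dim(pred), dim(ref)))
    stop("prediction and reference must share a grid")
  code <- if (is.character(tissue)) tissue_codes[[tissue]] else as.integer(tissue)
  P <- pred$labels == code
  R <- ref$labels == code
  np <- sum(P); nr <- sum(R); ni <- sum(P & R)
  c(dsc = if (np + nr > 0) 2 * ni / (np + nr) else NA_real_,
    tpr = if (nr > 0) ni / nr else NA_real_,
    pr  = if (np > 0) ni / np else NA_real_)
}

#' Score a segmentation over all tissues
#'
#' @param pred,ref [labelmap2d()] on the same grid.
#' @param tissues tissue codes to score (default: the non-air codes present
#'   in the reference).
#' @return tibble with columns `tissue`, `dsc`, `tpr`, `pr`.
#' @export
score_segmentation <- function(pred, ref, tissues = NULL) {
  if (is.null(tissues))
    tissues <- setdiff(sort(unique(as.vector(ref$labels))), 0L)
  purrr::map_dfr(tissues, function(tc) {
    m <- overlap_metrics(pred, ref, tc)
    tibble::tibble(tissue = .tissue_name(tc), dsc = m[["dsc"]],
                   tpr = m[["tpr"]], pr = m[["pr"]])
  })
}

.tissue_name <- function(code) names(tissue_codes)[match(code, tissue_codes)]

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null enumeration when `n_a + n_b <= 20` and the pooled sample has
#' no ties; otherwise the normal approximation with continuity and tie
#' correction.  If every value in both samples is identical the test is
#' degenerate and `p = 1` is returned.
#'
#' @param a,b numeric samples (each of size >= 3).
#' @return two-sided p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    stop("each sample must have size >= 3")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)
  use_exact <- (length(a) + length(b) <= 20L) &&
    !any(duplicated(pooled))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value)
}

#' Motion-stratified performance report
#'
#' Splits performance records into a low-motion stratum (grades 1-3 by
#' default) and a high-motion stratum (grades 4-5), and reports, per tissue
#' and method, the stratum means of the chosen metric, the relative
#' difference `(high - low) / low * 100` (%), and the two-sided Wilcoxon
#' rank-sum p-value between the strata.  Rows whose strata cannot both be
#' filled are flagged `incomplete`.
#'
#' @param records tibble with at least columns `tissue`, `method`,
#'   `motion_grade` and the metric column.
#' @param metric metric column name (default `"dsc"`).
#' @param low_grades,high_grades integer grade sets defining the strata.
#' @return tibble with columns `tissue`, `method`, `n_low`, `n_high`,
#'   `mean_low`, `mean_high`, `diff_pct`, `p_value`, `incomplete`.
#' @export
motion_stratified_report <- function(records, metric = "dsc",
                                     low_grades = 1:3, high_grades = 4:5) {
  stopifnot(all(c("tissue", "method", "motion_grade", metric) %in%
                  names(records)))
  records |>
    dplyr::mutate(.m = .data[[metric]],
                  stratum = dplyr::case_when(
                    .data$motion_grade %in% low_grades ~ "low",
                    .data$motion_grade %in% high_grades ~ "high",
                    TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$stratum), !is.na(.data$.m)) |>
    dplyr::group_by(.data$tissue, .data$method) |>
    dplyr::group_modify(function(d, key) {
      lo <- d$.m[d$stratum == "low"]
      hi <- d$.m[d$stratum == "high"]
      incomplete <- length(lo) == 0L || length(hi) == 0L
      tibble::tibble(
        n_low = length(lo), n_high = length(hi),
        mean_low = if (length(lo)) mean(lo) else NA_real_,
        mean_high = if (length(hi)) mean(hi) else NA_real_,
        diff_pct = if (!incomplete && mean(lo) != 0)
          (mean(hi) - mean(lo)) / mean(lo) * 100 else NA_real_,
        p_value = if (length(lo) >= 3L && length(hi) >= 3L)
          wilcoxon_rank_sum(lo, hi) else NA_real_,
        incomplete = incomplete)
    }) |>
    dplyr::ungroup()
}

#' Boxplot of segmentation performance records
#'
#' @param records tibble with columns `tissue`, `method` and the metric.
#' @param metric metric column to plot (default `"dsc"`).
#' @return a ggplot object.
#' @export
plot_performance <- function(records, metric = "dsc") {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$tissue, y = .data[[metric]],
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' Display a raster with optional label overlay
#'
#' @param image a [raster2d()].
#' @param labels optional [labelmap2d()] overlay (drawn semi-transparent
#'   with the conventional tissue colours: TB yellow, CB cyan, muscle red,
#'   SAT white).
#' @return a ggplot object.
#' @export
plot_raster <- function(image, labels = NULL) {
  g <- .pixel_grid(image)
  df <- tibble::tibble(x = as.vector(g$X), y = as.vector(g$Y),
                       value = as.vector(image$values))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "grey95") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
  if (!is.null(labels)) {
    cols <- c(trabecular = "yellow", cortical = "cyan",
              muscle = "red", sat = "white")
    ld <- tibble::tibble(x = as.vector(g$X), y = as.vector(g$Y),
                         tissue = .tissue_name(as.vector(labels$labels)))
    ld <- ld[!is.na(ld$tissue) & ld$tissue != "air", ]
    p <- p +
      ggplot2::geom_raster(data = ld,
                           ggplot2::aes(fill = NULL, x = .data$x,
                                        y = .data$y,
                                        alpha = 0.35),
                           fill = cols[ld$tissue], show.legend = FALSE)
  }
  p
}
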