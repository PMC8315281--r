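#' Tidy a cross-validation result
#'
#' Returns one row per disease (and, for repeated k-fold, optionally one row
#' per repeat) with the AUC and pool sizes.
#'
#' @param x An `mdrank_cv` object.
#' @param per_repeat Expand the per-repeat AUCs of a k-fold run into rows.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mdrank_cv <- function(x, per_repeat = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (per_repeat && "per_repeat_aucs" %in% names(out)) {
    out <- out |>
      dplyr::select(-"auc") |>
      tidyr::unnest_longer("per_repeat_aucs", values_to = "auc",
                           indices_to = "repeat_index")
  } else {
    out$per_repeat_aucs <- NULL
  }
  out$roc <- NULL
  out
}

#' One-row summary of a cross-validation result
#'
#' @param x An `mdrank_cv` object.
#' @param ... Unused.
#' @return A tibble with the number of diseases and the mean, minimum and
#'   maximum per-disease AUC.
#' @export
glance.mdrank_cv <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme[1],
    n_diseases = nrow(x),
    mean_auc = mean(x$auc),
    min_auc = min(x$auc),
    max_auc = max(x$auc)
  )
}

#' Tidy a microbe ranking
#'
#' @param x An `mdrank_ranking` object.
#' @param ... Unused.
#' @return The ranking as a plain tibble.
#' @export
tidy.mdrank_ranking <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Plot per-disease cross-validation AUCs
#'
#' Dot plot of per-disease AUC (sorted), with a dashed line at the
#' no-information level 0.5.
#'
#' @param object An `mdrank_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdrank_cv <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(disease = stats::reorder(.data$disease, .data$auc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc, y = .data$disease)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "per-disease AUC", y = NULL,
                  title = sprintf("%s cross-validation", object$scheme[1]))
}

#' Plot the top of a microbe ranking
#'
#' @param object An `mdrank_ranking` object.
#' @param top Number of top-ranked microbes to show (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdrank_ranking <- function(object, top = 30L, ...) {
  df <- utils::head(tibble::as_tibble(object), top) |>
    dplyr::mutate(microbe = stats::reorder(.data$microbe, .data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$microbe)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "steady-state probability", y = NULL,
                  title = attr(object, "disease") %||% "microbe ranking")
}

#' Plot a pooled ROC curve
#'
#' @param roc Tibble with `fpr`, `tpr` columns as returned by [roc_auc()].
#' @param label Optional curve label for the title.
#' @return A ggplot object.
#' @export
plot_roc <- function(roc, label = NULL) {
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = label)
}
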