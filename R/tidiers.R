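#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a logistic scoring model
#'
#' One row per coefficient (including the intercept), with standard errors
#' when the model was fitted here.
#'
#' @param x A `logistic_model`.
#' @param ... Unused.
#' @return A tibble: `descriptor`, `bin`, `transform`, `estimate`,
#'   `std_error`.
#' @method tidy logistic_model
#' @export
tidy.logistic_model <- function(x, ...) {
  out <- dplyr::bind_rows(
    tibble::tibble(descriptor = "(Intercept)", bin = "all",
                   transform = "identity", estimate = x$intercept),
    dplyr::select(x$terms, "descriptor", "bin", "transform",
                  estimate = "beta")
  )
  if (!is.null(x$coef_table) && nrow(x$coef_table) == nrow(out)) {
    out$std_error <- x$coef_table$std_error
  } else {
    out$std_error <- NA_real_
  }
  out
}

#' @rdname tidy.logistic_model
#' @method glance logistic_model
#' @export
glance.logistic_model <- function(x, ...) {
  tibble::tibble(
    provenance = x$provenance,
    n_terms = nrow(x$terms),
    aic = if (!is.null(x$aic)) x$aic else NA_real_,
    deviance = if (!is.null(x$fit)) x$fit$deviance else NA_real_,
    nobs = if (!is.null(x$fit)) stats::nobs(x$fit) else NA_integer_
  )
}

#' Tidy an evaluation report
#'
#' @param x A `site_evaluation`.
#' @param ... Unused.
#' @return The threshold sweep as a tibble (`threshold`, `fpr`, `tpr`,
#'   `mcc`).
#' @method tidy site_evaluation
#' @export
tidy.site_evaluation <- function(x, ...) x$roc

#' @rdname tidy.site_evaluation
#' @method glance site_evaluation
#' @export
glance.site_evaluation <- function(x, ...) {
  tibble::tibble(auc = x$auc, n = x$n, n_pos = x$n_pos,
                 guidance_threshold = x$guidance_threshold,
                 guidance_tpr = x$guidance_tpr,
                 guidance_mcc = x$guidance_mcc)
}

#' Plot an evaluation report
#'
#' ROC curve plus TPR-vs-threshold and MCC-vs-threshold panels, faceted.
#'
#' @param object A `site_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_evaluation
#' @export
autoplot.site_evaluation <- function(object, ...) {
  roc <- object$roc
  dat <- dplyr::bind_rows(
    tibble::tibble(panel = "ROC", x = roc$fpr, y = roc$tpr),
    tibble::tibble(panel = "TPR vs score threshold", x = roc$threshold,
                   y = roc$tpr),
    tibble::tibble(panel = "MCC vs score threshold", x = roc$threshold,
                   y = roc$mcc)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("AUC %.4f (%d hits, %d positive)", object$auc,
                      object$n, object$n_pos)) +
    ggplot2::theme_minimal()
}

#' Plot search hits
#'
#' Distance-matrix RMSD by rank for one search, a quick visual check of
#' the separation between the top match and the rest.
#'
#' @param object A `site_hits` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_hits
#' @export
autoplot.site_hits <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(rank = object$rank,
                                 rmsddm = object$rmsddm),
                  ggplot2::aes(x = .data$rank, y = .data$rmsddm)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rank", y = "rmsddm (Å)",
                  title = sprintf("%s vs %s", attr(object, "site_id"),
                                  attr(object, "target_id"))) +
    ggplot2::theme_minimal()
}
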