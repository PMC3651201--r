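#' Template size bin
#'
#' Size-specific parameterization uses a Heaviside-like switch over
#' template size: separate coefficients for 2-residue and 3-residue
#' templates and one shared set for 4-7 residues. Templates larger than 7
#' (the library holds sites up to 15 residues) fall into the "4-7" bin so
#' every searchable template scores.
#'
#' @param n_T Template residue count (>= 2).
#' @return One of `"2"`, `"3"`, `"4-7"`.
#' @export
size_bin <- function(n_T) {
  if (any(n_T < 2)) stop("size bins are defined for n_T >= 2")
  dplyr::case_when(n_T == 2 ~ "2", n_T == 3 ~ "3", TRUE ~ "4-7")
}

size_bins <- function() c("2", "3", "4-7")

#' Construct a logistic scoring model
#'
#' A scoring model is an intercept plus a table of terms, each keyed by a
#' descriptor name, a size bin (`"all"` for size-constrained terms), the
#' coefficient, and a transform (`identity`, `d_c`, or `inv_dc` for
#' `(d_c + 0.1)^-1`). The linear predictor is
#' `eta = intercept + sum(beta * x)` over the terms whose bin matches the
#' descriptor vector's size bin, and the score is the standard sigmoid
#' `1 / (1 + exp(-eta))`, always in (0, 1).
#'
#' @param intercept Model intercept.
#' @param terms Tibble with columns `descriptor`, `bin`, `beta`,
#'   `transform`.
#' @param provenance One of `initial`, `minimal`, `intermediate`, `final`,
#'   `fitted`.
#' @param fit Optional underlying `glm` fit (for fitted models).
#' @return A `logistic_model`.
#' @export
new_logistic_model <- function(intercept, terms,
                               provenance = "fitted", fit = NULL) {
  stopifnot(all(c("descriptor", "bin", "beta", "transform") %in% names(terms)),
            all(terms$bin %in% c(size_bins(), "all")))
  structure(list(intercept = intercept, terms = tibble::as_tibble(terms),
                 provenance = provenance, fit = fit),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model '%s'> intercept %.4g, %d term(s)\n",
              x$provenance, x$intercept, nrow(x$terms)))
  print(x$terms, n = Inf)
  invisible(x)
}

# Transform a descriptor table into the model's regressor columns.
descriptor_value <- function(dv, descriptor, transform) {
  known <- c("rmsddm", "e_inc", "f", "n_removed", "backbone_rmsd", "d_c",
             "interaction")
  if (!descriptor %in% known) {
    stop("unknown descriptor in model: ", descriptor)
  }
  if (!descriptor %in% names(dv)) {
    stop("descriptor '", descriptor, "' missing from the input")
  }
  x <- dv[[descriptor]]
  switch(transform,
    identity = x,
    d_c = x,
    inv_dc = 1 / (x + 0.1),
    stop("unknown transform: ", transform)
  )
}

#' Bundled scoring models
#'
#' The four published coefficient sets for the size-partitioned logistic
#' score, as estimated on the original curated-template training corpus:
#' `initial` (preliminary fit used for early rankings), `minimal`
#' (rmsddm + f only, the Process-1-only baseline), `intermediate`, and
#' `final` (the default operating model). These are shipped as-is, not
#' refit. In the final set the pocket-distance term enters as
#' `(d_c + 0.1)^-1` for the 4-7 bin only, and `f` is constrained equal
#' across bins.
#'
#' @param which One of `"initial"`, `"minimal"`, `"intermediate"`,
#'   `"final"`.
#' @return A `logistic_model`.
#' @export
bundled_model <- function(which = c("final", "minimal", "intermediate",
                                    "initial")) {
  which <- match.arg(which)
  t_ <- function(descriptor, bin, beta, transform = "identity") {
    tibble::tibble(descriptor = descriptor, bin = bin, beta = beta,
                   transform = transform)
  }
  model <- switch(which,
    initial = new_logistic_model(17.74, dplyr::bind_rows(
      t_("rmsddm", "all", -2.1),
      t_("e_inc", "all", 0.94),
      t_("f", "all", -18.18),
      t_("backbone_rmsd", "all", -3.94),
      t_("d_c", "all", -0.15, "d_c")
    ), provenance = "initial"),
    minimal = new_logistic_model(-3.09, dplyr::bind_rows(
      t_("rmsddm", "all", 1.35),
      t_("f", "all", -0.84)
    ), provenance = "minimal"),
    intermediate = new_logistic_model(-18.86, dplyr::bind_rows(
      t_("rmsddm", "2", -0.60), t_("rmsddm", "3", -0.92),
      t_("rmsddm", "4-7", -0.45),
      t_("f", "all", 19.15),
      t_("n_removed", "all", -2.764),
      t_("backbone_rmsd", "2", 0.49), t_("backbone_rmsd", "3", 3.15),
      t_("backbone_rmsd", "4-7", 0.50),
      t_("d_c", "4-7", -44.89, "inv_dc"),
      t_("interaction", "2", -3.80), t_("interaction", "3", -11.47),
      t_("interaction", "4-7", 14.81)
    ), provenance = "intermediate"),
    final = new_logistic_model(-4.8, dplyr::bind_rows(
      t_("rmsddm", "2", 0.21), t_("rmsddm", "3", -0.91),
      t_("rmsddm", "4-7", -0.01),
      t_("f", "all", -1.73),
      t_("backbone_rmsd", "2", 0.55), t_("backbone_rmsd", "3", 5.33),
      t_("backbone_rmsd", "4-7", 1.84),
      t_("d_c", "4-7", 18.61, "inv_dc"),
      t_("interaction", "2", 2.83), t_("interaction", "3", -12.63),
      t_("interaction", "4-7", 3.18)
    ), provenance = "final")
  )
  model
}

#' Score descriptor vectors with a logistic model
#'
#' @param model A `logistic_model`.
#' @param dv Descriptor tibble from [compute_descriptors()] (must include
#'   `n_T`).
#' @return Numeric vector of scores in (0, 1).
#' @export
score_hits <- function(model, dv) {
  stopifnot(inherits(model, "logistic_model"))
  bins <- size_bin(dv$n_T)
  eta <- rep(model$intercept, nrow(dv))
  for (i in seq_len(nrow(model$terms))) {
    tm <- model$terms[i, ]
    x <- descriptor_value(dv, tm$descriptor, tm$transform)
    active <- if (tm$bin == "all") rep(TRUE, nrow(dv)) else bins == tm$bin
    eta <- eta + ifelse(active, tm$beta * x, 0)
  }
  stats::plogis(eta)
}

#' Fit a logistic scoring model by maximum likelihood
#'
#' Unregularized binomial GLM fit of the positive/negative label on a
#' chosen descriptor/bin specification (convergence tolerance 1e-8).
#' Size-binned descriptors enter as descriptor-by-bin interaction columns.
#' Coefficient standard errors and AIC are reported; model selection
#' between specifications is typically guided by AIC.
#'
#' @param hits Labeled hit tibble: descriptor columns plus logical/0-1
#'   `label` and `n_T`.
#' @param spec Tibble with columns `descriptor`, `by_bin` (logical) and
#'   optionally `transform`; defaults to the final model's structure.
#' @return A `logistic_model` with provenance `"fitted"`; the `glm` object
#'   is kept in `$fit`, with coefficient table (estimate, SE) in
#'   `$coef_table` and AIC in `$aic`.
#' @export
fit_logistic <- function(hits,
                         spec = tibble::tibble(
                           descriptor = c("rmsddm", "f", "backbone_rmsd",
                                          "d_c", "interaction"),
                           by_bin = c(TRUE, FALSE, TRUE, TRUE, TRUE),
                           transform = c("identity", "identity", "identity",
                                         "inv_dc", "identity"))) {
  if (!"transform" %in% names(spec)) spec$transform <- "identity"
  lab <- as.integer(hits$label)
  if (length(unique(lab)) < 2) {
    stop("both positive and negative labels are required to fit")
  }
  bins <- factor(size_bin(hits$n_T), levels = size_bins())
  X <- list()
  cols <- list()
  for (i in seq_len(nrow(spec))) {
    d <- spec$descriptor[i]
    x <- descriptor_value(hits, d, spec$transform[i])
    if (spec$by_bin[i]) {
      for (b in levels(bins)) {
        if (!any(bins == b)) next
        nm <- paste0(d, "..", b)
        X[[nm]] <- ifelse(bins == b, x, 0)
        cols[[nm]] <- list(descriptor = d, bin = b,
                           transform = spec$transform[i])
      }
    } else {
      X[[d]] <- x
      cols[[d]] <- list(descriptor = d, bin = "all",
                        transform = spec$transform[i])
    }
  }
  df <- data.frame(X, check.names = FALSE)
  df$.label <- lab
  fit <- stats::glm(.label ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  if (!fit$converged) {
    warning("logistic fit did not converge (possible perfect separation)")
  }
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  keep <- names(cf)[-1]
  keep_clean <- gsub("`", "", keep)
  terms <- dplyr::bind_rows(purrr::map(seq_along(keep), function(i) {
    meta <- cols[[keep_clean[i]]]
    tibble::tibble(descriptor = meta$descriptor, bin = meta$bin,
                   beta = unname(cf[keep[i]]),
                   transform = meta$transform)
  }))
  terms <- terms[!is.na(terms$beta), ]
  model <- new_logistic_model(unname(cf[1]), terms, provenance = "fitted",
                              fit = fit)
  model$coef_table <- tibble::tibble(term = c("(Intercept)", keep_clean),
                                     estimate = unname(cf),
                                     std_error = unname(se))
  model$aic <- stats::AIC(fit)
  model
}

#' Label hits by exact EC agreement
#'
#' A hit is a true positive only when the template's EC number matches the
#' target's on all four fields; any wildcard or missing field makes the
#' comparison negative.
#'
#' @param hits Tibble with a `site_ec` column (template EC).
#' @param target_ec The target's four-field EC string.
#' @return `hits` with a logical `label` column added.
#' @export
label_hits <- function(hits, target_ec) {
  full_ec <- function(ec) {
    !is.na(ec) & grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)
  }
  hits$label <- full_ec(hits$site_ec) & full_ec(target_ec) &
    hits$site_ec == target_ec
  hits
}

#' Remove duplicate hits before evaluation
#'
#' Within groups sharing (target, template family, label) - typically
#' additional binding sites on a multimeric template - only the
#' highest-scoring hit is retained, so neither the true- nor the
#' false-positive rate is overstated. Score ties keep the
#' lexicographically smallest `site_id`.
#'
#' @param hits Scored, labeled hit tibble with `target_id`, `family_id`,
#'   `label`, `score`, `site_id`.
#' @return Deduplicated tibble.
#' @export
dedupe_hits <- function(hits) {
  hits |>
    dplyr::group_by(.data$target_id, .data$family_id, .data$label) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$site_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

# Trapezoid AUC from scores and 0/1 labels; tied scores move through the
# ROC together.
auc_trapezoid <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  label <- as.integer(label[ord])
  tp <- cumsum(label)
  fp <- cumsum(1 - label)
  ends <- cumsum(rle(s)$lengths)
  tpr <- c(0, tp[ends] / sum(label))
  fpr <- c(0, fp[ends] / sum(1 - label))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

mcc_from_counts <- function(tp, fp, tn, fn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' ROC / AUC / MCC evaluation of scored hits
#'
#' Sweeps the score threshold over all observed scores to produce the ROC
#' curve (trapezoid AUC), the true-positive-rate curve and the Matthews
#' correlation coefficient curve, plus per-size-bin AUCs. A score threshold
#' of about 0.75 is surfaced as practical guidance for calling a hit
#' positive.
#'
#' @param hits Scored, labeled (and typically deduplicated) hit tibble
#'   with `score`, `label` and `n_T`.
#' @return A `site_evaluation`: list with `auc`, `roc` (tibble `threshold`,
#'   `fpr`, `tpr`, `mcc`), `by_bin` (tibble `bin`, `n`, `n_pos`, `auc`),
#'   `n`, `n_pos`, and `guidance_threshold` (0.75) with its TPR/MCC.
#' @export
evaluate_hits <- function(hits) {
  lab <- as.integer(hits$label)
  if (length(unique(lab)) < 2) {
    stop("evaluation needs both positive and negative labels")
  }
  np <- sum(lab)
  nn <- sum(1 - lab)
  thresholds <- sort(unique(c(0, hits$score, 1)))
  roc <- purrr::map_dfr(thresholds, function(th) {
    pred <- as.integer(hits$score >= th)
    tp <- sum(pred & lab); fp <- sum(pred & !lab)
    fn <- np - tp; tn <- nn - fp
    tibble::tibble(threshold = th, fpr = fp / nn, tpr = tp / np,
                   mcc = mcc_from_counts(tp, fp, tn, fn))
  })
  by_bin <- hits |>
    dplyr::mutate(bin = size_bin(.data$n_T)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(), n_pos = sum(as.integer(.data$label)),
      auc = if (length(unique(.data$label)) < 2) NA_real_ else
        auc_trapezoid(.data$score, .data$label),
      .groups = "drop")
  g_row <- roc[which.min(abs(roc$threshold - 0.75)), ]
  structure(list(auc = auc_trapezoid(hits$score, lab), roc = roc,
                 by_bin = by_bin, n = nrow(hits), n_pos = np,
                 guidance_threshold = 0.75,
                 guidance_tpr = g_row$tpr, guidance_mcc = g_row$mcc),
            class = "site_evaluation")
}

#' @export
print.site_evaluation <- function(x, ...) {
  cat(sprintf("<site_evaluation> AUC %.4f over %d hits (%d positive)\n",
              x$auc, x$n, x$n_pos))
  cat(sprintf("  at threshold %.2f: TPR %.3f, MCC %.3f\n",
              x$guidance_threshold, x$guidance_tpr, x$guidance_mcc))
  print(x$by_bin)
  invisible(x)
}

#' Serialize / deserialize a logistic model as flat text
#'
#' Key-value TSV with an intercept row and one row per term.
#'
#' @param model A `logistic_model`.
#' @param file Path.
#' @return `write_model`: the path, invisibly. `read_model`: the model.
#' @export
write_model <- function(model, file) {
  tab <- dplyr::bind_rows(
    tibble::tibble(descriptor = "(Intercept)", bin = "all",
                   beta = model$intercept, transform = "identity"),
    model$terms
  )
  tab$provenance <- model$provenance
  readr::write_tsv(tab, file)
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  tab <- readr::read_tsv(file, show_col_types = FALSE)
  ic <- tab$descriptor == "(Intercept)"
  new_logistic_model(tab$beta[ic][1], tab[!ic, c("descriptor", "bin",
                                                 "beta", "transform")],
                     provenance = tab$provenance[1])
}
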