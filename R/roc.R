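#' Weighted ROC analysis of median CBF against infarction
#'
#' Sweeps a CBF cutoff over the sorted unique observed values; a pixel is
#' called positive (predicted infarct) when its CBF is less than or equal to
#' the cutoff. Sensitivity and specificity are weighted fractions within the
#' infarct and non-infarct classes; the area under the curve is obtained by
#' trapezoidal integration over (1 − specificity, sensitivity), which equals
#' the weighted Mann–Whitney concordance with ties counted one half.
#'
#' Weights enter only through within-class ratios (each class's weights are
#' normalized by that class's maximum before accumulation), so rescaling all
#' weights of a class — which is exactly what [balance_classes()] does —
#' leaves every coordinate of the curve and the AUC unchanged.
#'
#' @param table A class table (columns `cbf`, `label`, `weight`) with both
#'   classes present.
#' @param criterion Optimality criterion stored for
#'   [optimal_operating_point()]: `"youden"` (maximize sensitivity +
#'   specificity − 1, the default) or `"closest"` (minimize distance to the
#'   perfect corner (0, 1) in ROC space).
#' @return An object of class `cbf_roc`: a list with `curve` (tibble:
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `optimal` (one-row
#'   tibble from [optimal_operating_point()]), `criterion`, and the class
#'   weight totals `w1`, `w0` and counts `n1`, `n0`.
#' @export
roc_curve <- function(table, criterion = c("youden", "closest")) {
  check_class_table(table)
  criterion <- match.arg(criterion)
  tab <- table[table$weight > 0, ]
  if (!any(tab$label == 1L) || !any(tab$label == 0L)) {
    abort("Both classes must carry positive weight.")
  }
  # normalize weights within class by the class maximum: the curve depends on
  # weights only through these ratios, making it exactly invariant to
  # per-class rescaling
  w <- tab$weight
  w[tab$label == 1L] <- w[tab$label == 1L] / max(w[tab$label == 1L])
  w[tab$label == 0L] <- w[tab$label == 0L] / max(w[tab$label == 0L])

  o <- order(tab$cbf)
  cbf <- tab$cbf[o]
  lab <- tab$label[o]
  wo <- w[o]
  cw1 <- cumsum(wo * (lab == 1L))
  cw0 <- cumsum(wo * (lab == 0L))
  last <- which(!duplicated(cbf, fromLast = TRUE))
  W1 <- cw1[length(cw1)]
  W0 <- cw0[length(cw0)]
  sens <- cw1[last] / W1
  spec <- 1 - cw0[last] / W0
  curve <- tibble(
    threshold = c(-Inf, cbf[last]),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  x <- 1 - curve$specificity
  y <- curve$sensitivity
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  out <- structure(
    list(
      curve = curve, auc = auc, criterion = criterion,
      w1 = sum(tab$weight[tab$label == 1L]),
      w0 = sum(tab$weight[tab$label == 0L]),
      n1 = sum(tab$label == 1L), n0 = sum(tab$label == 0L)
    ),
    class = "cbf_roc"
  )
  out$optimal <- optimal_operating_point(out, criterion)
  out
}

#' Optimal operating point of a ROC curve
#'
#' Selects the CBF threshold at the curve's optimal operating point. The
#' default criterion is Youden's J (sensitivity + specificity − 1);
#' `"closest"` instead minimizes the Euclidean distance to the perfect
#' corner (0, 1). Ties are broken toward the lower CBF threshold. Accuracy
#' is the weighted fraction of correctly classified pixels at the chosen
#' threshold, using the class weight totals of the analyzed table.
#'
#' @param roc A `cbf_roc` from [roc_curve()].
#' @param criterion `"youden"` or `"closest"`; defaults to the criterion
#'   stored in `roc`.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `youden`, `criterion`.
#' @export
optimal_operating_point <- function(roc, criterion = NULL) {
  stopifnot(inherits(roc, "cbf_roc"))
  criterion <- match.arg(criterion %||% roc$criterion, c("youden", "closest"))
  cv <- roc$curve[is.finite(roc$curve$threshold), ]
  j <- cv$sensitivity + cv$specificity - 1
  i <- if (criterion == "youden") {
    which.max(j)   # first maximum = lowest qualifying threshold
  } else {
    d2 <- (1 - cv$sensitivity)^2 + (1 - cv$specificity)^2
    which.min(d2)
  }
  acc <- (cv$sensitivity[i] * roc$w1 + cv$specificity[i] * roc$w0) /
    (roc$w1 + roc$w0)
  tibble(
    threshold = cv$threshold[i],
    sensitivity = cv$sensitivity[i],
    specificity = cv$specificity[i],
    accuracy = acc,
    youden = j[i],
    criterion = criterion
  )
}

#' @export
print.cbf_roc <- function(x, ...) {
  cat(sprintf("<cbf_roc> %d infarct / %d non-infarct pixels, AUC %.4f\n",
              x$n1, x$n0, x$auc))
  cat(sprintf(
    "  optimal (%s): threshold %.1f, sens %.2f, spec %.2f, acc %.2f\n",
    x$optimal$criterion, x$optimal$threshold, x$optimal$sensitivity,
    x$optimal$specificity, x$optimal$accuracy
  ))
  invisible(x)
}

#' @rdname roc_curve
#' @param x,object A `cbf_roc` object.
#' @param ... Unused.
#' @return `tidy()` returns the threshold sweep as a tibble; `glance()` a
#'   one-row summary (AUC, optimal threshold and its metrics).
#' @export
tidy.cbf_roc <- function(x, ...) x$curve

#' @rdname roc_curve
#' @export
glance.cbf_roc <- function(x, ...) {
  dplyr::bind_cols(
    tibble(auc = x$auc, n_infarct = x$n1, n_noninfarct = x$n0),
    x$optimal
  )
}

#' @rdname roc_curve
#' @export
autoplot.cbf_roc <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(
      data = object$optimal,
      ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity),
      colour = "red", size = 2
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.3f; optimal threshold %.1f mL/min/100g",
                      object$auc, object$optimal$threshold)
    ) +
    ggplot2::theme_minimal()
}
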