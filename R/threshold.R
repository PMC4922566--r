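#' Build the per-pixel classification table
#'
#' Superimposes the final infarct and non-infarct grey-matter masks onto the
#' median CBF map and extracts one row per retained pixel: its median CBF,
#' its outcome label (infarct = 1, non-infarct = 0) and a unit weight.
#' Non-finite CBF values are dropped with a message. This table is the input
#' to [balance_classes()], [fit_logistic()] and [roc_curve()].
#'
#' @param median_cbf A [median_cbf_map()] result or `"CBF"` [scalar_map()].
#' @param infarct_gm,noninfarct_gm Non-empty disjoint [roi_mask()]s.
#' @return A tibble with columns `cbf`, `label`, `weight`.
#' @export
build_class_table <- function(median_cbf, infarct_gm, noninfarct_gm) {
  if (inherits(median_cbf, "median_cbf_map")) median_cbf <- median_cbf$map
  stopifnot(inherits(median_cbf, "scalar_map"))
  if (mask_count(infarct_gm) == 0L) {
    abort("Infarct mask is empty: subject is non-analyzable.")
  }
  if (mask_count(noninfarct_gm) == 0L) {
    abort("Non-infarct mask is empty: subject is non-analyzable.")
  }
  v <- median_cbf$values
  vi <- v[infarct_gm$members]
  vn <- v[noninfarct_gm$members]
  tab <- tibble(
    cbf = c(vi, vn),
    label = rep(c(1L, 0L), c(length(vi), length(vn))),
    weight = 1
  )
  n_bad <- sum(!is.finite(tab$cbf))
  if (n_bad > 0) {
    inform(sprintf("build_class_table: dropped %d non-finite CBF pixel(s).", n_bad))
    tab <- tab[is.finite(tab$cbf), ]
  }
  if (!any(tab$label == 1L) || !any(tab$label == 0L)) {
    abort("Both classes must survive the non-finite filter.")
  }
  tab
}

#' Equalize class mass by weighting
#'
#' Multiplies every infarct row's weight by the ratio of total non-infarct
#' weight to total infarct weight, so that the two classes carry equal total
#' mass. This is the continuous analogue of scaling the infarct histogram
#' counts up bin-by-bin: relative frequencies within each class are
#' unchanged, so the ROC analysis is unaffected, but the logistic regression
#' is no longer dominated by the much larger penumbra/oligemia class.
#'
#' @param table A class table from [build_class_table()] (columns `cbf`,
#'   `label`, `weight`), with both classes present.
#' @param bin_width If not `NULL`, mirrors the histogram procedure literally:
#'   CBF values are binned at this width (mL·min⁻¹·100g⁻¹) and each row's
#'   CBF is replaced by its bin midpoint before weighting. The default
#'   (`NULL`) keeps raw per-pixel values, which is lossless.
#' @return The table with balanced weights (and binned `cbf` if requested).
#' @export
balance_classes <- function(table, bin_width = NULL) {
  check_class_table(table)
  if (!is.null(bin_width)) {
    stopifnot(bin_width > 0)
    table$cbf <- (floor(table$cbf / bin_width) + 0.5) * bin_width
  }
  w1 <- sum(table$weight[table$label == 1L])
  w0 <- sum(table$weight[table$label == 0L])
  k <- w0 / w1
  table$weight <- ifelse(table$label == 1L, table$weight * k, table$weight)
  table
}

check_class_table <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("cbf", "label", "weight") %in% names(table))) {
    abort("A class table needs columns `cbf`, `label`, `weight`.")
  }
  if (!all(table$label %in% c(0L, 1L))) {
    abort("`label` must be 0 (non-infarct) or 1 (infarct).")
  }
  if (any(!is.finite(table$weight)) || any(table$weight < 0)) {
    abort("Weights must be finite and non-negative.")
  }
  if (!any(table$label == 1L) || !any(table$label == 0L)) {
    abort("Both classes must be present.")
  }
  invisible(table)
}

#' Weighted logistic regression of infarction on CBF
#'
#' Fits `P(infarct | cbf) = plogis(beta0 + beta1 * cbf)` by weighted maximum
#' likelihood using iteratively reweighted least squares. Convergence is
#' declared when the relative log-likelihood change falls below `1e-10` or
#' the largest coefficient step below `1e-8`, within at most 100 iterations;
#' complete separation (diverging coefficients) is reported through
#' `converged = FALSE` with the last iterate retained. The fit is invariant
#' to rescaling all weights by a constant.
#'
#' @param table A class table (see [build_class_table()]), typically after
#'   [balance_classes()]; both classes present and CBF not all identical.
#' @param max_iter,tol_loglik,tol_step Convergence controls.
#' @return An object of class `cbf_logit` with elements `beta0`, `beta1`,
#'   `converged`, `n_iter`, `log_lik`, `nobs`, `vcov` and `cbf_range`.
#' @examples
#' tab <- tibble::tibble(
#'   cbf = c(rnorm(200, 10, 5), rnorm(200, 30, 5)),
#'   label = rep(c(1L, 0L), each = 200), weight = 1
#' )
#' fit <- fit_logistic(tab)
#' probability_crossing(fit, 0.75)
#' @export
fit_logistic <- function(table, max_iter = 100L, tol_loglik = 1e-10,
                         tol_step = 1e-8) {
  check_class_table(table)
  keep <- table$weight > 0
  x <- table$cbf[keep]
  y <- as.numeric(table$label[keep])
  w <- table$weight[keep]
  if (length(unique(x)) < 2L) {
    abort("CBF values are all identical: the slope is unidentifiable.")
  }
  if (!any(y == 1) || !any(y == 0)) abort("Both classes must carry weight.")
  X <- cbind(1, x)
  dimnames(X) <- NULL
  # start from the null model: intercept at the weighted log-odds, slope 0
  pbar <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
  beta <- c(qlogis(pbar), 0)
  eps <- 1e-12
  ll_of <- function(p) sum(w * (y * log(pmax(p, eps)) +
                                  (1 - y) * log(pmax(1 - p, eps))))
  p <- plogis(drop(X %*% beta))
  ll <- ll_of(p)
  converged <- FALSE
  it <- 0L
  info <- NULL
  while (it < max_iter) {
    it <- it + 1L
    pc <- pmin(pmax(p, eps), 1 - eps)
    wirls <- w * pc * (1 - pc)
    z <- drop(X %*% beta) + (y - pc) / (pc * (1 - pc))
    info <- crossprod(X, wirls * X)
    step_ok <- TRUE
    beta_new <- tryCatch(
      drop(solve(info, crossprod(X, wirls * z))),
      error = function(e) {
        step_ok <<- FALSE
        beta
      }
    )
    if (!step_ok || any(!is.finite(beta_new))) break
    p_new <- plogis(drop(X %*% beta_new))
    ll_new <- ll_of(p_new)
    step <- max(abs(beta_new - beta))
    rel <- abs(ll_new - ll) / (abs(ll) + eps)
    beta <- beta_new
    p <- p_new
    ll <- ll_new
    if (rel < tol_loglik || step < tol_step) {
      converged <- TRUE
      break
    }
  }
  # complete separation: the likelihood has no maximizer and the fitted
  # probabilities collapse onto the labels while the slope diverges
  if (converged) {
    separated <- all(abs(y - p) < 1e-6) || max(abs(beta)) > 1e8
    if (separated) converged <- FALSE
  }
  beta <- unname(beta)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  structure(
    list(
      beta0 = beta[1], beta1 = beta[2],
      converged = converged, n_iter = it, log_lik = ll,
      nobs = length(y), vcov = vcov, cbf_range = range(x)
    ),
    class = "cbf_logit"
  )
}

#' @export
print.cbf_logit <- function(x, ...) {
  cat(sprintf(
    "<cbf_logit> logit(p) = %.4g %+.4g * CBF  (%s, %d iterations, logLik %.2f)\n",
    x$beta0, x$beta1,
    if (x$converged) "converged" else "NOT converged", x$n_iter, x$log_lik
  ))
  invisible(x)
}

#' @rdname fit_logistic
#' @param x,object A `cbf_logit` fit.
#' @param ... Unused.
#' @return `tidy()` returns a tibble of coefficients with standard errors;
#'   `glance()` a one-row fit summary including the 50% and 75% probability
#'   crossings.
#' @export
tidy.cbf_logit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble(
    term = c("(Intercept)", "cbf"),
    estimate = c(x$beta0, x$beta1),
    std.error = se
  )
}

#' @rdname fit_logistic
#' @export
glance.cbf_logit <- function(x, ...) {
  tibble(
    converged = x$converged, n_iter = x$n_iter, log_lik = x$log_lik,
    nobs = x$nobs,
    p50_cbf = if (x$beta1 != 0) probability_crossing(x, 0.5, quiet = TRUE)
              else NA_real_,
    p75_cbf = if (x$beta1 != 0) probability_crossing(x, 0.75, quiet = TRUE)
              else NA_real_
  )
}

#' Predicted infarction probability
#'
#' @param object A `cbf_logit` fit.
#' @param newdata Optional data frame with a `cbf` column (or numeric CBF
#'   vector).
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.cbf_logit <- function(object, newdata, ...) {
  cbf <- if (is.data.frame(newdata)) newdata$cbf else as.numeric(newdata)
  plogis(object$beta0 + object$beta1 * cbf)
}

#' CBF at a given predicted infarction probability
#'
#' Inverts the logistic model: the CBF at which the predicted probability of
#' infarction equals `p` is `(qlogis(p) - beta0) / beta1`. The 75% crossing
#' is a conventional per-animal summary of the probability curve.
#'
#' @param fit A `cbf_logit` from [fit_logistic()].
#' @param p Probability in (0, 1); default 0.75.
#' @param quiet Suppress the warning for non-converged fits.
#' @return CBF in mL·min⁻¹·100g⁻¹.
#' @export
probability_crossing <- function(fit, p = 0.75, quiet = FALSE) {
  stopifnot(inherits(fit, "cbf_logit"), p > 0, p < 1)
  if (fit$beta1 == 0) {
    abort("Slope is zero: the probability curve never crosses p.")
  }
  if (!fit$converged && !quiet) {
    warn("Fit did not converge; the crossing is based on the last iterate.")
  }
  (qlogis(p) - fit$beta0) / fit$beta1
}

#' Plot the fitted infarction-probability curve
#'
#' Predicted probability of infarction against CBF over the observed CBF
#' range, with the 75% probability level and its CBF crossing marked.
#'
#' @param object A `cbf_logit` fit.
#' @param p_mark Probability level to mark (default 0.75).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbf_logit <- function(object, p_mark = 0.75, ...) {
  grid <- tibble(cbf = seq(object$cbf_range[1], object$cbf_range[2],
                           length.out = 400))
  grid$p <- predict(object, grid)
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$cbf, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(CBF ~ (mL %.% min^-1 %.% "100g"^-1)),
      y = "Predicted probability of infarction"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (object$beta1 != 0 && object$converged) {
    xc <- probability_crossing(object, p_mark, quiet = TRUE)
    if (xc >= object$cbf_range[1] && xc <= object$cbf_range[2]) {
      gg <- gg +
        ggplot2::geom_hline(yintercept = p_mark, linetype = "dotted") +
        ggplot2::geom_vline(xintercept = xc, linetype = "dotted")
    }
  }
  gg
}
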