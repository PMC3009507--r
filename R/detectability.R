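#' Index of detectability between test and control score distributions
#'
#' Quantifies how well a coherence measure separates a collection of
#' known-coherent ("test") modules from random ("control") modules, as the
#' binormal separation index
#' `D = (mean_T - mean_C) / sqrt(var_T + var_C)`
#' (sample variances). Under binormal assumptions the area under the ROC
#' curve of the two distributions is `pnorm(D)`, so D is monotonically
#' related to the AUC; D above `qnorm(0.95)` corresponds to separation
#' significant at p < 0.05 against a standard-normal reference.
#'
#' Degenerate inputs: when both variances are zero, D is 0 for equal means
#' and a signed infinity otherwise.
#'
#' @param test_scores,control_scores Numeric vectors of at least two
#'   coherence scores each.
#' @return An object of class `detectability_report`; see [tidy()] /
#'   [glance()] methods and [autoplot.detectability_report()].
#' @examples
#' rep <- detectability(c(2, 4), c(0, 2))
#' glance(rep)$d  # 1
#' @export
detectability <- function(test_scores, control_scores) {
  test_scores <- as.numeric(test_scores)
  control_scores <- as.numeric(control_scores)
  if (length(test_scores) < 2L || length(control_scores) < 2L) {
    abort("both score collections need at least two values.",
          class = "funcoh_error_argument")
  }
  if (anyNA(test_scores) || anyNA(control_scores)) {
    abort("score collections must not contain missing values.",
          class = "funcoh_error_argument")
  }
  mt <- mean(test_scores)
  mc <- mean(control_scores)
  vt <- stats::var(test_scores)
  vc <- stats::var(control_scores)
  pooled <- vt + vc
  d <- if (pooled == 0) {
    if (mt == mc) 0 else Inf * sign(mt - mc)
  } else {
    (mt - mc) / sqrt(pooled)
  }
  structure(
    list(
      d = d,
      auc = stats::pnorm(d),
      threshold = stats::qnorm(0.95),
      mean_test = mt, var_test = vt, n_test = length(test_scores),
      mean_control = mc, var_control = vc, n_control = length(control_scores),
      scores = tibble::tibble(
        group = rep(c("test", "control"),
                    c(length(test_scores), length(control_scores))),
        score = c(test_scores, control_scores)
      )
    ),
    class = "detectability_report"
  )
}

#' @export
print.detectability_report <- function(x, ...) {
  cat(sprintf(
    "<detectability_report> D = %.4f (p<0.05 threshold %.4f), binormal AUC = %.4f\n",
    x$d, x$threshold, x$auc))
  cat(sprintf("  test:    n = %d, mean = %.4f, var = %.4f\n",
              x$n_test, x$mean_test, x$var_test))
  cat(sprintf("  control: n = %d, mean = %.4f, var = %.4f\n",
              x$n_control, x$mean_control, x$var_control))
  invisible(x)
}

#' Per-score table of a detectability report
#'
#' @param x A `detectability_report`.
#' @param ... Unused.
#' @return A tibble with columns `group` (`"test"`/`"control"`) and `score`.
#' @export
tidy.detectability_report <- function(x, ...) {
  x$scores
}

#' One-row summary of a detectability report
#'
#' @param x A `detectability_report`.
#' @param ... Unused.
#' @return A one-row tibble: `d`, `auc`, `threshold`, and the group moments
#'   and sizes.
#' @export
glance.detectability_report <- function(x, ...) {
  tibble::tibble(
    d = x$d, auc = x$auc, threshold = x$threshold,
    mean_test = x$mean_test, var_test = x$var_test, n_test = x$n_test,
    mean_control = x$mean_control, var_control = x$var_control,
    n_control = x$n_control
  )
}

#' Plot the two score distributions of a detectability report
#'
#' @param object A `detectability_report`.
#' @param ... Unused.
#' @return A ggplot: overlaid score densities for the test and control
#'   collections, with the separation index in the subtitle.
#' @export
autoplot.detectability_report <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::labs(
      x = "coherence score", y = "density", fill = NULL,
      title = "Test vs control coherence scores",
      subtitle = sprintf("index of detectability D = %.3f", object$d)
    ) +
    ggplot2::theme_minimal()
}
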