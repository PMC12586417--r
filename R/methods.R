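#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.corsm_fit <- function(x, ...) {
  cat(sprintf(
    "<corsm_fit> %s variant: %d persons x %d items on [%g, %g]\n",
    x$variant, nrow(x$persons), nrow(x$items),
    x$geometry$lower, x$geometry$upper
  ))
  cat(sprintf(
    "  dispersion %s, logLik %.3f, %s in %d cycles\n",
    paste(signif(x$dispersion$theta, 4), collapse = ", "),
    x$logLik,
    if (x$converged) "converged" else "NOT converged",
    x$cycles
  ))
  invisible(x)
}

#' Tidy a fitted continuous rating scale model
#'
#' @param x A `corsm_fit`.
#' @param what One of `"items"`, `"persons"`, `"dispersion"`, `"steps"`
#'   (steps only for discrete fits).
#' @param ... Unused.
#' @return A tibble of the requested parameter class.
#' @method tidy corsm_fit
#' @export
tidy.corsm_fit <- function(x, what = c(
                             "items", "persons", "dispersion", "steps"
                           ), ...) {
  what <- match.arg(what)
  if (what == "steps") {
    if (is.null(x$steps)) {
      stop("Step difficulties exist only for discrete fits.", call. = FALSE)
    }
    return(x$steps)
  }
  x[[what]]
}

#' One-row summary of a fitted model
#'
#' @param x A `corsm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sizes, mean dispersion, marginal log-likelihood,
#'   convergence record.
#' @method glance corsm_fit
#' @export
glance.corsm_fit <- function(x, ...) {
  tibble::tibble(
    n_persons = nrow(x$persons),
    n_items = nrow(x$items),
    variant = x$variant,
    theta = mean(x$dispersion$theta),
    logLik = x$logLik,
    converged = x$converged,
    cycles = x$cycles
  )
}

#' Plot a fitted model
#'
#' `type = "items"` draws item difficulties with approximate 95% error bars;
#' `type = "persons"` draws the ability distribution.
#'
#' @param object A `corsm_fit`.
#' @param type `"items"` or `"persons"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corsm_fit
#' @export
autoplot.corsm_fit <- function(object, type = c("items", "persons"), ...) {
  type <- match.arg(type)
  if (type == "items") {
    df <- object$items
    df$item <- factor(df$item, levels = df$item[order(df$difficulty)])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$difficulty, y = .data$item)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbarh(
        ggplot2::aes(
          xmin = .data$difficulty - 1.96 * .data$se,
          xmax = .data$difficulty + 1.96 * .data$se
        ),
        height = 0.2
      ) +
      ggplot2::labs(x = "Item difficulty", y = NULL)
  } else {
    ggplot2::ggplot(
      object$persons, ggplot2::aes(x = .data$ability)
    ) +
      ggplot2::geom_histogram(bins = 30) +
      ggplot2::labs(x = "Ability (MAP)", y = "Persons")
  }
}

#' Plot a recovery report
#'
#' MAD by condition, one panel per parameter class.
#'
#' @param object A `recovery_report` from [run_recovery_study()] or
#'   [run_discrete_recovery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  df <- object
  xvar <- if ("sample_size" %in% names(df)) "sample_size" else "test_length"
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[xvar]], y = .data$mad,
    colour = factor(.data$test_length)
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(
      x = xvar, y = "Mean absolute deviation", colour = "test length"
    )
}

#' Plot item fit statistics
#'
#' Outfit mean squares with the 0.6-1.4 reference band; only values above
#' 1.4 mark an item for removal.
#'
#' @param records A tibble from [outfit_mnsq()].
#' @return A ggplot object.
#' @export
plot_item_fit <- function(records) {
  records$item <- factor(records$item, levels = records$item)
  ggplot2::ggplot(records, ggplot2::aes(
    x = .data$item, y = .data$outfit, colour = .data$retained
  )) +
    ggplot2::geom_hline(yintercept = c(0.6, 1.4), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Outfit MNSQ") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' @importFrom rlang .data
NULL
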