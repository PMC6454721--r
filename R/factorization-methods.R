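#' @export
print.brsnmf_fit <- function(x, ...) {
  cat(sprintf(
    "<brsnmf_fit> method = %s, %d drugs, k = %d, %d iterations (%s), objective = %.4g\n",
    x$method, nrow(x$H), x$config$k, x$iterations,
    if (x$converged) "converged" else "not converged",
    tail(x$objective, 1)
  ))
  invisible(x)
}

#' Tidiers for factorization fits
#'
#' `tidy()` returns the community indicator in long form (one row per drug x
#' community with the nonnegative membership weight and whether it is the
#' argmax); `glance()` returns a one-row model summary.
#'
#' @param x A `brsnmf_fit` from [brsnmf()] or [semi_nmf()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.brsnmf_fit <- function(x, ...) {
  H <- x$H
  hard <- max.col(H, ties.method = "first")
  tibble(
    drug = rep(rownames(H), ncol(H)),
    community = rep(seq_len(ncol(H)), each = nrow(H)),
    weight = as.vector(H),
    assigned = as.vector(col(H) == hard)
  )
}

#' @rdname tidy.brsnmf_fit
#' @export
glance.brsnmf_fit <- function(x, ...) {
  tibble(
    method = x$method,
    k = x$config$k,
    alpha = x$config$alpha,
    beta = x$config$beta,
    iterations = x$iterations,
    converged = x$converged,
    objective = tail(x$objective, 1)
  )
}

#' @rdname tidy.brsnmf_fit
#' @param object A `brsnmf_fit`.
#' @export
autoplot.brsnmf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective) - 1,
               objective = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "objective",
                  title = sprintf("%s objective trace", object$method)) +
    ggplot2::theme_minimal()
}
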