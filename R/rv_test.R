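# Common result container for all rare-variant association tests, so the
# simulation harness and the eQTL pipeline can treat methods as plug-ins.

new_rv_test <- function(statistic, p_value, method,
                        permutations_used = NA_integer_,
                        per_variant = NULL, approximate = FALSE,
                        details = list()) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         permutations_used = permutations_used, per_variant = per_variant,
         approximate = approximate, details = details),
    class = "rv_test"
  )
}

#' @export
print.rv_test <- function(x, ...) {
  cat(sprintf("<rv_test: %s>\n", x$method))
  cat(sprintf("  statistic = %.6g\n", x$statistic))
  if (!is.na(x$p_value)) {
    cat(sprintf("  p value   = %.4g%s\n", x$p_value,
                if (isTRUE(x$approximate)) " (approximate)" else ""))
  }
  if (!is.na(x$permutations_used)) {
    cat(sprintf("  permutations used = %d\n", x$permutations_used))
  }
  invisible(x)
}

#' Tidy per-variant evidence from a test result
#'
#' For tests that carry per-variant detail (LRT-q), returns one row per
#' variant with the log likelihood ratio and the fitted group means; for
#' other tests returns the one-row summary.
#'
#' @param x an `rv_test` result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.rv_test <- function(x, ...) {
  if (!is.null(x$per_variant)) return(tibble::as_tibble(x$per_variant))
  glance.rv_test(x)
}

#' One-row summary of a test result
#'
#' @param x an `rv_test` result.
#' @param ... unused.
#' @return a one-row tibble with `method`, `statistic`, `p_value`,
#'   `permutations_used` and `approximate`.
#' @export
glance.rv_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = x$statistic,
    p_value = x$p_value,
    permutations_used = x$permutations_used,
    approximate = x$approximate
  )
}
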