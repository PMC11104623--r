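#' Hartigan's dip statistic and Monte-Carlo dip test for unimodality
#'
#' `dip_statistic()` computes the dip D of a sample: the smallest sup-norm
#' distance between the empirical CDF and any unimodal CDF (convex up to the
#' mode, concave beyond it). It is computed exactly, via a bisection on the
#' band half-width with a convex-minorant / concave-majorant feasibility
#' check, rather than from interpolated tables. For a sample of n distinct
#' values, 1/(2n) <= D <= 0.25.
#'
#' `dip_test()` returns a Monte-Carlo p-value against the classical uniform
#' null: the proportion of uniform(0, 1) samples of the same size whose dip
#' is at least as large as the observed one (with add-one correction, so
#' p is never exactly 0). Large D, small p indicate multimodality.
#'
#' @param x numeric sample, at least 4 observations.
#' @param n_mc number of Monte-Carlo null samples.
#' @param seed optional integer seed for the Monte-Carlo draw (the global
#'   RNG state is restored afterwards).
#' @param null_dips optional numeric vector of precomputed null dip values
#'   for this sample size (see [dip_null()]); when supplied, `n_mc` and
#'   `seed` are ignored. Useful when testing many samples of the same size.
#' @return `dip_statistic()`: the dip (numeric scalar). `dip_test()`: an
#'   object of class `dip_htest` with elements `statistic`, `p.value`, `n`,
#'   `n_mc`.
#' @examples
#' set.seed(1)
#' dip_test(c(rnorm(50, -2), rnorm(50, 2)), n_mc = 199)
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 4L) {
    stop("sample too small: the dip test needs at least 4 observations",
         call. = FALSE)
  }
  if (any(!is.finite(x))) stop("sample must be finite", call. = FALSE)
  dip_cpp(x)
}

#' @rdname dip_statistic
#' @export
dip_test <- function(x, n_mc = 9999, seed = NULL, null_dips = NULL) {
  d <- dip_statistic(x)
  n <- length(x)
  if (is.null(null_dips)) {
    null_dips <- dip_null(n, n_mc, seed = seed)
  }
  p <- (sum(null_dips >= d) + 1) / (length(null_dips) + 1)
  structure(list(statistic = d, p.value = p, n = n,
                 n_mc = length(null_dips)),
            class = "dip_htest")
}

#' @rdname dip_statistic
#' @param n sample size for the null reference samples.
#' @export
dip_null <- function(n, n_mc = 9999, seed = NULL) {
  with_seed(seed, dip_null_cpp(as.integer(n), as.integer(n_mc)))
}

#' @export
print.dip_htest <- function(x, ...) {
  cat("Hartigan's dip test for unimodality (Monte-Carlo uniform null)\n")
  cat(sprintf("  D = %.4g, n = %d, p = %.4g (%d null samples)\n",
              x$statistic, x$n, x$p.value, x$n_mc))
  invisible(x)
}

# Evaluate `expr` under an optional temporary seed, restoring the RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
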