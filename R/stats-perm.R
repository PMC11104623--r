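#' Permutation t-tests
#'
#' A t-test whose p-value comes from a permutation null rather than the t
#' distribution. For paired or one-sample tests the null is built by random
#' sign flips of the (differences from `mu`); for two independent samples by
#' random reassignment of the group labels. The p-value uses the add-one
#' formula `(b + 1) / (n_perm + 1)` and is therefore never exactly zero.
#'
#' @param a numeric sample (first group, or the single sample).
#' @param b second sample for a two-sample or paired test, or a scalar null
#'   value `mu` for a one-sample test; default 0.
#' @param paired logical; when `TRUE`, `a` and `b` are paired and the test
#'   is a sign-flip test on `a - b`.
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @param n_perm number of random permutations.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return Object of class `perm_htest`: `statistic` (the t statistic),
#'   `p.value`, `n_perm`, `alternative`, `scheme` (`"sign-flip"` or
#'   `"label-permutation"`), `seed`, `estimate` (mean difference).
#' @examples
#' set.seed(1)
#' perm_ttest(rnorm(20, 0.8), rnorm(20), n_perm = 999, seed = 7)
#' @export
perm_ttest <- function(a, b = 0, paired = FALSE,
                       alternative = c("two.sided", "greater", "less"),
                       n_perm = 10000, seed = NULL) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a)
  one_sample <- length(b) == 1L && !paired
  if (paired) {
    if (length(b) != length(a)) stop("paired samples must have equal length",
                                     call. = FALSE)
    d <- a - b
  } else if (one_sample) {
    d <- a - b
  }
  if (one_sample || paired) {
    n <- length(d)
    if (n < 2L) stop("need at least 2 observations", call. = FALSE)
    if (sd(d) == 0 && mean(d) == 0) {
      # identical pairs: every sign flip reproduces the data exactly
      return(structure(list(statistic = 0, p.value = 1, n_perm = n_perm,
                            alternative = alternative,
                            scheme = "sign-flip", seed = seed,
                            estimate = 0),
                       class = "perm_htest"))
    }
    if (sd(d) == 0) stop("degenerate test: zero variance", call. = FALSE)
    tstat <- mean(d) / (sd(d) / sqrt(n))
    perm <- with_seed(seed, {
      flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
      dd <- flips * d
      mns <- colMeans(dd)
      sds <- sqrt((colSums(dd^2) - n * mns^2) / (n - 1))
      mns / (sds / sqrt(n))
    })
    scheme <- "sign-flip"
    estimate <- mean(d)
  } else {
    b <- as.numeric(b)
    na <- length(a); nb <- length(b)
    if (na < 2L || nb < 2L) stop("need at least 2 observations per group",
                                 call. = FALSE)
    if (sd(a) == 0 && sd(b) == 0) {
      stop("degenerate test: zero variance in both groups", call. = FALSE)
    }
    pool <- c(a, b)
    tfun <- function(ga, gb) {
      (mean(ga) - mean(gb)) /
        sqrt(var(ga) / length(ga) + var(gb) / length(gb))
    }
    tstat <- tfun(a, b)
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(na + nb, na)
        tfun(pool[idx], pool[-idx])
      }, numeric(1))
    })
    scheme <- "label-permutation"
    estimate <- mean(a) - mean(b)
  }
  perm[!is.finite(perm)] <- 0
  p <- switch(alternative,
    two.sided = (sum(abs(perm) >= abs(tstat)) + 1) / (n_perm + 1),
    greater   = (sum(perm >= tstat) + 1) / (n_perm + 1),
    less      = (sum(perm <= tstat) + 1) / (n_perm + 1))
  structure(list(statistic = tstat, p.value = p, n_perm = n_perm,
                 alternative = alternative, scheme = scheme, seed = seed,
                 estimate = estimate),
            class = "perm_htest")
}

#' @export
print.perm_htest <- function(x, ...) {
  cat("Permutation t-test (", x$scheme, ")\n", sep = "")
  cat(sprintf("  t = %.4g, p = %.4g (%s, %d permutations)\n",
              x$statistic, x$p.value, x$alternative, x$n_perm))
  if (!is.null(x$flagged) && length(x$flagged)) {
    cat("  note:", length(x$flagged),
        "unit(s) used the penalized slope fallback\n")
  }
  invisible(x)
}

#' Holm step-down multiple-testing correction
#'
#' Thin wrapper around `p.adjust(method = "holm")` that also returns the
#' rejection decisions at a given alpha. Holm-adjusted p-values are never
#' larger than Bonferroni's and never smaller than the raw ones.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha familywise error level for the decisions.
#' @return Data frame with columns `p`, `p_adjusted`, `reject`.
#' @export
holm_correct <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- p.adjust(p, method = "holm")
  data.frame(p = p, p_adjusted = adj, reject = adj <= alpha)
}

#' Participant-level learning-trend test for decoding success
#'
#' Tests whether the probability of valid decoding increases over trials.
#' For each participant a logistic regression of outcome on centred trial
#' number is fitted by iteratively reweighted least squares; participants
#' whose outcomes are constant or separable (slope unbounded) fall back to a
#' ridge-penalised IRLS fit (penalty `ridge` on the slope) and are flagged.
#' The participant slopes are then tested against zero with a one-sample
#' sign-flip permutation test (alternative: mean slope > 0).
#'
#' @param outcomes data frame with columns `participant`, `trial_c`
#'   (centred trial number) and `outcome` (0/1), e.g. from
#'   [decoding_outcome_table()].
#' @param n_perm,seed,alternative passed to [perm_ttest()].
#' @param ridge penalty used by the fallback fit.
#' @return A `perm_htest` with extra elements `slopes` (per-participant data
#'   frame) and `flagged` (participants that used the fallback).
#' @export
learning_trend_test <- function(outcomes, n_perm = 10000, seed = NULL,
                                alternative = "greater", ridge = 0.5) {
  need <- c("participant", "trial_c", "outcome")
  if (!all(need %in% names(outcomes))) {
    stop("`outcomes` needs columns participant, trial_c, outcome",
         call. = FALSE)
  }
  ids <- unique(outcomes$participant)
  if (length(ids) < 2L) {
    stop("group-level trend test needs at least 2 participants",
         call. = FALSE)
  }
  fit_one <- function(df) {
    yy <- df$outcome
    xx <- df$trial_c
    if (length(unique(yy)) > 1L) {
      fit <- suppressWarnings(
        stats::glm(yy ~ xx, family = binomial())
      )
      mu <- fit$fitted.values
      sep <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
      if (!sep) {
        return(list(slope = unname(coef(fit)[2]), flagged = FALSE))
      }
    }
    list(slope = logistic_ridge_slope(xx, yy, ridge), flagged = TRUE)
  }
  fits <- lapply(ids, function(id) {
    fit_one(outcomes[outcomes$participant == id, , drop = FALSE])
  })
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  flagged <- ids[vapply(fits, `[[`, logical(1), "flagged")]
  res <- perm_ttest(slopes, 0, alternative = alternative, n_perm = n_perm,
                    seed = seed)
  res$slopes <- data.frame(participant = ids, slope = slopes,
                           flagged = ids %in% flagged)
  res$flagged <- flagged
  res$scheme <- "per-participant logistic slopes, sign-flip"
  res
}

# IRLS for logistic regression with an L2 penalty on the slope only;
# bounded even under complete separation or constant outcomes.
logistic_ridge_slope <- function(x, y, ridge = 0.5, max_iter = 100) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  pen <- diag(c(0, ridge))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    new_beta <- drop(solve(XtW %*% X + pen, XtW %*% z))
    if (max(abs(new_beta - beta)) < 1e-10) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  beta[2]
}
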