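#' Permutation-based mixed ANOVA
#'
#' Mixed (split-plot) analysis of variance with one between-participant
#' factor and one or two within-participant factors, on a balanced table of
#' per-participant condition cell means. The classical parametric F values
#' are computed with [stats::aov()] using an
#' `Error(participant/(within factors))` stratification; p-values come from
#' permutation nulls: the between-participant main effect permutes the group
#' labels across participants, while within effects and all interactions
#' permute the within-condition cell labels independently within each
#' participant. Both the parametric F (with its degrees of freedom) and the
#' permutation p are reported.
#'
#' The design must be balanced: every participant contributes exactly one
#' value per within-cell, belongs to exactly one between group, and the
#' between groups have equal size; otherwise an error is raised (drop
#' participants to restore balance first).
#'
#' @param data data frame of cell means.
#' @param dv name of the dependent-variable column.
#' @param participant name of the participant-identifier column.
#' @param between name of the between-participant factor column.
#' @param within character vector (length 1 or 2) of within-participant
#'   factor columns.
#' @param n_perm number of permutations per scheme.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return Object of class `perm_anova`: a list with `table` (data frame
#'   with `effect`, `F`, `df1`, `df2`, `p_perm`, `scheme`), `n_perm`,
#'   `seed`.
#' @export
perm_mixed_anova <- function(data, dv, participant = "participant",
                             between = "order",
                             within = c("feedback", "phase"),
                             n_perm = 10000, seed = NULL) {
  cols <- c(dv, participant, between, within)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dd <- data.frame(
    .y = as.numeric(data[[dv]]),
    .id = factor(data[[participant]]),
    .b = factor(data[[between]])
  )
  for (i in seq_along(within)) dd[[paste0(".w", i)]] <- factor(data[[within[i]]])
  wnames <- paste0(".w", seq_along(within))

  # balance checks
  cell <- interaction(dd[wnames], drop = FALSE)
  tab <- table(dd$.id, cell)
  if (any(tab != 1)) {
    stop("unbalanced design: every participant needs exactly one value per ",
         "within-condition cell", call. = FALSE)
  }
  id_groups <- unique(dd[, c(".id", ".b")])
  if (anyDuplicated(id_groups$.id)) {
    stop("each participant must belong to exactly one between-group level",
         call. = FALSE)
  }
  gsz <- table(id_groups$.b)
  if (length(unique(gsz)) != 1L) {
    stop("unbalanced design: between groups must have equal size ",
         "(drop participants to restore balance)", call. = FALSE)
  }

  fixed <- paste(c(".b", wnames), collapse = " * ")
  err <- paste0("Error(.id/(", paste(wnames, collapse = " * "), "))")
  form <- stats::as.formula(paste(".y ~", fixed, "+", err))

  f_of <- function(d) {
    s <- summary(suppressWarnings(aov(form, data = d)))
    out <- list()
    for (stratum in s) {
      tb <- stratum[[1]]
      fs <- tb[["F value"]]
      if (is.null(fs)) next
      nms <- trimws(rownames(tb))
      keep <- nms != "Residuals"
      if (!any(keep)) next
      df_res <- tb[["Df"]][nms == "Residuals"][1]
      for (r in which(keep)) {
        f <- fs[r]
        if (!is.finite(f)) f <- 0 # zero between/within variance
        out[[nms[r]]] <- c(F = f, df1 = tb[["Df"]][r], df2 = df_res)
      }
    }
    out
  }

  obs <- f_of(dd)
  effects <- names(obs)
  is_between_main <- effects == ".b"

  counts <- setNames(numeric(length(effects)), effects)
  ids <- levels(dd$.id)
  id_rows <- split(seq_len(nrow(dd)), dd$.id)
  grp_of_id <- setNames(as.character(id_groups$.b),
                        as.character(id_groups$.id))

  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      # between null: reshuffle group assignment across participants
      db <- dd
      new_grp <- sample(unname(grp_of_id[ids]))
      db$.b <- factor(new_grp[match(as.character(dd$.id), ids)],
                      levels = levels(dd$.b))
      fb <- f_of(db)
      # within null: permute cell labels (values) within each participant
      dw <- dd
      for (rows in id_rows) dw$.y[rows] <- dd$.y[sample(rows)]
      fw <- f_of(dw)
      for (e in effects) {
        src <- if (e == ".b") fb else fw
        if (!is.null(src[[e]]) && src[[e]][["F"]] >= obs[[e]][["F"]]) {
          counts[e] <- counts[e] + 1
        }
      }
    }
  })

  pretty <- function(e) {
    e <- gsub("\\.b", between, e)
    for (i in seq_along(within)) {
      e <- gsub(paste0("\\.w", i), within[i], e)
    }
    e
  }
  tabout <- data.frame(
    effect = vapply(effects, pretty, character(1)),
    F = vapply(effects, function(e) obs[[e]][["F"]], numeric(1)),
    df1 = vapply(effects, function(e) obs[[e]][["df1"]], numeric(1)),
    df2 = vapply(effects, function(e) obs[[e]][["df2"]], numeric(1)),
    p_perm = (counts + 1) / (n_perm + 1),
    scheme = ifelse(is_between_main, "between-label permutation",
                    "within-participant cell permutation"),
    row.names = NULL
  )
  structure(list(table = tabout, n_perm = n_perm, seed = seed,
                 between = between, within = within),
            class = "perm_anova")
}

#' @export
print.perm_anova <- function(x, ...) {
  cat("Permutation-based mixed ANOVA (between:", x$between,
      "; within:", paste(x$within, collapse = ", "), ")\n")
  tb <- x$table
  tb$F <- round(tb$F, 3)
  tb$p_perm <- signif(tb$p_perm, 3)
  print(tb, row.names = FALSE)
  cat(sprintf("  %d permutations per scheme\n", x$n_perm))
  invisible(x)
}
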