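#' Replicate medians of a per-cell measurement ("super plot" reduction)
#'
#' Collapses per-cell values to one median per (strain, replicate) group,
#' the reduction underlying a super plot: biological replicates, not cells,
#' are the units of inference. Requires a balanced design -- every strain
#' must appear in every replicate -- because the downstream paired ANOVA
#' blocks on replicate.
#'
#' @param measurements Tibble of per-cell values.
#' @param value Name of the value column (default `"share_old"`).
#' @param strain,replicate Names of the grouping columns.
#' @return A tibble `strain`, `replicate`, `n_cells`, `median_value`.
#' @export
replicate_medians <- function(measurements, value = "share_old",
                              strain = "strain", replicate = "replicate") {
  for (col in c(value, strain, replicate)) {
    if (!col %in% names(measurements)) {
      abort(sprintf("column `%s` not found", col))
    }
  }
  med <- measurements |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(strain = .data[[strain]], replicate = .data[[replicate]]) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     median_value = median(.data[[value]]), .groups = "drop")
  strains <- unique(med$strain)
  reps <- unique(med$replicate)
  full <- tidyr::expand_grid(strain = strains, replicate = reps)
  missing <- dplyr::anti_join(full, med, by = c("strain", "replicate"))
  if (nrow(missing) > 0) {
    abort(paste0("unbalanced design; missing (strain, replicate) group(s): ",
                 paste(sprintf("(%s, %s)", missing$strain, missing$replicate),
                       collapse = ", ")),
          class = "polegrow_balance_error")
  }
  dplyr::arrange(med, .data$strain, .data$replicate)
}

#' Paired one-way ANOVA on replicate medians
#'
#' The "paired one-way ANOVA" of a super plot: a balanced repeated-measures
#' one-way ANOVA treating replicate as a block. With k strains and n
#' replicate blocks,
#' `SS_strain = n * sum((strain mean - grand mean)^2)`,
#' `SS_block = k * sum((block mean - grand mean)^2)`,
#' `SS_error = SS_total - SS_strain - SS_block`, and
#' `F = (SS_strain / (k-1)) / (SS_error / ((k-1)(n-1)))`, with the p-value
#' from the upper tail of the F distribution. When a `reference` strain is
#' given, each other strain is additionally compared against it by the same
#' procedure restricted to the pair (k = 2), with p-values adjusted across
#' comparisons (`"holm"` default, also `"bonferroni"` or `"none"`).
#'
#' A perfectly consistent table (SS_error = 0) is reported as degenerate:
#' `F = Inf`, `p = 0`, `degenerate = TRUE`.
#'
#' @param medians Tibble from [replicate_medians()] (columns `strain`,
#'   `replicate`, `median_value`), or any balanced k x n value table with
#'   those columns.
#' @param reference Optional reference strain for pairwise contrasts.
#' @param adjust Multiplicity adjustment for the pairwise contrasts.
#' @param value Name of the value column (default `"median_value"`).
#' @return An object of class `superplot_anova` with `tidy()` and
#'   `glance()` methods.
#' @examples
#' tb <- tibble::tibble(
#'   strain = rep(c("A", "B"), each = 3),
#'   replicate = rep(1:3, 2),
#'   median_value = c(1, 2, 3, 2, 4, 3)
#' )
#' fit <- paired_oneway_anova(tb)
#' glance(fit) # F = 3 on (1, 2) df
#' @export
paired_oneway_anova <- function(medians, reference = NULL,
                                adjust = c("holm", "bonferroni", "none"),
                                value = "median_value") {
  adjust <- match.arg(adjust)
  tbl <- tibble(strain = as.character(medians$strain),
                replicate = as.character(medians$replicate),
                value = medians[[value]])
  strains <- unique(tbl$strain)
  reps <- unique(tbl$replicate)
  k <- length(strains)
  n <- length(reps)
  if (k < 2 || n < 2) {
    abort("need at least 2 strains and 2 replicate blocks",
          class = "polegrow_precondition_error")
  }
  if (nrow(tbl) != k * n || anyDuplicated(tbl[c("strain", "replicate")]) > 0) {
    abort("`medians` must be a balanced table with one value per (strain, replicate)",
          class = "polegrow_balance_error")
  }

  core <- rm_anova_core(tbl)
  contrasts <- NULL
  if (!is.null(reference)) {
    if (!reference %in% strains) {
      abort(sprintf("reference strain '%s' not present", reference))
    }
    others <- setdiff(strains, reference)
    contrasts <- purrr::map_dfr(others, function(s) {
      sub <- tbl[tbl$strain %in% c(reference, s), ]
      fit <- rm_anova_core(sub)
      tibble(strain = s, reference = reference, F_statistic = fit$F,
             df1 = fit$df1, df2 = fit$df2, p_value = fit$p,
             degenerate = fit$degenerate)
    })
    contrasts$p_adjusted <- stats::p.adjust(contrasts$p_value, method = adjust)
  }

  structure(
    list(medians = medians, k = k, n = n,
         ss_strain = core$ss_strain, ss_block = core$ss_block,
         ss_error = core$ss_error, F_statistic = core$F,
         df_between = core$df1, df_error = core$df2, p_value = core$p,
         degenerate = core$degenerate,
         reference = reference, adjust = adjust, contrasts = contrasts),
    class = "superplot_anova"
  )
}

# repeated-measures one-way ANOVA sums of squares on a long balanced table
rm_anova_core <- function(tbl) {
  k <- length(unique(tbl$strain))
  n <- length(unique(tbl$replicate))
  grand <- mean(tbl$value)
  strain_means <- tapply(tbl$value, tbl$strain, mean)
  block_means <- tapply(tbl$value, tbl$replicate, mean)
  ss_total <- sum((tbl$value - grand)^2)
  ss_strain <- n * sum((strain_means - grand)^2)
  ss_block <- k * sum((block_means - grand)^2)
  ss_error <- ss_total - ss_strain - ss_block
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  degenerate <- ss_error <= max(1e-12 * ss_total, .Machine$double.xmin)
  if (degenerate && ss_strain > 0) {
    f <- Inf
    p <- 0
  } else if (degenerate) {
    f <- 0
    p <- 1
  } else {
    f <- (ss_strain / df1) / (ss_error / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(ss_strain = ss_strain, ss_block = ss_block, ss_error = max(0, ss_error),
       F = f, df1 = df1, df2 = df2, p = p, degenerate = degenerate)
}

#' @export
print.superplot_anova <- function(x, ...) {
  cat("Paired one-way ANOVA on replicate medians (super plot)\n")
  cat(sprintf("  %d strain(s) x %d replicate block(s)\n", x$k, x$n))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g%s\n", x$df_between, x$df_error,
              x$F_statistic, x$p_value,
              if (x$degenerate) " [degenerate: SS_error = 0]" else ""))
  if (!is.null(x$contrasts)) {
    cat(sprintf("  pairwise vs '%s' (%s-adjusted):\n", x$reference, x$adjust))
    for (i in seq_len(nrow(x$contrasts))) {
      cat(sprintf("    %s: F(%d, %d) = %.4g, p_adj = %.4g\n",
                  x$contrasts$strain[i], x$contrasts$df1[i], x$contrasts$df2[i],
                  x$contrasts$F_statistic[i], x$contrasts$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' @describeIn paired_oneway_anova One row per term (strain effect, block,
#'   error) plus the pairwise contrasts when present.
#' @param x A `superplot_anova` object.
#' @param ... Unused.
#' @method tidy superplot_anova
#' @export
tidy.superplot_anova <- function(x, ...) {
  terms <- tibble(
    term = c("strain", "replicate_block", "error"),
    df = c(x$df_between, x$n - 1, x$df_error),
    sumsq = c(x$ss_strain, x$ss_block, x$ss_error),
    statistic = c(x$F_statistic, NA, NA),
    p.value = c(x$p_value, NA, NA)
  )
  if (!is.null(x$contrasts)) {
    terms <- dplyr::bind_rows(terms, tibble(
      term = paste0("contrast: ", x$contrasts$strain, " vs ", x$contrasts$reference),
      df = x$contrasts$df1,
      sumsq = NA_real_,
      statistic = x$contrasts$F_statistic,
      p.value = x$contrasts$p_adjusted
    ))
  }
  terms
}

#' @describeIn paired_oneway_anova One-row model summary.
#' @method glance superplot_anova
#' @export
glance.superplot_anova <- function(x, ...) {
  tibble(
    k = x$k, n = x$n, statistic = x$F_statistic,
    df = x$df_between, df.residual = x$df_error,
    p.value = x$p_value, degenerate = x$degenerate
  )
}
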