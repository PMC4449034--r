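# Two-way fixed-effects ANOVA of editing levels across tissues and
# developmental stages, with the tissue x stage interaction.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Two-way ANOVA of editing levels (tissue, stage, interaction)
#'
#' Fits `editing_level ~ tissue * stage` by least squares on a balanced
#' design and reports the F test of each effect. On a balanced design the
#' sequential (type-I) sums of squares used here coincide with the other
#' SS types, and they are additive. An all-equal response (zero residual
#' sum of squares) leaves the F statistics undefined; such fits are
#' flagged degenerate rather than raising an error.
#'
#' @param measurements Tibble with columns `tissue`, `stage`,
#'   `editing_level` (fractions in `[0, 1]`); every tissue x stage cell
#'   must contain the same number (>= 2) of replicate measurements.
#' @return Object of class `rdd_anova`: a list with `table` (tibble
#'   `effect`, `df`, `sumsq`, `meansq`, `statistic`, `p_value`), `fit`
#'   (the underlying `aov`), `n`, and `degenerate`.
#' @export
anova_tissue_stage <- function(measurements) {
  req <- c("tissue", "stage", "editing_level")
  if (!all(req %in% names(measurements))) {
    abort("measurements need columns tissue, stage, editing_level")
  }
  m <- mutate(measurements,
    tissue = factor(.data$tissue), stage = factor(.data$stage)
  )
  if (nlevels(m$tissue) < 2L || nlevels(m$stage) < 2L) {
    abort("at least two levels per factor are required")
  }
  cells <- count(m, .data$tissue, .data$stage, .drop = FALSE)
  if (length(unique(cells$n)) != 1L || min(cells$n) < 2L) {
    abort(paste0(
      "the design is unbalanced or has cells with fewer than 2 replicates; ",
      "this model expects the balanced design produced by ",
      "generate_editing_level_dataset()"
    ))
  }
  fit <- aov(editing_level ~ tissue * stage, data = m)
  s <- summary(fit)[[1]]
  tab <- tibble(
    effect = c("tissue", "stage", "tissue:stage", "residuals"),
    df = s[["Df"]],
    sumsq = s[["Sum Sq"]],
    meansq = s[["Mean Sq"]],
    statistic = s[["F value"]],
    p_value = s[["Pr(>F)"]]
  )
  # a zero residual SS (all-equal responses within a cell) leaves F
  # undefined; compare on the scale of the data, not the (possibly zero)
  # total SS
  degenerate <- tab$sumsq[tab$effect == "residuals"] <
    1e-10 * max(sum(tab$sumsq), mean(m$editing_level)^2, 1e-8)
  if (degenerate) {
    tab$statistic <- NA_real_
    tab$p_value <- NA_real_
  }
  structure(
    list(table = tab, fit = fit, n = nrow(m), degenerate = degenerate),
    class = "rdd_anova"
  )
}

#' @export
print.rdd_anova <- function(x, ...) {
  cat(sprintf(
    "Two-way ANOVA of editing levels (n = %d%s)\n",
    x$n, if (x$degenerate) ", degenerate: zero residual variance" else ""
  ))
  print(x$table)
  invisible(x)
}

#' Tidy an `rdd_anova` fit
#'
#' @param x An [anova_tissue_stage()] result.
#' @param ... Unused.
#' @return Tibble with one row per model term
#'   (`effect`, `df`, `sumsq`, `meansq`, `statistic`, `p_value`).
#' @importFrom generics tidy
#' @export
tidy.rdd_anova <- function(x, ...) {
  x$table
}

#' One-row summary of an `rdd_anova` fit
#'
#' @param x An [anova_tissue_stage()] result.
#' @param ... Unused.
#' @return One-row tibble: `n`, `df_residual`, `sigma` (residual SD),
#'   `degenerate`.
#' @importFrom generics glance
#' @export
glance.rdd_anova <- function(x, ...) {
  res <- x$table[x$table$effect == "residuals", ]
  tibble(
    n = x$n,
    df_residual = res$df,
    sigma = sqrt(res$meansq),
    degenerate = x$degenerate
  )
}

#' Write an ANOVA table as TSV
#'
#' @param x An [anova_tissue_stage()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anova <- function(x, path) {
  readr::write_tsv(tidy(x), path, progress = FALSE)
  invisible(path)
}
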