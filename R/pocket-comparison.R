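#' Compare binding pockets on their per-repeat NSQ_AUC values
#'
#' Treats each pocket's per-repeat NSQ_AUC values as a group and tests
#' whether pockets differ: a one-way ANOVA followed by Tukey's HSD for more
#' than two pockets, or an unpaired Welch t-test for exactly two. Pairwise
#' results carry significance stars (`*` P<=0.05, `**` 0.01, `***` 0.001,
#' `****` 0.0001) and the direction of superiority.
#'
#' @param data Data frame with one row per (pocket, repeat).
#' @param value,pocket_id Columns (tidy-eval) holding the per-repeat NSQ_AUC
#'   and the pocket identifier. Defaults `nsq_auc`, `pocket_id`.
#' @return An object of class `pocket_comparison` with elements
#'   `per_pocket` (mean, SEM, n per pocket), `omnibus` (method, statistic,
#'   df, p-value) and `pairwise` (estimate = difference in means, p-value,
#'   stars, better pocket per pair). `tidy()` returns the pairwise table,
#'   `glance()` the omnibus row.
#' @examples
#' d <- tibble::tibble(
#'   pocket_id = rep(c("p1", "p2", "p3"), each = 3),
#'   nsq_auc = c(1, 2, 3, 2, 3, 4, 3, 4, 5)
#' )
#' glance(compare_pockets(d))  # F = 3 on (2, 6) df
#' @export
compare_pockets <- function(data, value = nsq_auc, pocket_id = pocket_id) {
  df <- tibble::tibble(
    value = rlang::eval_tidy(rlang::enquo(value), data),
    pocket = as.character(rlang::eval_tidy(rlang::enquo(pocket_id), data))
  )
  pockets <- sort(unique(df$pocket))
  if (length(pockets) < 2L) {
    stop("need at least two pockets to compare.", call. = FALSE)
  }
  sizes <- table(df$pocket)
  if (any(sizes < 2L)) {
    stop("every pocket needs >= 2 repeat values.", call. = FALSE)
  }

  per_pocket <- df |>
    dplyr::group_by(pocket_id = .data$pocket) |>
    dplyr::summarise(
      mean_nsq_auc = mean(.data$value),
      sem = stats::sd(.data$value) / sqrt(dplyr::n()),
      n_repeats = dplyr::n(),
      .groups = "drop"
    )

  df$pocket <- factor(df$pocket, levels = pockets)

  if (length(pockets) == 2L) {
    a <- df$value[df$pocket == pockets[1]]
    b <- df$value[df$pocket == pockets[2]]
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                   error = function(e) NULL)
    omnibus <- tibble::tibble(
      method = "Welch t-test",
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df1 = NA_real_,
      df2 = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p_value = if (is.null(tt)) NA_real_ else tt$p.value
    )
    pairwise <- tibble::tibble(
      pocket_a = pockets[1], pocket_b = pockets[2],
      estimate = mean(a) - mean(b),
      p_value = omnibus$p_value
    )
  } else {
    if (stats::var(df$value) == 0) {
      # all observations identical: 0/0, F undefined
      f_stat <- NA_real_
      omnibus <- tibble::tibble(
        method = "one-way ANOVA", statistic = NA_real_,
        df1 = length(pockets) - 1,
        df2 = nrow(df) - length(pockets), p_value = NA_real_
      )
    } else {
      fit <- stats::aov(value ~ pocket, data = df)
      an <- summary(fit)[[1]]
      f_stat <- an$`F value`[1]
      omnibus <- tibble::tibble(
        method = "one-way ANOVA",
        statistic = f_stat,
        df1 = an$Df[1], df2 = an$Df[2],
        p_value = an$`Pr(>F)`[1]
      )
    }
    if (is.na(f_stat)) {
      warning("zero residual variance: F undefined; pairwise tests skipped.",
              call. = FALSE)
      pairwise <- tibble::tibble(
        pocket_a = character(), pocket_b = character(),
        estimate = double(), p_value = double()
      )
    } else {
      tk <- stats::TukeyHSD(fit)$pocket
      pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- tibble::tibble(
        pocket_a = purrr::map_chr(pair_names, 1),
        pocket_b = purrr::map_chr(pair_names, 2),
        estimate = tk[, "diff"],
        p_value = tk[, "p adj"]
      )
    }
  }

  pairwise <- pairwise |>
    dplyr::mutate(
      stars = significance_stars(.data$p_value),
      better = dplyr::case_when(
        .data$p_value > 0.05 | is.na(.data$p_value) ~ NA_character_,
        .data$estimate > 0 ~ .data$pocket_a,
        TRUE ~ .data$pocket_b
      )
    )

  structure(
    list(per_pocket = per_pocket, omnibus = omnibus, pairwise = pairwise),
    class = "pocket_comparison"
  )
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' @export
print.pocket_comparison <- function(x, ...) {
  cat("<pocket_comparison>\n")
  cat(sprintf("  %s: statistic %.3f, p = %.3g\n",
              x$omnibus$method, x$omnibus$statistic, x$omnibus$p_value))
  print(x$per_pocket)
  print(x$pairwise)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pocket_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.pocket_comparison <- function(x, ...) x$omnibus
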