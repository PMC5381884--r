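#' Enrichment factors at fractions of the ranked database, by chemotype
#'
#' The enrichment factor at x% measures how over-represented a chemotype's
#' true positives are among the top x% of the ranked screened database:
#'
#' \deqn{EF_x = \frac{TP_x / N_x}{TP / N}}
#'
#' where `N` is the total number of screened compounds, `N_x = round(x N /
#' 100)` (at least 1) the number in the top fraction, `TP` the chemotype's
#' true positives overall and `TP_x` those found in the top fraction. EF of 1
#' means no enrichment; the maximum is `N / N_x` (capped by `N / TP` when the
#' chemotype is larger than the fraction).
#'
#' @param data Ranked score table, one row per compound (use
#'   [best_of_repeats()] first). Must carry score, class-label and chemotype
#'   columns.
#' @param x_percent Fractions of the ranked database, in percent
#'   (default `c(2, 5, 10)`).
#' @param chemotypes Chemotype labels to evaluate; defaults to every
#'   chemotype present among true positives, plus `"all"`, which pools every
#'   true positive.
#' @param score,label,chemotype Columns (tidy-eval).
#' @param positive True-positive value of `label`.
#' @param lower_is_better Score direction.
#' @return A tibble of class `vs_enrichment` with columns `chemotype`,
#'   `x_percent`, `tp`, `n`, `tp_x`, `n_x` and `ef`. Chemotypes with no true
#'   positives yield `NA` with a warning. `autoplot()` draws the EF bars.
#' @examples
#' tbl <- tibble::tibble(
#'   score = 1:10, class_label = rep(c("active", "decoy"), 5),
#'   chemotype = "A"
#' )
#' enrichment_factor(tbl, x_percent = 10)
#' @export
enrichment_factor <- function(data, x_percent = c(2, 5, 10),
                              chemotypes = NULL,
                              score = score, label = class_label,
                              chemotype = chemotype, positive = "active",
                              lower_is_better = TRUE) {
  df <- tibble::tibble(
    score = rlang::eval_tidy(rlang::enquo(score), data),
    class_label = rlang::eval_tidy(rlang::enquo(label), data),
    chemotype = as.character(rlang::eval_tidy(rlang::enquo(chemotype), data))
  )
  stopifnot(all(x_percent > 0), all(x_percent <= 100))
  n <- nrow(df)
  s <- if (lower_is_better) df$score else -df$score
  df <- df[order(s), ]
  is_tp <- df$class_label == positive

  if (is.null(chemotypes)) {
    chemotypes <- c(sort(unique(df$chemotype[is_tp])), "all")
  }

  res <- tidyr::expand_grid(chemotype = chemotypes, x_percent = x_percent) |>
    purrr::pmap_dfr(function(chemotype, x_percent) {
      in_chem <- if (chemotype == "all") is_tp else {
        is_tp & df$chemotype == chemotype
      }
      tp <- sum(in_chem)
      n_x <- max(1L, round_half_up(x_percent * n / 100))
      tp_x <- sum(in_chem[seq_len(n_x)])
      ef <- if (tp == 0L) NA_real_ else (tp_x / n_x) / (tp / n)
      tibble::tibble(
        chemotype = chemotype, x_percent = x_percent,
        tp = tp, n = n, tp_x = tp_x, n_x = n_x, ef = ef
      )
    })
  if (anyNA(res$ef)) {
    warning(sprintf(
      "no true positives for chemotype(s): %s; EF undefined.",
      paste(unique(res$chemotype[is.na(res$ef)]), collapse = ", ")
    ), call. = FALSE)
  }
  class(res) <- c("vs_enrichment", class(res))
  res
}

# deterministic commercial rounding (round() halves-to-even would make
# N_x depend on parity)
round_half_up <- function(x) floor(x + 0.5)

#' @exportS3Method ggplot2::autoplot
autoplot.vs_enrichment <- function(object, ...) {
  object$x_percent <- factor(
    paste0("EF", object$x_percent),
    levels = paste0("EF", sort(unique(object$x_percent)))
  )
  ggplot2::ggplot(
    object,
    ggplot2::aes(.data$chemotype, .data$ef, fill = .data$x_percent)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Chemotype", y = "Enrichment factor", fill = NULL) +
    ggplot2::theme_bw()
}
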