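#' Collapse repeated dockings to the best score per ligand and pocket
#'
#' Docking with stochastic conformational sampling is run several times per
#' ligand; the best-scoring repeat is retained to represent that ligand's
#' score against a pocket. Any other columns (class label, chemotype) are
#' carried from the retained row.
#'
#' @param data Long-format score table with one row per
#'   (ligand, pocket, repeat).
#' @param score,ligand_id,pocket_id Columns (tidy-eval) holding the docking
#'   score and grouping identifiers. `pocket_id` may be absent from the data,
#'   in which case grouping is by ligand only.
#' @param lower_is_better Score direction; docking energies default to
#'   lower-is-better.
#' @return A tibble with one row per (ligand, pocket) carrying the best
#'   score. Deterministic: ties keep the lowest repeat index (or first row).
#' @examples
#' tbl <- tibble::tibble(
#'   ligand_id = "L1", pocket_id = "p", repeat_idx = 1:3,
#'   score = c(-20, -25, -22)
#' )
#' best_of_repeats(tbl)$score  # -25
#' @export
best_of_repeats <- function(data, score = score, ligand_id = ligand_id,
                            pocket_id = pocket_id, lower_is_better = TRUE) {
  score_q <- rlang::enquo(score)
  lig_q <- rlang::enquo(ligand_id)
  poc_q <- rlang::enquo(pocket_id)
  has_pocket <- tryCatch(
    {rlang::eval_tidy(poc_q, data); TRUE},
    error = function(e) FALSE
  )
  grps <- if (has_pocket) list(lig_q, poc_q) else list(lig_q)
  s_dir <- if (lower_is_better) 1 else -1
  data |>
    dplyr::group_by(!!!grps) |>
    dplyr::arrange(s_dir * !!score_q, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Per-repeat NSQ_AUC with mean and standard error
#'
#' Computes one ROC curve and NSQ_AUC per docking repeat (no best-of-repeats
#' pooling), then summarizes across repeats as mean +/- SEM, the quantity
#' reported in ROC-figure insets. Ligands missing any repeat are dropped
#' with a warning so every repeat's ROC is built on the same compound set.
#'
#' @inheritParams best_of_repeats
#' @param label Column holding the two-level class label (tidy-eval).
#' @param repeat_idx Column holding the repeat index (tidy-eval).
#' @param positive Value of `label` counted as true positive.
#' @return An object of class `nsq_repeats`: tibble `per_repeat`
#'   (`repeat_idx`, `nsq_auc`, `auc`) plus `mean`, `sem` and `n_repeats`.
#'   `tidy()` returns the per-repeat table; `glance()` the summary row.
#' @export
per_repeat_nsq <- function(data, score = score, label = class_label,
                           ligand_id = ligand_id, repeat_idx = repeat_idx,
                           positive = "active", lower_is_better = TRUE) {
  df <- tibble::tibble(
    ligand_id = rlang::eval_tidy(rlang::enquo(ligand_id), data),
    repeat_idx = rlang::eval_tidy(rlang::enquo(repeat_idx), data),
    score = rlang::eval_tidy(rlang::enquo(score), data),
    class_label = rlang::eval_tidy(rlang::enquo(label), data)
  )
  reps <- sort(unique(df$repeat_idx))
  if (length(reps) < 2L) {
    stop("per-repeat statistics need at least 2 repeats (SEM undefined).",
         call. = FALSE)
  }
  complete <- df |>
    dplyr::distinct(.data$ligand_id, .data$repeat_idx) |>
    dplyr::count(.data$ligand_id) |>
    dplyr::filter(.data$n == length(reps)) |>
    dplyr::pull(.data$ligand_id)
  n_drop <- dplyr::n_distinct(df$ligand_id) - length(complete)
  if (n_drop > 0L) {
    warning(sprintf("%d ligand(s) with incomplete repeats dropped.", n_drop),
            call. = FALSE)
    df <- dplyr::filter(df, .data$ligand_id %in% complete)
  }

  per_repeat <- purrr::map_dfr(reps, function(r) {
    roc <- compute_roc(
      dplyr::filter(df, .data$repeat_idx == r),
      positive = positive, lower_is_better = lower_is_better
    )
    tibble::tibble(repeat_idx = r, nsq_auc = roc$nsq_auc, auc = roc$auc)
  })

  structure(
    list(
      per_repeat = per_repeat,
      mean = mean(per_repeat$nsq_auc),
      sem = stats::sd(per_repeat$nsq_auc) / sqrt(nrow(per_repeat)),
      n_repeats = nrow(per_repeat),
      n_dropped = n_drop
    ),
    class = "nsq_repeats"
  )
}

#' @export
print.nsq_repeats <- function(x, ...) {
  cat(sprintf("<nsq_repeats> %d repeats: mean NSQ_AUC %.2f +/- %.2f (SEM)\n",
              x$n_repeats, x$mean, x$sem))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nsq_repeats <- function(x, ...) x$per_repeat

#' @exportS3Method generics::glance
glance.nsq_repeats <- function(x, ...) {
  tibble::tibble(
    mean_nsq_auc = x$mean, sem = x$sem,
    n_repeats = x$n_repeats, n_dropped = x$n_dropped
  )
}
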