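#' Build an ROC step curve from a ranked score table
#'
#' Constructs the receiver operating characteristic curve for one binding
#' pocket by sweeping the docking-score threshold from best to worst and
#' recording, at each distinct score, the fraction of true positives (TPR)
#' and false positives (FPR) recovered so far. Tied scores advance true and
#' false positives jointly, producing a diagonal segment, so the curve does
#' not depend on the input row order.
#'
#' @param data A data frame with one row per screened compound (typically the
#'   output of [best_of_repeats()] for a single pocket and repeat set).
#' @param score Column holding the docking score (tidy-eval). Default `score`.
#' @param label Column holding the two-level class label (tidy-eval).
#'   Default `class_label`.
#' @param positive Value of `label` treated as the true-positive class.
#' @param lower_is_better Score direction. Docking energies are
#'   lower-is-better; set `FALSE` for probability-like scores.
#'
#' @return An object of class `vs_roc`: a list with `points` (tibble of
#'   `fpr`, `tpr`), `auc`, `sq_auc`, `sq_auc_perfect`, `sq_auc_random`,
#'   `nsq_auc`, `n_tp`, `n_fp` and the `positive` label used.
#'   `tidy()` returns the curve points, `glance()` the scalar metrics, and
#'   `autoplot()` draws the curve with the random diagonal and an NSQ_AUC
#'   inset.
#'
#' @details The early-recovery summary reported in `nsq_auc` is the
#'   normalized square-root AUC: the area under TPR as a function of
#'   \eqn{u = \sqrt{FPR}}, rescaled so that perfect retrieval scores 100 and
#'   the random diagonal scores 0 (see [nsq_auc()]).
#'
#' @examples
#' tbl <- tibble::tibble(
#'   score = c(-30, -20, -10, -5),
#'   class_label = c("active", "decoy", "active", "decoy")
#' )
#' r <- compute_roc(tbl)
#' glance(r)
#' @export
compute_roc <- function(data, score = score, label = class_label,
                        positive = "active", lower_is_better = TRUE) {
  score <- rlang::eval_tidy(rlang::enquo(score), data)
  label <- rlang::eval_tidy(rlang::enquo(label), data)
  if (length(score) != length(label) || length(score) == 0L) {
    stop("`data` must supply non-empty, equal-length score and label columns.",
         call. = FALSE)
  }
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]
  label <- label[keep]

  lv <- unique(label)
  if (!positive %in% lv) {
    stop(sprintf("positive class '%s' absent from the label column.", positive),
         call. = FALSE)
  }
  if (length(lv) != 2L) {
    stop(sprintf(
      "ROC needs exactly two class labels; found %d (%s).",
      length(lv), paste(lv, collapse = ", ")
    ), call. = FALSE)
  }

  is_tp <- label == positive
  n_tp <- sum(is_tp)
  n_fp <- sum(!is_tp)
  if (n_tp == 0L || n_fp == 0L) {
    stop("one class is empty; cannot build an ROC curve.", call. = FALSE)
  }

  # orient so larger is better, then sweep thresholds over distinct scores
  s <- if (lower_is_better) -score else score
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  tp <- is_tp[o]
  grp <- cumsum(!duplicated(s))        # tie blocks share a group id
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  last <- !duplicated(grp, fromLast = TRUE)

  points <- tibble::tibble(
    fpr = c(0, cum_fp[last] / n_fp),
    tpr = c(0, cum_tp[last] / n_tp)
  )

  auc <- trapezoid_area(points$fpr, points$tpr)
  sq <- sqrt_axis_area(points$fpr, points$tpr)
  sq_perfect <- 1
  sq_random <- 1 / 3

  structure(
    list(
      points = points,
      auc = auc,
      sq_auc = sq,
      sq_auc_perfect = sq_perfect,
      sq_auc_random = sq_random,
      nsq_auc = 100 * (sq - sq_random) / (sq_perfect - sq_random),
      n_tp = n_tp,
      n_fp = n_fp,
      positive = positive
    ),
    class = "vs_roc"
  )
}

# trapezoid rule on the step/diagonal curve
trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Exact area under TPR as a function of u = sqrt(FPR). On each segment TPR is
# linear in FPR, i.e. quadratic in u, so the piece integrates in closed form;
# the diagonal TPR = FPR therefore yields exactly 1/3.
sqrt_axis_area <- function(fpr, tpr) {
  f1 <- utils::head(fpr, -1); f2 <- utils::tail(fpr, -1)
  t1 <- utils::head(tpr, -1); t2 <- utils::tail(tpr, -1)
  run <- f2 > f1
  s <- ifelse(run, (t2 - t1) / (f2 - f1), 0)
  u1 <- sqrt(f1); u2 <- sqrt(f2)
  sum(((t1 - s * f1) * (u2 - u1) + s * (u2^3 - u1^3) / 3)[run])
}

#' Normalized square-root AUC of an ROC curve
#'
#' The early-recovery statistic used to compare binding pockets. The ROC's
#' false-positive axis is square-root transformed, which up-weights the early
#' part of the ranked list, and the area under the transformed curve
#' (`SQ_AUC`) is normalized between the perfect curve (area 1 for any class
#' counts) and the random diagonal (area \eqn{\int_0^1 u^2 du = 1/3}):
#'
#' \deqn{NSQ\_AUC = 100 \, \frac{SQ\_AUC - SQ\_AUC_{random}}
#'                             {SQ\_AUC_{perfect} - SQ\_AUC_{random}}}
#'
#' Perfect retrieval scores 100, random scores 0, and curves that rank false
#' positives ahead of true positives are negative, down to -50 for the worst
#' possible ranking.
#'
#' @param roc A `vs_roc` object from [compute_roc()], or a data frame of
#'   curve points with columns `fpr` and `tpr` (monotone, from (0,0) to
#'   (1,1)).
#' @return A single number in \[-50, 100\].
#' @export
nsq_auc <- function(roc) {
  if (inherits(roc, "vs_roc")) return(roc$nsq_auc)
  if (is.data.frame(roc) && all(c("fpr", "tpr") %in% names(roc))) {
    sq <- sqrt_axis_area(roc$fpr, roc$tpr)
    return(100 * (sq - 1 / 3) / (1 - 1 / 3))
  }
  stop("`roc` must be a vs_roc object or a data frame with fpr and tpr.",
       call. = FALSE)
}

#' @export
print.vs_roc <- function(x, ...) {
  cat(sprintf(
    "<vs_roc> %d true positives vs %d false positives\n", x$n_tp, x$n_fp
  ))
  cat(sprintf("  AUC      %.4f\n", x$auc))
  cat(sprintf("  SQ_AUC   %.4f  (perfect %.3f, random %.3f)\n",
              x$sq_auc, x$sq_auc_perfect, x$sq_auc_random))
  cat(sprintf("  NSQ_AUC  %.2f\n", x$nsq_auc))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.vs_roc <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.vs_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, sq_auc = x$sq_auc, nsq_auc = x$nsq_auc,
    n_tp = x$n_tp, n_fp = x$n_fp
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.vs_roc <- function(object, colour = "#2166ac", ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         colour = "black", linewidth = 0.3) +
    ggplot2::geom_step(colour = colour, linewidth = 0.8) +
    ggplot2::annotate(
      "text", x = 0.95, y = 0.05, hjust = 1,
      label = sprintf("NSQ_AUC = %.1f", object$nsq_auc)
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positives recovered (fraction)",
      y = "True positives recovered (fraction)"
    ) +
    ggplot2::theme_bw()
}

#' Rank of a named compound on the ROC's false-positive axis
#'
#' Reports the FPR at which a given compound (typically the co-crystallized
#' cognate ligand) is recovered in the ranked list — the position marked by
#' the vertical dashed line on ROC figures.
#'
#' @inheritParams compute_roc
#' @param ligand_id Column holding compound identifiers (tidy-eval).
#' @param id Identifier of the compound of interest.
#' @return The FPR (fraction in \[0, 1\]) at the compound's rank.
#' @export
ligand_rank_fpr <- function(data, id, score = score, label = class_label,
                            ligand_id = ligand_id, positive = "active",
                            lower_is_better = TRUE) {
  score <- rlang::eval_tidy(rlang::enquo(score), data)
  label <- rlang::eval_tidy(rlang::enquo(label), data)
  ids <- rlang::eval_tidy(rlang::enquo(ligand_id), data)
  if (!id %in% ids) {
    stop(sprintf("ligand '%s' not present in the table.", id), call. = FALSE)
  }
  s <- if (lower_is_better) -score else score
  n_fp <- sum(label != positive)
  # false positives strictly better than the compound's score (ties excluded)
  sum(s > s[ids == id][1] & label != positive) / n_fp
}
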