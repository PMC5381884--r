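#' Simulate a docking-score table with known ground truth
#'
#' Emulates the output of a stochastic docking engine screening a known
#' ligand library against decoys, following the 39-decoys-per-active
#' convention of GPCR decoy databases. Each compound draws a latent score
#' once — decoys from Normal(`baseline`, `score_sd`^2), actives shifted
#' better (lower) by `effect_size` plus a chemotype-specific shift — and each
#' docking repeat adds independent Normal(0, `repeat_noise_sd`^2)
#' perturbation. Lower scores are better throughout.
#'
#' @param n_actives Number of known ligands (default 50).
#' @param decoys_per_active Decoys per active (default 39, the GDD ratio).
#' @param n_repeats Docking repeats per compound (default 3).
#' @param effect_size Mean score improvement of actives over decoys, in
#'   score units. 0 means actives are indistinguishable from decoys.
#' @param baseline Decoy mean score (energy-like units; default -20).
#' @param score_sd Between-compound score spread (default 3).
#' @param repeat_noise_sd Repeat-to-repeat docking noise (default 0.3).
#' @param chemotype_profile Named list mapping chemotype labels to
#'   `c(fraction, shift)`: the fraction of actives in that chemotype (must
#'   sum to 1) and an extra additive score shift (negative = docks better).
#' @param pocket_id Pocket label stamped on every row.
#' @param seed Integer seed; identical arguments and seed reproduce the
#'   table exactly.
#' @return A tibble with columns `ligand_id`, `pocket_id`, `repeat_idx`,
#'   `score`, `class_label` (`"active"`/`"decoy"`), `pharmacology` and
#'   `chemotype` (decoys carry `"other"`).
#' @examples
#' tbl <- simulate_scores(n_actives = 5, effect_size = 6, seed = 1)
#' nrow(tbl)  # (5 + 5 * 39) * 3
#' @export
simulate_scores <- function(n_actives = 50, decoys_per_active = 39,
                            n_repeats = 3, effect_size = 3,
                            baseline = -20, score_sd = 3,
                            repeat_noise_sd = 0.3,
                            chemotype_profile = list(
                              A = c(0.4, -1), B = c(0.3, 0),
                              C = c(0.2, 0), D = c(0.1, 1)
                            ),
                            pocket_id = "pocket1", seed = NULL) {
  if (n_actives < 1 || decoys_per_active < 1 || n_repeats < 1) {
    stop("counts must be positive.", call. = FALSE)
  }
  fracs <- purrr::map_dbl(chemotype_profile, 1)
  shifts <- purrr::map_dbl(chemotype_profile, 2)
  if (abs(sum(fracs) - 1) > 1e-8) {
    stop("chemotype fractions must sum to 1.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n_decoys <- n_actives * decoys_per_active
  # largest-remainder apportionment of actives to chemotypes
  raw <- fracs * n_actives
  counts <- floor(raw)
  rem <- n_actives - sum(counts)
  if (rem > 0) {
    top_up <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top_up] <- counts[top_up] + 1L
  }
  chem <- rep(names(chemotype_profile), counts)

  compounds <- tibble::tibble(
    ligand_id = c(
      sprintf("ACT%04d", seq_len(n_actives)),
      sprintf("DEC%05d", seq_len(n_decoys))
    ),
    class_label = rep(c("active", "decoy"), c(n_actives, n_decoys)),
    pharmacology = rep(c("agonist", "unknown"), c(n_actives, n_decoys)),
    chemotype = c(chem, rep("other", n_decoys)),
    mu = c(
      baseline - effect_size + shifts[match(chem, names(chemotype_profile))],
      rep(baseline, n_decoys)
    )
  )
  compounds$latent <- stats::rnorm(nrow(compounds), compounds$mu, score_sd)

  tidyr::expand_grid(compounds, repeat_idx = seq_len(n_repeats)) |>
    dplyr::mutate(
      pocket_id = pocket_id,
      score = .data$latent +
        stats::rnorm(dplyr::n(), 0, repeat_noise_sd)
    ) |>
    dplyr::select(
      "ligand_id", "pocket_id", "repeat_idx", "score",
      "class_label", "pharmacology", "chemotype"
    )
}

#' Simulate several pockets with distinct screening power
#'
#' Convenience wrapper around [simulate_scores()]: one score table per
#' pocket, each with its own active/decoy separation, row-bound into one
#' long table. The same compound set size and chemotype profile is used for
#' every pocket; each pocket draws independent scores.
#'
#' @param effect_sizes Named numeric vector: pocket id -> effect size in
#'   score units.
#' @param seed Integer seed controlling all pockets.
#' @param ... Passed to [simulate_scores()].
#' @return A tibble in the same shape as [simulate_scores()].
#' @export
simulate_pockets <- function(effect_sizes, seed = NULL, ...) {
  if (is.null(names(effect_sizes))) {
    names(effect_sizes) <- sprintf("pocket%d", seq_along(effect_sizes))
  }
  if (!is.null(seed)) set.seed(seed)
  purrr::imap_dfr(
    effect_sizes,
    function(es, id) simulate_scores(effect_size = es, pocket_id = id, ...)
  )
}
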