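#' Run the full screening-evaluation stage
#'
#' End-to-end evaluation of one score table: best-of-repeats ROC per pocket
#' for the requested contrast(s), per-repeat NSQ_AUC mean +/- SEM,
#' chemotype enrichment factors, and the cross-pocket comparison statistics
#' (skipped with a notice when only one pocket is present). Figures and CSV
#' tables are written under `output_dir` together with a JSON manifest
#' (configuration, input hashes, versions) sufficient to reproduce the run.
#'
#' @param scores Score table (tibble or CSV path) with columns `ligand_id`,
#'   `pocket_id`, `repeat_idx`, `score`, `class_label` and optionally
#'   `pharmacology`, `chemotype`.
#' @param output_dir Output directory (created if needed).
#' @param contrasts Which contrasts to evaluate: `"decoys"` (actives vs
#'   decoys) and/or `"pharmacology"` (agonists vs inhibitors).
#' @param ef_fractions EF percentages (default `c(2, 5, 10)`).
#' @param lower_is_better Score direction.
#' @param write_plots Write ROC/EF figures (PNG) alongside the CSVs.
#' @return Invisibly, a list: `roc` (per pocket x contrast `vs_roc`),
#'   `repeat_stats`, `enrichment`, `comparison`, `metrics` (summary
#'   tibble), and `manifest_file`.
#' @export
run_screen_eval <- function(scores, output_dir,
                            contrasts = c("decoys", "pharmacology"),
                            ef_fractions = c(2, 5, 10),
                            lower_is_better = TRUE, write_plots = TRUE) {
  scores_path <- NULL
  if (is.character(scores)) {
    scores_path <- scores
    scores <- tibble::as_tibble(utils::read.csv(scores))
  }
  required <- c("ligand_id", "pocket_id", "repeat_idx", "score", "class_label")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols) > 0) {
    stop(sprintf("score table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(scores$class_label)) {
    bad <- unique(scores$ligand_id[is.na(scores$class_label)])
    stop(sprintf("missing class labels for: %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  if (!"chemotype" %in% names(scores)) scores$chemotype <- "other"
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  pockets <- sort(unique(scores$pocket_id))
  contrasts <- match.arg(contrasts, several.ok = TRUE)

  contrast_spec <- list(
    decoys = list(label_col = "class_label", positive = "active"),
    pharmacology = list(label_col = "pharmacology", positive = "agonist")
  )

  roc_list <- list()
  repeat_rows <- list()
  ef_list <- list()
  metrics <- list()

  for (ctr in contrasts) {
    cs <- contrast_spec[[ctr]]
    if (!cs$label_col %in% names(scores)) next
    labs <- scores[[cs$label_col]]
    sub <- scores[labs %in% contrast_levels(ctr), ]
    if (dplyr::n_distinct(sub[[cs$label_col]]) < 2) next
    for (p in pockets) {
      sp <- sub[sub$pocket_id == p, ]
      best <- best_of_repeats(sp, lower_is_better = lower_is_better)
      roc <- compute_roc(
        best, label = !!rlang::sym(cs$label_col), positive = cs$positive,
        lower_is_better = lower_is_better
      )
      key <- paste(p, ctr, sep = ".")
      roc_list[[key]] <- roc
      reps <- per_repeat_nsq(
        sp, label = !!rlang::sym(cs$label_col), positive = cs$positive,
        lower_is_better = lower_is_better
      )
      repeat_rows[[key]] <- glance(reps) |>
        dplyr::mutate(pocket_id = p, contrast = ctr, .before = 1)
      metrics[[key]] <- glance(roc) |>
        dplyr::mutate(pocket_id = p, contrast = ctr, .before = 1)
      if (ctr == "decoys") {
        ef_list[[p]] <- enrichment_factor(
          best, x_percent = ef_fractions, positive = cs$positive,
          lower_is_better = lower_is_better
        ) |>
          dplyr::mutate(pocket_id = p, .before = 1)
      }
      if (write_plots) {
        ggplot2::ggsave(
          file.path(output_dir, sprintf("roc_%s_%s.png", p, ctr)),
          autoplot(roc), width = 4.5, height = 4.5, dpi = 150
        )
      }
    }
  }

  repeat_stats <- dplyr::bind_rows(repeat_rows)
  enrichment <- dplyr::bind_rows(ef_list)
  metrics <- dplyr::bind_rows(metrics)

  comparison <- NULL
  if (length(pockets) >= 2) {
    comparison <- purrr::map(contrasts, function(ctr) {
      keys <- paste(pockets, ctr, sep = ".")
      keys <- keys[keys %in% names(roc_list)]
      if (length(keys) < 2) return(NULL)
      per <- purrr::map_dfr(keys, function(k) {
        p <- sub(paste0(".", ctr), "", k, fixed = TRUE)
        sp <- scores[scores$pocket_id == p, ]
        cs <- contrast_spec[[ctr]]
        sp <- sp[sp[[cs$label_col]] %in% contrast_levels(ctr), ]
        tidy(per_repeat_nsq(
          sp, label = !!rlang::sym(cs$label_col), positive = cs$positive,
          lower_is_better = lower_is_better
        )) |>
          dplyr::mutate(pocket_id = p)
      })
      compare_pockets(per)
    }) |> stats::setNames(contrasts)
    comparison <- purrr::compact(comparison)
    for (ctr in names(comparison)) {
      utils::write.csv(
        tidy(comparison[[ctr]]),
        file.path(output_dir, sprintf("comparison_%s.csv", ctr)),
        row.names = FALSE
      )
    }
  } else {
    message("single pocket: cross-pocket statistics skipped.")
  }

  utils::write.csv(metrics, file.path(output_dir, "roc_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(repeat_stats, file.path(output_dir, "repeat_stats.csv"),
                   row.names = FALSE)
  if (nrow(enrichment) > 0) {
    utils::write.csv(enrichment, file.path(output_dir, "enrichment.csv"),
                     row.names = FALSE)
    if (write_plots) {
      for (p in unique(enrichment$pocket_id)) {
        ggplot2::ggsave(
          file.path(output_dir, sprintf("ef_%s.png", p)),
          autoplot(enrichment[enrichment$pocket_id == p, ]),
          width = 5, height = 3.5, dpi = 150
        )
      }
    }
  }

  manifest_file <- write_manifest(
    output_dir,
    config = list(
      contrasts = contrasts, ef_fractions = ef_fractions,
      lower_is_better = lower_is_better
    ),
    inputs = scores_path
  )

  invisible(list(
    roc = roc_list, repeat_stats = repeat_stats, enrichment = enrichment,
    comparison = comparison, metrics = metrics, manifest_file = manifest_file
  ))
}

contrast_levels <- function(ctr) {
  if (ctr == "decoys") c("active", "decoy") else c("agonist", "inhibitor")
}

#' Run the structural-comparison stage
#'
#' Loads a group of co-complexes sharing a ligand, superposes them,
#' computes pairwise ligand/pocket RMSD matrices and residue-aligned
#' interaction fingerprints, and (when a quality table is supplied) the
#' per-residue RSCC/B-factor flags. CSV tables, figures and a manifest are
#' written under `output_dir`.
#'
#' @param pdb_files Named character vector of PDB paths (names become
#'   complex ids), or a list of `gpcr_complex` objects.
#' @param ligand_code 3-letter ligand code shared by the group.
#' @param output_dir Output directory.
#' @param radius Pocket radius in angstroms (default 5).
#' @param quality_table Optional per-residue RSCC/B-factor table (see
#'   [quality_report()]).
#' @param write_plots Write the heat-map/quality figures.
#' @return Invisibly: `group` (superposed), `rmsd` (matrices), `ifp`
#'   (list of `ifp_matrix`), `heatmap`, `quality`, `manifest_file`.
#' @export
run_structure_compare <- function(pdb_files, ligand_code, output_dir,
                                  radius = 5, quality_table = NULL,
                                  write_plots = TRUE) {
  complexes <- if (is.character(pdb_files)) {
    ids <- names(pdb_files)
    if (is.null(ids)) ids <- sub("\\.pdb$", "", basename(pdb_files))
    purrr::map2(pdb_files, ids,
                ~ load_complex(.x, ligand_code, complex_id = .y))
  } else {
    pdb_files
  }
  if (length(complexes) < 2) {
    stop("need at least two complexes to compare.", call. = FALSE)
  }
  codes <- unique(purrr::map_chr(complexes, ~ .x$ligand$code))
  if (length(codes) != 1) {
    stop(sprintf("mismatched ligand codes: %s.", paste(codes, collapse = ", ")),
         call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  group <- superpose_group(complexes)
  mats <- rmsd_matrices(group)
  utils::write.csv(mats$ligand, file.path(output_dir, "ligand_rmsd.csv"))
  utils::write.csv(mats$pocket, file.path(output_dir, "pocket_rmsd.csv"))

  ifps <- purrr::map(group$complexes, compute_ifp, pocket = group$pocket)
  hm <- ifp_heatmap(ifps)
  utils::write.csv(hm$table, file.path(output_dir, "ifp.csv"),
                   row.names = FALSE)
  if (write_plots) {
    ggplot2::ggsave(file.path(output_dir, "ifp_heatmap.png"), hm$plot,
                    width = 7, height = 1.2 + length(ifps) * 1.2, dpi = 150)
  }

  quality <- NULL
  if (!is.null(quality_table)) {
    quality <- quality_report(quality_table, group$pocket)
    utils::write.csv(quality, file.path(output_dir, "quality.csv"),
                     row.names = FALSE)
    if (write_plots) {
      ggplot2::ggsave(file.path(output_dir, "quality.png"),
                      autoplot(quality), width = 6, height = 3.5, dpi = 150)
    }
  }

  manifest_file <- write_manifest(
    output_dir,
    config = list(ligand_code = ligand_code, radius = radius),
    inputs = if (is.character(pdb_files)) pdb_files else NULL
  )

  invisible(list(
    group = group, rmsd = mats, ifp = ifps, heatmap = hm,
    quality = quality, manifest_file = manifest_file
  ))
}

write_manifest <- function(output_dir, config, inputs = NULL) {
  manifest <- list(
    package = "vspocket",
    version = as.character(utils::packageVersion("vspocket")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    input_md5 = if (!is.null(inputs)) {
      as.list(tools::md5sum(inputs))
    } else NULL
  )
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}
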