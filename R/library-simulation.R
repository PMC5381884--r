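#' Simulate a known-ligand SDF library with scaffold families
#'
#' Builds a small-molecule library from distinct chemical scaffold families
#' (benzimidazoles, biphenyls, cyclohexane amides, pyridylmethyl amides),
#' varying a substituent within each family so that within-family structural
#' dissimilarity is much smaller than between-family dissimilarity — the
#' situation chemotype clustering assumes. A configurable fraction of
#' molecules carries one or two stereocenters, and a configurable number of
#' enantiomer-double pairs (the same constitution deposited twice in
#' opposite configurations, as happens in ligand databases built from
#' racemic assay data) exercises deduplication.
#'
#' @param family_sizes Integer vector (length <= 4): molecules per scaffold
#'   family. Default `c(4, 3, 3, 2)`.
#' @param stereo_fraction Fraction of molecules given a chiral substituent
#'   (default 0.5). A fraction of 0 yields an achiral library.
#' @param n_enantiomer_pairs Number of molecules additionally deposited as
#'   their opposite enantiomer under a new id (default 0).
#' @param dir Directory for the output files (created if needed).
#' @param seed Integer seed; output files are byte-identical per seed.
#' @return A list: `sdf_file`, `labels_file` and `truth` — a tibble
#'   (`ligand_id`, `family`, `smiles`, `n_stereocenters`,
#'   `is_enantiomer_double`) recording the generating ground truth.
#' @export
simulate_library <- function(family_sizes = c(4, 3, 3, 2),
                             stereo_fraction = 0.5,
                             n_enantiomer_pairs = 0,
                             dir = tempdir(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(family_sizes) <= 4, all(family_sizes >= 1))

  scaffolds <- c(
    "c1ccc2[nH]c(%s)nc2c1",        # benzimidazole
    "c1ccc(-c2ccc(%s)cc2)cc1",     # biphenyl
    "C1CCCCC1C(=O)N%s",            # cyclohexane carboxamide
    "c1cc(cnc1)CNC(=O)%s"          # pyridylmethyl amide
  )[seq_along(family_sizes)]
  achiral_subs <- c("C", "CC", "CCC", "CCCC", "CCl", "CCO", "CC(C)C", "CCF")
  chiral_subs <- list(
    list(plain = "C(C)O",      ent = c("[C@H](C)O", "[C@@H](C)O"),    n = 1L),
    list(plain = "C(C)CO",     ent = c("[C@H](C)CO", "[C@@H](C)CO"),  n = 1L),
    list(plain = "C(C)C(O)CC",
         ent = c("[C@H](C)[C@H](O)CC", "[C@@H](C)[C@@H](O)CC"), n = 2L)
  )

  rows <- list()
  counter <- 0L
  for (f in seq_along(family_sizes)) {
    n_chiral <- round(family_sizes[f] * stereo_fraction)
    for (m in seq_len(family_sizes[f])) {
      counter <- counter + 1L
      id <- sprintf("LIG%03d", counter)
      if (m <= n_chiral) {
        cs <- chiral_subs[[(m - 1L) %% length(chiral_subs) + 1L]]
        rows[[counter]] <- tibble::tibble(
          ligand_id = id, family = LETTERS[f],
          smiles = sprintf(scaffolds[f], cs$ent[1]),
          smiles_opposite = sprintf(scaffolds[f], cs$ent[2]),
          n_stereocenters = cs$n
        )
      } else {
        sub <- achiral_subs[(m - 1L) %% length(achiral_subs) + 1L]
        rows[[counter]] <- tibble::tibble(
          ligand_id = id, family = LETTERS[f],
          smiles = sprintf(scaffolds[f], sub),
          smiles_opposite = NA_character_,
          n_stereocenters = 0L
        )
      }
    }
  }
  truth <- dplyr::bind_rows(rows)
  truth$is_enantiomer_double <- FALSE

  if (n_enantiomer_pairs > 0) {
    eligible <- which(!is.na(truth$smiles_opposite))
    if (length(eligible) < n_enantiomer_pairs) {
      stop("not enough chiral molecules to form the requested enantiomer pairs.",
           call. = FALSE)
    }
    pick <- eligible[seq_len(n_enantiomer_pairs)]
    doubles <- truth[pick, ] |>
      dplyr::mutate(
        ligand_id = paste0(.data$ligand_id, "ENT"),
        smiles = .data$smiles_opposite,
        is_enantiomer_double = TRUE
      )
    truth <- dplyr::bind_rows(truth, doubles)
  }
  truth$smiles_opposite <- NULL

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sdf_file <- file.path(dir, "library.sdf")
  labels_file <- file.path(dir, "library_labels.csv")

  smi_txt <- paste(paste(truth$smiles, truth$ligand_id), collapse = "\n")
  sdf_str <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi_txt, "\n"))
  writeLines(sub("\n$", "", sdf_str), sdf_file)
  utils::write.csv(
    tibble::tibble(
      ligand_id = truth$ligand_id, label = "active", pharmacology = "agonist"
    ),
    labels_file, row.names = FALSE
  )

  list(sdf_file = sdf_file, labels_file = labels_file, truth = truth)
}
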