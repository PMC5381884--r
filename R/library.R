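#' Load a ligand library from an SDF file
#'
#' Reads an SDF (V2000/V3000) ligand library into a `ligand_library` object:
#' a records table plus the parsed molecules. Each record gets a canonical
#' achiral constitution key (stereo descriptors stripped), a count of
#' potential stereocenters perceived from the 2D graph, and a racemic flag
#' (set when at least one stereocenter is present). Malformed records are
#' skipped with a warning reporting the count.
#'
#' @param sdf_source Path to an SDF file, or a `ChemmineR::SDFset`.
#' @param labels Optional sidecar data frame (or CSV path) with columns
#'   `ligand_id`, `label` (`active`/`decoy`) and optionally `pharmacology`
#'   (`agonist`/`inhibitor`/`unknown`). Records without a label default to
#'   `active`/`unknown`.
#' @return A `ligand_library`: list with `records` (tibble: `ligand_id`,
#'   `constitution_key`, `n_stereocenters`, `racemic_flag`,
#'   `enantiomer_multiplicity`, `class_label`, `pharmacology`, `chemotype`)
#'   and `molecules` (the `SDFset`, one entry per record, same order).
#'   `tidy()` returns the records tibble.
#' @export
load_library <- function(sdf_source, labels = NULL) {
  sdf <- if (inherits(sdf_source, "SDFset")) {
    sdf_source
  } else {
    if (!file.exists(sdf_source)) {
      stop(sprintf("SDF file not found: %s", sdf_source), call. = FALSE)
    }
    tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(sdf_source)),
      error = function(e) {
        stop(sprintf("unreadable SDF '%s': %s", sdf_source, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  ok <- ChemmineR::validSDF(sdf)
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    warning(sprintf("%d malformed SDF record(s) skipped.", n_bad),
            call. = FALSE)
    sdf <- sdf[ok]
  }
  if (length(sdf) == 0) stop("empty ligand library.", call. = FALSE)

  # ids from record titles; an SDFset passed in keeps its compound ids
  ids <- if (inherits(sdf_source, "SDFset")) {
    ChemmineR::cid(sdf)
  } else {
    ChemmineR::sdfid(sdf)
  }
  ids[!nzchar(ids)] <- sprintf("MOL%04d", which(!nzchar(ids)))
  ids <- make.unique(ids, sep = "_dup")
  ChemmineR::cid(sdf) <- ids

  can <- canonical_smiles(sdf)
  keys <- constitution_key(can$smiles)
  n_st <- purrr::map_int(seq_along(sdf), function(i) {
    g <- sdf_graph(sdf[[i]])
    count_stereocenters(g$atoms, g$bonds)
  })

  records <- tibble::tibble(
    ligand_id = ids,
    constitution_key = keys,
    n_stereocenters = n_st,
    racemic_flag = n_st >= 1L,
    enantiomer_multiplicity = 1L,
    class_label = "active",
    pharmacology = "unknown",
    chemotype = "unassigned"
  )

  if (!is.null(labels)) {
    if (is.character(labels)) {
      labels <- utils::read.csv(labels, stringsAsFactors = FALSE)
    }
    labels <- tibble::as_tibble(labels)
    stopifnot(all(c("ligand_id", "label") %in% names(labels)))
    m <- match(records$ligand_id, labels$ligand_id)
    records$class_label <- ifelse(is.na(m), "active", labels$label[m])
    if ("pharmacology" %in% names(labels)) {
      records$pharmacology <- ifelse(
        is.na(m), "unknown", labels$pharmacology[m]
      )
    }
  }

  new_ligand_library(records, sdf)
}

new_ligand_library <- function(records, molecules, id_map = NULL) {
  structure(
    list(records = records, molecules = molecules, id_map = id_map),
    class = "ligand_library"
  )
}

#' @export
print.ligand_library <- function(x, ...) {
  cat(sprintf(
    "<ligand_library> %d record(s); %d racemic; %d unique constitution(s)\n",
    nrow(x$records), sum(x$records$racemic_flag),
    dplyr::n_distinct(x$records$constitution_key)
  ))
  print(x$records, n = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ligand_library <- function(x, ...) x$records

#' Convert a library to its racemic form
#'
#' Emulates racemic library preparation: stereo annotations are dropped
#' (the constitution key is already achiral), molecules with at least one
#' perceived stereocenter are flagged racemic, and the number of enumerable
#' enantiomer labels is recorded as `2^n_stereocenters`. Enumeration is
#' bookkeeping only — no 3D stereoisomer geometries are generated, since a
#' docking engine with racemic sampling handles that downstream.
#'
#' @param library A `ligand_library`.
#' @param max_multiplicity Cap on the enumerated multiplicity (default
#'   `2^10`); molecules exceeding it are capped with a warning.
#' @return The library with `racemic_flag` and `enantiomer_multiplicity`
#'   updated. Deterministic.
#' @export
racemize_library <- function(library, max_multiplicity = 1024L) {
  stopifnot(inherits(library, "ligand_library"))
  rec <- library$records
  mult <- 2^rec$n_stereocenters
  over <- mult > max_multiplicity
  if (any(over)) {
    warning(sprintf(
      "%d molecule(s) exceed the multiplicity cap (%d); capped.",
      sum(over), max_multiplicity
    ), call. = FALSE)
    mult[over] <- max_multiplicity
  }
  rec$racemic_flag <- rec$n_stereocenters >= 1L
  rec$enantiomer_multiplicity <- as.integer(mult)
  new_ligand_library(rec, library$molecules, library$id_map)
}

#' Merge records sharing one constitution
#'
#' Molecules present in more than one enantiomeric state collapse to a
#' single record once stereo is dropped, and must be counted only once in
#' any screening analysis. Records sharing a `constitution_key` are merged
#' into the one with the lexicographically smallest id; an id map (old id ->
#' retained id) is stored on the library for joining score tables.
#'
#' @param library A `ligand_library` (typically racemized).
#' @return The deduplicated library; `$id_map` is a tibble
#'   (`old_id`, `new_id`) covering every input record. Merging records with
#'   conflicting active/decoy labels is an error naming the ids.
#' @export
deduplicate <- function(library) {
  stopifnot(inherits(library, "ligand_library"))
  rec <- library$records
  conflicts <- rec |>
    dplyr::group_by(.data$constitution_key) |>
    dplyr::filter(dplyr::n_distinct(.data$class_label) > 1L)
  if (nrow(conflicts) > 0) {
    stop(sprintf(
      "conflicting class labels within one constitution: %s",
      paste(conflicts$ligand_id, collapse = ", ")
    ), call. = FALSE)
  }
  rec <- rec[order(rec$ligand_id), ]
  keep <- rec |>
    dplyr::group_by(.data$constitution_key) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  id_map <- rec |>
    dplyr::left_join(
      dplyr::select(keep, "constitution_key", new_id = "ligand_id"),
      by = "constitution_key"
    ) |>
    dplyr::select(old_id = "ligand_id", "new_id")
  keep <- keep[order(match(keep$ligand_id, library$records$ligand_id)), ]
  mols <- library$molecules[match(keep$ligand_id,
                                  ChemmineR::cid(library$molecules))]
  prev <- library$id_map
  if (!is.null(prev)) {
    id_map <- prev |>
      dplyr::left_join(id_map, by = c(new_id = "old_id")) |>
      dplyr::select("old_id", new_id = "new_id.y")
  }
  new_ligand_library(keep, mols, id_map)
}

#' Write a library's records table to CSV
#'
#' @param library A `ligand_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  utils::write.csv(library$records, path, row.names = FALSE)
  invisible(path)
}
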