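#' Load a ligand/receptor co-complex from a PDB file
#'
#' Reads a PDB entry and reduces it to the material the structural
#' comparisons use: protein heavy atoms of the selected chain(s) plus one
#' bound ligand. Waters and all other hetero molecules are removed,
#' hydrogens are dropped, alternate locations are resolved to the highest
#' occupancy (ties: altloc `A`), and author residue numbering is preserved.
#' Ligand connectivity is inferred from interatomic distances against
#' covalent-radius sums, the standard approach for coordinate files without
#' bond records.
#'
#' @param pdb_source Path to a PDB file, or a `bio3d::pdb` object.
#' @param ligand_code 3-letter chemical component code of the bound ligand.
#' @param chains Chain id(s) to keep; `NULL` keeps all chains.
#' @param complex_id Identifier for the complex; defaults to the file name
#'   plus chain.
#' @return A `gpcr_complex`: list with `complex_id`, `atoms` (tibble:
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `element`, `x`, `y`, `z`)
#'   and `ligand` (list: `code`, `atoms` tibble, `bonds` tibble
#'   `a1`,`a2`).
#' @export
load_complex <- function(pdb_source, ligand_code, chains = NULL,
                         complex_id = NULL) {
  pdb <- if (inherits(pdb_source, "pdb")) {
    pdb_source
  } else {
    bio3d::read.pdb(pdb_source, rm.alt = FALSE)
  }
  at <- tibble::as_tibble(pdb$atom)
  if (is.null(complex_id)) {
    complex_id <- paste0(
      if (is.character(pdb_source)) {
        sub("\\.pdb$", "", basename(pdb_source))
      } else "complex",
      if (!is.null(chains)) paste0("-", paste(chains, collapse = ""))
    )
  }

  if (!is.null(chains)) {
    if (!all(chains %in% at$chain)) {
      stop(sprintf(
        "chain(s) %s absent from the structure.",
        paste(setdiff(chains, at$chain), collapse = ", ")
      ), call. = FALSE)
    }
    at <- dplyr::filter(at, .data$chain %in% chains)
  }

  if (!"elesy" %in% names(at)) at$elesy <- NA_character_
  at <- at |>
    dplyr::mutate(element = element_of(.data$elesy, .data$elety)) |>
    dplyr::filter(
      !.data$resid %in% c("HOH", "WAT", "DOD"),
      .data$element != "H"
    ) |>
    dplyr::mutate(insert = dplyr::coalesce(.data$insert, ""))

  # resolve altlocs: highest occupancy, ties to the earliest altloc id;
  # file atom order is preserved
  at <- at |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(
      .data$chain, .data$resno, .data$insert, .data$resid, .data$elety
    ) |>
    dplyr::arrange(
      dplyr::desc(dplyr::coalesce(.data$o, 1)),
      dplyr::coalesce(.data$alt, ""), .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")

  lig_at <- dplyr::filter(at, .data$resid == ligand_code)
  if (nrow(lig_at) == 0) {
    stop(sprintf("ligand '%s' not found in the selected chains.", ligand_code),
         call. = FALSE)
  }
  # one ligand copy: first (chain, resno) instance
  first_inst <- lig_at |> dplyr::distinct(.data$chain, .data$resno) |>
    dplyr::slice(1L)
  lig_at <- dplyr::semi_join(lig_at, first_inst, by = c("chain", "resno"))

  prot <- at |>
    dplyr::filter(.data$type == "ATOM", .data$resid != ligand_code) |>
    dplyr::transmute(
      chain = .data$chain, resno = .data$resno, insert = .data$insert,
      resid = .data$resid, elety = .data$elety, element = .data$element,
      x = .data$x, y = .data$y, z = .data$z
    )

  lig_atoms <- lig_at |>
    dplyr::transmute(
      name = .data$elety,
      element = .data$element,
      x = .data$x, y = .data$y, z = .data$z
    )
  lig_bonds <- infer_bonds(lig_atoms)

  new_gpcr_complex(
    complex_id = complex_id,
    atoms = prot,
    ligand = list(code = ligand_code, atoms = lig_atoms, bonds = lig_bonds)
  )
}

new_gpcr_complex <- function(complex_id, atoms, ligand) {
  stopifnot(all(is.finite(atoms$x)), all(is.finite(ligand$atoms$x)))
  structure(
    list(complex_id = complex_id, atoms = atoms, ligand = ligand),
    class = "gpcr_complex"
  )
}

#' @export
print.gpcr_complex <- function(x, ...) {
  cat(sprintf(
    "<gpcr_complex> %s: %d protein atoms / %d residues; ligand %s (%d atoms)\n",
    x$complex_id, nrow(x$atoms),
    nrow(dplyr::distinct(x$atoms, .data$chain, .data$resno, .data$insert)),
    x$ligand$code, nrow(x$ligand$atoms)
  ))
  invisible(x)
}

element_of <- function(elesym, elety) {
  out <- toupper(trimws(elesym))
  miss <- is.na(out) | !nzchar(out)
  guess <- toupper(substr(trimws(elety), 1, 1))
  out[miss] <- guess[miss]
  # normalize two-letter symbols
  out <- sub("^CL$", "Cl", out); out <- sub("^BR$", "Br", out)
  out
}

covalent_radius <- c(
  C = 0.77, N = 0.75, O = 0.73, S = 1.03, P = 1.06, F = 0.71,
  Cl = 0.99, Br = 1.14, I = 1.33, B = 0.82, H = 0.37
)

# bonds from interatomic distance <= sum of covalent radii + 0.45 A
infer_bonds <- function(atoms, slack = 0.45) {
  n <- nrow(atoms)
  if (n < 2) return(tibble::tibble(a1 = integer(), a2 = integer()))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r <- covalent_radius[atoms$element]
  r[is.na(r)] <- 0.77
  cutoff <- outer(r, r, "+") + slack
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  tibble::tibble(a1 = hit[, 1], a2 = hit[, 2])
}

is_connected_graph <- function(n, bonds) {
  if (n <= 1) return(TRUE)
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::is_connected(g)
}

#' Define a binding pocket from one or more complexes
#'
#' A pocket is the set of residues with any heavy atom within `radius`
#' angstroms of any ligand heavy atom. For a group of complexes the pocket
#' is the union of the members' pockets, matched across complexes by author
#' residue number (and insertion code) — the combined residue set used for
#' pocket RMSD and fingerprint comparison. The analysis pocket convention
#' uses 5 A; docking-box residue selection uses 4 A.
#'
#' @param complexes A `gpcr_complex` or list of them.
#' @param radius Distance cutoff in angstroms (default 5).
#' @return A `pocket_definition`: tibble (`resno`, `insert`, `resid`) with
#'   attributes `radius` and `scope`.
#' @export
define_pocket <- function(complexes, radius = 5) {
  stopifnot(radius > 0)
  if (inherits(complexes, "gpcr_complex")) complexes <- list(complexes)
  per <- purrr::map_dfr(complexes, function(cx) {
    prot <- as.matrix(cx$atoms[, c("x", "y", "z")])
    lig <- as.matrix(cx$ligand$atoms[, c("x", "y", "z")])
    # min distance from each protein atom to any ligand atom
    d2 <- apply(lig, 1, function(p) {
      (prot[, 1] - p[1])^2 + (prot[, 2] - p[2])^2 + (prot[, 3] - p[3])^2
    })
    near <- sqrt(do.call(pmin, as.data.frame(d2))) <= radius
    dplyr::distinct(
      cx$atoms[near, ], .data$resno, .data$insert, .data$resid
    )
  })
  pocket <- dplyr::distinct(per, .data$resno, .data$insert, .keep_all = TRUE) |>
    dplyr::arrange(.data$resno, .data$insert)
  if (nrow(pocket) == 0) {
    stop("empty pocket: no residue within radius of the ligand (wrong chain or ligand code?).",
         call. = FALSE)
  }
  structure(
    pocket,
    radius = radius,
    scope = if (length(complexes) > 1) "group_union" else "single_complex",
    class = c("pocket_definition", class(pocket))
  )
}

#' Superpose a group of complexes onto a reference
#'
#' Least-squares rigid-body superposition (Kabsch) of each complex onto the
#' reference using backbone heavy atoms (N, CA, C, O) of the shared
#' pocket-union residues; the fitted transformation is applied to all atoms
#' including the ligand. Backbone-only fitting keeps side-chain and ligand
#' differences out of the frame definition, so subsequent ligand RMSD
#' reflects position within the pocket.
#'
#' @param complexes List of `gpcr_complex` objects.
#' @param reference Index of the reference complex (default 1).
#' @param pocket Optional `pocket_definition`; default is the 5-angstrom
#'   group-union pocket.
#' @return A `superposed_group`: list with `complexes` (transformed),
#'   `fit` (tibble: `complex_id`, `fit_rmsd`, `n_fit_atoms`) and `pocket`.
#' @export
superpose_group <- function(complexes, reference = 1, pocket = NULL) {
  stopifnot(length(complexes) >= 1)
  if (is.null(pocket)) pocket <- define_pocket(complexes, radius = 5)
  ref <- complexes[[reference]]
  bb <- c("N", "CA", "C", "O")

  fit_atoms <- function(cx) {
    cx$atoms |>
      dplyr::semi_join(pocket, by = c("resno", "insert")) |>
      dplyr::filter(.data$elety %in% bb) |>
      dplyr::select("resno", "insert", "elety", "x", "y", "z")
  }
  ref_fit <- fit_atoms(ref)

  out <- purrr::map(complexes, function(cx) {
    m <- dplyr::inner_join(
      ref_fit, fit_atoms(cx),
      by = c("resno", "insert", "elety"), suffix = c("_ref", "_mob")
    )
    if (nrow(m) < 3) {
      stop(sprintf("fewer than 3 matched backbone atoms for %s.",
                   cx$complex_id), call. = FALSE)
    }
    fixed <- c(t(as.matrix(m[, c("x_ref", "y_ref", "z_ref")])))
    mobile_fit <- c(t(as.matrix(m[, c("x_mob", "y_mob", "z_mob")])))
    all_xyz <- c(t(as.matrix(
      rbind(
        cx$atoms[, c("x", "y", "z")],
        stats::setNames(cx$ligand$atoms[, c("x", "y", "z")], c("x", "y", "z"))
      )
    )))
    moved <- bio3d::fit.xyz(
      fixed = fixed,
      mobile = c(mobile_fit, all_xyz),
      fixed.inds = seq_along(fixed),
      mobile.inds = seq_along(mobile_fit)
    )
    fitted_sub <- moved[seq_along(mobile_fit)]
    rest <- matrix(moved[-seq_along(mobile_fit)], ncol = 3, byrow = TRUE)
    n_prot <- nrow(cx$atoms)
    cx$atoms$x <- rest[seq_len(n_prot), 1]
    cx$atoms$y <- rest[seq_len(n_prot), 2]
    cx$atoms$z <- rest[seq_len(n_prot), 3]
    lig_ix <- n_prot + seq_len(nrow(cx$ligand$atoms))
    cx$ligand$atoms$x <- rest[lig_ix, 1]
    cx$ligand$atoms$y <- rest[lig_ix, 2]
    cx$ligand$atoms$z <- rest[lig_ix, 3]
    list(
      complex = cx,
      fit_rmsd = sqrt(mean((fitted_sub - fixed)^2) * 3),
      n_fit = nrow(m)
    )
  })

  structure(
    list(
      complexes = purrr::map(out, "complex"),
      fit = tibble::tibble(
        complex_id = purrr::map_chr(out, ~ .x$complex$complex_id),
        fit_rmsd = purrr::map_dbl(out, "fit_rmsd"),
        n_fit_atoms = purrr::map_int(out, ~ as.integer(.x$n_fit))
      ),
      pocket = pocket,
      reference = complexes[[reference]]$complex_id
    ),
    class = "superposed_group"
  )
}

#' @export
print.superposed_group <- function(x, ...) {
  cat(sprintf("<superposed_group> %d complexes on reference %s\n",
              length(x$complexes), x$reference))
  print(x$fit)
  invisible(x)
}
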