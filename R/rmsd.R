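#' Symmetry-minimized heavy-atom RMSD between two bound ligands
#'
#' Computes the heavy-atom RMSD between the same ligand in two superposed
#' complexes, with no additional fitting, so the value reflects both the
#' relative orientation and the relative position of the ligand within the
#' pocket frame. Atom correspondence is established by element-labeled graph
#' isomorphism and, among all isomorphisms (topological symmetries such as a
#' flipped phenyl or swapped carboxylate oxygens), the RMSD-minimizing one
#' is used. If the enumeration exceeds `max_mappings`, correspondence falls
#' back to atom-name matching with a warning.
#'
#' @param complex_a,complex_b `gpcr_complex` objects holding ligands of the
#'   same constitution, already in a common frame (see [superpose_group()]).
#' @param max_mappings Cap on enumerated isomorphisms (default 10000).
#' @return RMSD in angstroms.
#' @export
ligand_rmsd <- function(complex_a, complex_b, max_mappings = 10000) {
  la <- complex_a$ligand
  lb <- complex_b$ligand
  xa <- as.matrix(la$atoms[, c("x", "y", "z")])
  xb <- as.matrix(lb$atoms[, c("x", "y", "z")])
  if (nrow(xa) != nrow(xb)) {
    stop("ligands differ in heavy-atom count; not the same constitution.",
         call. = FALSE)
  }
  maps <- ligand_mappings(la, lb)
  if (length(maps) == 0) {
    stop("ligand graphs are not isomorphic; cannot compute RMSD.",
         call. = FALSE)
  }
  if (length(maps) > max_mappings) {
    warning(sprintf(
      "%d symmetry mappings exceed the cap; falling back to atom-name matching.",
      length(maps)
    ), call. = FALSE)
    m <- match(la$atoms$name, lb$atoms$name)
    if (anyNA(m)) {
      stop("atom names do not match between the two ligands.", call. = FALSE)
    }
    return(rmsd_of(xa, xb[m, , drop = FALSE]))
  }
  min(purrr::map_dbl(maps, function(m) rmsd_of(xa, xb[m, , drop = FALSE])))
}

rmsd_of <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# all element-preserving graph isomorphisms a -> b (VF2)
ligand_mappings <- function(la, lb) {
  ga <- ligand_igraph(la)
  gb <- ligand_igraph(lb)
  elems <- sort(unique(c(la$atoms$element, lb$atoms$element)))
  ca <- match(la$atoms$element, elems)
  cb <- match(lb$atoms$element, elems)
  iso <- igraph::isomorphisms(
    ga, gb, method = "vf2", vertex.color1 = ca, vertex.color2 = cb
  )
  purrr::map(iso, as.integer)
}

ligand_igraph <- function(lig) {
  g <- igraph::make_empty_graph(n = nrow(lig$atoms), directed = FALSE)
  if (nrow(lig$bonds) > 0) {
    g <- igraph::add_edges(g, t(as.matrix(lig$bonds[, c("a1", "a2")])))
  }
  g
}

#' Heavy-atom RMSD between two binding pockets
#'
#' RMSD over the pocket residues' heavy atoms in two superposed complexes,
#' matching atoms by residue number, insertion code and atom name. Atoms
#' present in only one complex (e.g. missing side-chains) are skipped, so
#' structures with incomplete residues are still comparable over their
#' shared atoms.
#'
#' @param complex_a,complex_b `gpcr_complex` objects in a common frame.
#' @param pocket A `pocket_definition` from [define_pocket()].
#' @return RMSD in angstroms, with attribute `n_atoms` (matched atom count).
#' @export
pocket_rmsd <- function(complex_a, complex_b, pocket) {
  sel <- function(cx) {
    cx$atoms |>
      dplyr::semi_join(pocket, by = c("resno", "insert")) |>
      dplyr::select("resno", "insert", "elety", "x", "y", "z")
  }
  m <- dplyr::inner_join(
    sel(complex_a), sel(complex_b),
    by = c("resno", "insert", "elety"), suffix = c("_a", "_b")
  )
  if (nrow(m) == 0) {
    stop("no matched pocket atoms between the two complexes.", call. = FALSE)
  }
  out <- rmsd_of(
    as.matrix(m[, c("x_a", "y_a", "z_a")]),
    as.matrix(m[, c("x_b", "y_b", "z_b")])
  )
  attr(out, "n_atoms") <- nrow(m)
  out
}

#' Pairwise RMSD matrices for a superposed group
#'
#' Computes all-vs-all ligand RMSD and pocket RMSD for a superposed group
#' of complexes, the matrices reported alongside ROC comparisons of the
#' corresponding pockets.
#'
#' @param group A `superposed_group` from [superpose_group()].
#' @return A list of two symmetric matrices, `ligand` and `pocket`, with
#'   complex ids as dimnames.
#' @export
rmsd_matrices <- function(group) {
  stopifnot(inherits(group, "superposed_group"))
  cxs <- group$complexes
  n <- length(cxs)
  ids <- purrr::map_chr(cxs, "complex_id")
  lig <- poc <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j >= i) next
      lig[i, j] <- lig[j, i] <- ligand_rmsd(cxs[[i]], cxs[[j]])
      poc[i, j] <- poc[j, i] <-
        as.numeric(pocket_rmsd(cxs[[i]], cxs[[j]], group$pocket))
    }
  }
  list(ligand = lig, pocket = poc)
}
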