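# Seven-class protein-ligand interaction fingerprints.
#
# Receptor atom roles come from residue/atom-name lookup tables under a
# pH-7 convention (Asp/Glu anionic, Lys/Arg cationic, His neutral); ligand
# atom roles are perceived from the element-labeled bond graph by simple
# rules (amine N cationic/donor, carboxylate O anionic/acceptor, planar
# C/N rings aromatic, carbons not bonded to N/O hydrophobic). Structures
# carry no hydrogens, so hydrogen bonds are judged on donor-acceptor
# heavy-atom distance plus the antecedent-donor-acceptor angle.

ifp_types <- c(
  "hydrophobic", "hbond_donor", "hbond_acceptor",
  "weak_hbond_donor", "weak_hbond_acceptor", "ionic", "aromatic"
)

#' Default geometric cutoffs for interaction fingerprints
#'
#' Literature-standard distance/angle rules; every value can be overridden
#' via the `cutoffs` argument of [compute_ifp()]. Distances in angstroms,
#' angles in degrees. Fingerprints flag *likely* interactions under these
#' rules, not their absolute presence.
#'
#' @return Named list: `hydrophobic` (4.5), `hbond` (3.5),
#'   `hbond_min_angle` (90), `weak_hbond` (3.8), `ionic` (4.0),
#'   `aromatic` (5.0).
#' @export
ifp_cutoffs <- function() {
  list(
    hydrophobic = 4.5, hbond = 3.5, hbond_min_angle = 90,
    weak_hbond = 3.8, ionic = 4.0, aromatic = 5.0
  )
}

# receptor side-chain role tables (backbone roles added in code)
.res_donor <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  HIS = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1"
)
.res_acceptor <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = "ND1"
)
.res_anion <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.res_cation <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.res_aromatic <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(
    c("CG", "CD1", "CD2", "NE1", "CE2"),
    c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  )
)
# carbons with no attached hydrogen (excluded from weak C-H donors);
# backbone carbonyl C is added in code
.res_c_no_h <- list(
  ASP = "CG", GLU = "CD", ASN = "CG", GLN = "CD", ARG = "CZ",
  PHE = "CG", TYR = c("CG", "CZ"), TRP = c("CG", "CD2", "CE2"), HIS = "CG"
)
# heavy-atom antecedents of donor atoms, for the angle test
.donor_antecedent <- list(
  N = "CA", OG = "CB", OG1 = "CB", OH = "CZ", SG = "CB", ND2 = "CG",
  NE2 = c("CD", "CE1"), NZ = "CE", NE = "CD", NH1 = "CZ", NH2 = "CZ",
  NE1 = c("CD1", "CE2"), ND1 = c("CG", "CE1")
)

receptor_roles <- function(atoms) {
  res <- atoms$resid
  ety <- atoms$elety
  role <- tibble::tibble(
    donor = ety == "N" |
      purrr::map2_lgl(res, ety, ~ .y %in% (.res_donor[[.x]] %||% character())),
    acceptor = ety == "O" |
      purrr::map2_lgl(res, ety,
                      ~ .y %in% (.res_acceptor[[.x]] %||% character())),
    anion = purrr::map2_lgl(res, ety,
                            ~ .y %in% (.res_anion[[.x]] %||% character())),
    cation = purrr::map2_lgl(res, ety,
                             ~ .y %in% (.res_cation[[.x]] %||% character())),
    apolar = atoms$element %in% c("C", "S") & ety != "C" &
      !purrr::map2_lgl(res, ety,
                       ~ .y %in% (.res_acceptor[[.x]] %||% character())),
    weak_donor = atoms$element == "C" & ety != "C" &
      !purrr::map2_lgl(res, ety,
                       ~ .y %in% (.res_c_no_h[[.x]] %||% character()))
  )
  # proline backbone N has no H
  role$donor[res == "PRO" & ety == "N"] <- FALSE
  role
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ligand atom roles perceived from the bond graph
ligand_roles <- function(lig) {
  atoms <- lig$atoms
  bonds <- lig$bonds
  n <- nrow(atoms)
  nb <- purrr::map(seq_len(n), function(i) {
    c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])
  })
  deg <- lengths(nb)
  el <- atoms$element
  nb_el <- purrr::map(nb, ~ el[.x])

  # carboxylate: C bonded to two O, at least one terminal
  carbox_o <- rep(FALSE, n)
  for (i in which(el == "C")) {
    os <- nb[[i]][el[nb[[i]]] == "O"]
    if (length(os) == 2 && any(deg[os] == 1)) carbox_o[os] <- TRUE
  }
  # amine N: N bonded only to carbons (not amide: no neighbor C that also
  # binds a terminal O)
  amide_c <- rep(FALSE, n)
  for (i in which(el == "C")) {
    os <- nb[[i]][el[nb[[i]]] == "O" & deg[nb[[i]]] == 1]
    if (length(os) >= 1 && any(el[nb[[i]]] == "N")) amide_c[i] <- TRUE
  }
  amine_n <- el == "N" & purrr::map_lgl(nb_el, ~ all(.x == "C")) &
    !purrr::map_lgl(nb, ~ any(amide_c[.x])) & deg <= 3

  rings <- planar_rings(atoms, bonds)
  ring_atoms <- unique(unlist(rings))
  in_ring <- seq_len(n) %in% ring_atoms

  # standard valences give implicit H counts for donor perception
  h <- implicit_h(
    tibble::tibble(id = seq_len(n), element = el),
    tibble::tibble(a1 = bonds$a1, a2 = bonds$a2,
                   order = rep(1L, nrow(bonds)))
  )

  tibble::tibble(
    donor = (el == "N" & h > 0 & !in_ring) |
      (el == "O" & deg == 1 & !carbox_o & h > 0),
    acceptor = el == "O" | (el == "N" & !amine_n & h == 0),
    anion = carbox_o,
    cation = amine_n,
    apolar = (el == "C" & purrr::map_lgl(nb_el, ~ !any(.x %in% c("N", "O")))) |
      el == "S",
    weak_donor = el == "C" & h > 0,
    rings = list(rings)
  ) |>
    dplyr::mutate(donor = .data$donor | .data$cation)
}

# rings of size 5-6, all C/N, coplanar within 0.1 A -> aromatic
planar_rings <- function(atoms, bonds, tol = 0.1) {
  n <- nrow(atoms)
  if (nrow(bonds) < 3) return(list())
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(
      g, igraph::get_edge_ids(g, c(bonds$a1[k], bonds$a2[k]))
    )
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = bonds$a1[k], to = bonds$a2[k]
    )$vpath[[1]])
    ring <- as.integer(sp)
    if (length(ring) < 5 || length(ring) > 6) next
    key <- paste(sort(ring), collapse = "-")
    if (key %in% seen) next
    seen <- c(seen, key)
    if (!all(atoms$element[ring] %in% c("C", "N"))) next
    if (!is_planar(xyz[ring, , drop = FALSE], tol)) next
    rings[[length(rings) + 1L]] <- ring
  }
  rings
}

is_planar <- function(xyz, tol) {
  c0 <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, c0))
  normal <- sv$v[, 3]
  all(abs(sweep(xyz, 2, c0) %*% normal) <= tol)
}

#' Compute a seven-class interaction fingerprint for one complex
#'
#' For each pocket residue, flags likely ligand contacts of seven types —
#' hydrophobic, hydrogen-bond donor/acceptor (residue as donor / as
#' acceptor), weak (C-H) hydrogen-bond donor/acceptor, ionic and aromatic —
#' from heavy-atom distances and donor-angle geometry. A residue with no
#' heavy atom near the ligand gets an all-false row.
#'
#' @param complex A `gpcr_complex`.
#' @param pocket A `pocket_definition`; rows of the result follow it.
#' @param cutoffs Geometric rules; see [ifp_cutoffs()].
#' @return An `ifp_matrix`: tibble with `resno`, `insert`, `resid` and one
#'   logical column per interaction type; attribute `complex_id`.
#' @export
compute_ifp <- function(complex, pocket, cutoffs = ifp_cutoffs()) {
  prot <- dplyr::semi_join(complex$atoms, pocket, by = c("resno", "insert"))
  rr <- receptor_roles(prot)
  lig <- complex$ligand
  lr <- ligand_roles(lig)
  lxyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  dmat <- crossdist(pxyz, lxyz)

  lig_nb <- purrr::map(seq_len(nrow(lig$atoms)), function(i) {
    c(lig$bonds$a2[lig$bonds$a1 == i], lig$bonds$a1[lig$bonds$a2 == i])
  })
  lig_rings <- lr$rings[[1]]
  ring_centroids <- purrr::map(lig_rings, ~ colMeans(lxyz[.x, , drop = FALSE]))

  res_key <- paste(prot$resno, prot$insert)
  rows <- purrr::pmap_dfr(
    list(pocket$resno, pocket$insert, pocket$resid),
    function(resno, insert, resid) {
      ix <- which(res_key == paste(resno, insert))
      bits <- stats::setNames(rep(FALSE, length(ifp_types)), ifp_types)
      if (length(ix) > 0) {
        d <- dmat[ix, , drop = FALSE]
        ra <- rr[ix, ]
        bits["hydrophobic"] <- any(
          d[ra$apolar, lr$apolar, drop = FALSE] <= cutoffs$hydrophobic
        )
        bits["hbond_donor"] <- hbond_hit(
          prot[ix, ], ra$donor, lxyz, lr$acceptor, d, cutoffs,
          donor_side = "receptor", lig = lig, lig_nb = lig_nb
        )
        bits["hbond_acceptor"] <- hbond_hit(
          prot[ix, ], ra$acceptor, lxyz, lr$donor, d, cutoffs,
          donor_side = "ligand", lig = lig, lig_nb = lig_nb
        )
        bits["weak_hbond_donor"] <- any(
          d[ra$weak_donor, lr$acceptor, drop = FALSE] <= cutoffs$weak_hbond
        )
        bits["weak_hbond_acceptor"] <- any(
          d[ra$acceptor, lr$weak_donor, drop = FALSE] <= cutoffs$weak_hbond
        )
        bits["ionic"] <- any(
          d[ra$anion, lr$cation, drop = FALSE] <= cutoffs$ionic
        ) || any(
          d[ra$cation, lr$anion, drop = FALSE] <= cutoffs$ionic
        )
        if (length(ring_centroids) > 0 &&
            !is.null(.res_aromatic[[resid]])) {
          rxyz <- as.matrix(prot[ix, c("x", "y", "z")])
          for (ring_names in .res_aromatic[[resid]]) {
            sel <- prot$elety[ix] %in% ring_names
            if (sum(sel) < length(ring_names)) next
            cen <- colMeans(rxyz[sel, , drop = FALSE])
            for (lc in ring_centroids) {
              if (sqrt(sum((cen - lc)^2)) <= cutoffs$aromatic) {
                bits["aromatic"] <- TRUE
              }
            }
          }
        }
      }
      tibble::as_tibble_row(c(
        list(resno = resno, insert = insert, resid = resid),
        as.list(bits)
      ))
    }
  )
  structure(
    rows,
    complex_id = complex$complex_id, cutoffs = cutoffs,
    class = c("ifp_matrix", class(rows))
  )
}

crossdist <- function(a, b) {
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}

# donor-acceptor distance <= cutoff and antecedent-donor-acceptor angle
# >= min angle for every heavy antecedent present
hbond_hit <- function(prot_res, rec_mask, lxyz, lig_mask, d, cutoffs,
                      donor_side, lig, lig_nb) {
  hits <- which(
    d[rec_mask, lig_mask, drop = FALSE] <= cutoffs$hbond, arr.ind = TRUE
  )
  if (nrow(hits) == 0) return(FALSE)
  rec_ix <- which(rec_mask)[hits[, 1]]
  lig_ix <- which(lig_mask)[hits[, 2]]
  rxyz <- as.matrix(prot_res[, c("x", "y", "z")])
  for (k in seq_len(length(rec_ix))) {
    r <- rec_ix[k]; l <- lig_ix[k]
    if (donor_side == "receptor") {
      ante_names <- .donor_antecedent[[prot_res$elety[r]]]
      ante_ix <- which(prot_res$elety %in% ante_names)
      ok <- all(purrr::map_lgl(ante_ix, function(a) {
        angle_deg(rxyz[a, ], rxyz[r, ], lxyz[l, ]) >= cutoffs$hbond_min_angle
      }))
    } else {
      ante_ix <- lig_nb[[l]]
      ok <- all(purrr::map_lgl(ante_ix, function(a) {
        angle_deg(lxyz[a, ], lxyz[l, ], rxyz[r, ]) >= cutoffs$hbond_min_angle
      }))
    }
    if (ok) return(TRUE)
  }
  FALSE
}

angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(pmin(1, pmax(-1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) *
    180 / pi
}

#' Residue-aligned fingerprint comparison across a group of complexes
#'
#' Stacks the fingerprints of several complexes over a shared pocket-union
#' row set into one long table and a heat-map figure with the conventional
#' coloring (hydrophobic blue, hydrogen bonds red, weak hydrogen bonds
#' orange, ionic purple, aromatic green), aligning complexes of the same
#' receptor to highlight interaction differences.
#'
#' @param ifps List of `ifp_matrix` objects sharing a row set.
#' @param annotations Optional data frame (`resno`, `segment`) of secondary
#'   structure labels (e.g. 7TM helix/loop names) appended to the residue
#'   axis labels.
#' @return List with `table` (long tibble: `complex_id`, `resno`, `insert`,
#'   `resid`, `interaction`, `present`) and `plot` (ggplot).
#' @export
ifp_heatmap <- function(ifps, annotations = NULL) {
  if (length(ifps) == 0) stop("empty group of fingerprints.", call. = FALSE)
  keys <- purrr::map(ifps, ~ paste(.x$resno, .x$insert))
  if (length(unique(purrr::map_chr(keys, paste, collapse = "|"))) != 1) {
    stop("fingerprint row sets differ; compute them on the group pocket.",
         call. = FALSE)
  }
  long <- purrr::map_dfr(ifps, function(m) {
    tidyr::pivot_longer(
      tibble::as_tibble(m) |>
        dplyr::mutate(complex_id = attr(m, "complex_id")),
      dplyr::all_of(ifp_types),
      names_to = "interaction", values_to = "present"
    )
  })
  cols <- c(
    hydrophobic = "#2166ac", hbond_donor = "#b2182b",
    hbond_acceptor = "#d6604d", weak_hbond_donor = "#e08214",
    weak_hbond_acceptor = "#fdb863", ionic = "#762a83",
    aromatic = "#1b7837"
  )
  long$interaction <- factor(long$interaction, levels = ifp_types)
  if (!is.null(annotations)) {
    m <- match(long$resno, annotations$resno)
    long$segment <- annotations$segment[m]
  }
  long$residue_label <- paste0(long$resid, long$resno)
  if (!is.null(annotations)) {
    long$residue_label <- paste0(
      long$residue_label,
      ifelse(is.na(long$segment), "", paste0(" (", long$segment, ")"))
    )
  }
  plot <- ggplot2::ggplot(
    dplyr::filter(long, .data$present),
    ggplot2::aes(
      x = .data$residue_label,
      y = .data$interaction, fill = .data$interaction
    )
  ) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$complex_id)) +
    ggplot2::labs(x = "Pocket residue", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
      legend.position = "none"
    )
  list(table = long, plot = plot)
}
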