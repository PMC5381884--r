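# Internal helpers around ChemmineR / ChemmineOB molecule objects.

# Atom table (id, element) and bond table (a1, a2, order) for one SDF record.
sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- tibble::tibble(
    id = seq_len(nrow(ab)),
    element = sub("_.*$", "", rownames(ab))
  )
  bonds <- if (nrow(bb) == 0) {
    tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
  } else {
    tibble::tibble(
      a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  }
  list(atoms = atoms, bonds = bonds)
}

# Canonical SMILES for each record of an SDFset (titles preserved).
canonical_smiles <- function(sdfset) {
  str <- paste(unlist(methods::as(sdfset, "SDFstr")@a), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(str, "\n"))
  parse_smiles_lines(out)
}

# Stereo-free canonical constitution key: strip tetrahedral (@) and
# cis/trans (/ \) marks from canonical SMILES, then re-canonicalize.
constitution_key <- function(smiles) {
  flat <- gsub("[@/\\\\]", "", smiles)
  out <- ChemmineOB::convertFormat(
    "SMI", "CAN",
    paste0(paste(flat, sprintf("m%d", seq_along(flat))), collapse = "\n")
  )
  parsed <- parse_smiles_lines(out)
  parsed$smiles[order(match(parsed$title, sprintf("m%d", seq_along(flat))))]
}

parse_smiles_lines <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  tibble::tibble(smiles = trimws(parts[, 1]), title = trimws(parts[, 2]))
}

standard_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3
)

# Implicit hydrogen count per atom from standard valences and bond orders.
implicit_h <- function(atoms, bonds) {
  used <- rep(0L, nrow(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      o <- bonds$order[k]
      if (o == 4L) o <- 1.5  # aromatic SDF bond
      used[bonds$a1[k]] <- used[bonds$a1[k]] + o
      used[bonds$a2[k]] <- used[bonds$a2[k]] + o
    }
  }
  val <- standard_valence[atoms$element]
  h <- val - ceiling(used)
  h[is.na(h) | h < 0] <- 0
  as.integer(h)
}

# Weisfeiler-Lehman iterative refinement labels on a molecular graph,
# optionally with one atom removed (for per-branch hashing around a
# candidate stereocenter). Returns character labels, one per atom.
wl_labels <- function(atoms, bonds, drop_atom = NULL, n_iter = NULL) {
  keep <- setdiff(atoms$id, drop_atom)
  idx <- match(keep, atoms$id)
  lab <- paste0(atoms$element[idx], "H", implicit_h(atoms, bonds)[idx])
  nb <- vector("list", length(keep))
  pos <- match(seq_len(nrow(atoms)), keep)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      i <- pos[bonds$a1[k]]; j <- pos[bonds$a2[k]]
      if (is.na(i) || is.na(j)) next
      nb[[i]] <- c(nb[[i]], list(c(j, bonds$order[k])))
      nb[[j]] <- c(nb[[j]], list(c(i, bonds$order[k])))
    }
  }
  if (is.null(n_iter)) n_iter <- length(keep)
  for (it in seq_len(n_iter)) {
    new_lab <- vapply(seq_along(keep), function(i) {
      env <- vapply(
        nb[[i]], function(e) paste0(e[2], ":", lab[e[1]]), character(1)
      )
      paste0(lab[i], "(", paste(sort(env), collapse = ","), ")")
    }, character(1))
    # compress to keep strings short
    lab <- as.character(match(new_lab, sort(unique(new_lab))))
    lab <- paste0("c", lab)
  }
  stats::setNames(lab, keep)
}

# Count potential tetrahedral stereocenters: a carbon bearing four distinct
# substituent branches (implicit H counted as one branch). Branches are
# compared by rooted WL refinement on the graph with the candidate removed,
# so ring-closures through the candidate are handled. This perceives
# *potential* centers from constitution alone, which is the relevant notion
# for racemic bookkeeping where configurations are unspecified.
count_stereocenters <- function(atoms, bonds) {
  if (nrow(atoms) < 4) return(0L)
  h <- implicit_h(atoms, bonds)
  deg <- rep(0L, nrow(atoms))
  has_multi <- rep(FALSE, nrow(atoms))
  if (nrow(bonds) > 0) {
    tab <- table(factor(c(bonds$a1, bonds$a2), levels = atoms$id))
    deg <- as.integer(tab)
    multi <- bonds$order > 1
    has_multi[unique(c(bonds$a1[multi], bonds$a2[multi]))] <- TRUE
  }
  cand <- which(
    atoms$element == "C" & !has_multi & deg >= 3L & (deg + h) == 4L & h <= 1L
  )
  n <- 0L
  for (a in cand) {
    neigh <- c(
      bonds$a2[bonds$a1 == a], bonds$a1[bonds$a2 == a]
    )
    lab <- wl_labels(atoms, bonds, drop_atom = a)
    branch <- unname(lab[as.character(neigh)])
    if (h[a] == 1L) branch <- c(branch, "H")
    if (!anyDuplicated(branch)) n <- n + 1L
  }
  n
}
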