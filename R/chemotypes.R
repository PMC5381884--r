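#' Cluster a known-ligand library into chemotype families
#'
#' Groups structurally similar ligands by hierarchical clustering of
#' pairwise 2D dissimilarity (1 - Tanimoto over a hashed structural
#' fingerprint). The tree is cut per-library: the lowest height at which
#' exactly `max_clusters` clusters of size >= 2 exist or, failing that, the
#' cut keeping the `max_clusters` largest clusters. The named clusters are
#' labeled `A`..`D` in decreasing size; everything else is `other`. Each
#' named cluster reports its medoid (the member minimizing summed
#' dissimilarity to the cluster — the molecule illustrating the chemotype).
#' Cut heights are per-library quantities and not comparable across
#' libraries.
#'
#' @param library A `ligand_library`. Clustering runs on the records of
#'   `class_label == "active"` only (chemotypes describe the known-ligand
#'   library, not decoys); pass a decoy-free library or rely on the filter.
#' @param max_clusters Maximum number of named clusters (default 4).
#' @param method Fingerprint backing the dissimilarity: `"atompair"`
#'   (Tanimoto over atom-pair descriptors, higher resolution) or `"fp1024"`
#'   (1024-bit folded fingerprint).
#' @return A `chemotype_clustering`: `labels` (tibble `ligand_id`,
#'   `chemotype`), `centers` (tibble `chemotype`, `center_id`, `size`),
#'   `cut_height`, `hclust` and the dissimilarity `matrix`. `tidy()` returns
#'   the label table.
#' @details With fewer ligands than `max_clusters` every molecule becomes
#'   its own named cluster; an all-identical library yields a single
#'   cluster `A`. Ties in cluster size are broken by the lexicographically
#'   smallest member id, making labels independent of input order.
#' @export
cluster_chemotypes <- function(library, max_clusters = 4,
                               method = c("atompair", "fp1024")) {
  stopifnot(inherits(library, "ligand_library"))
  method <- match.arg(method)
  act <- library$records$class_label == "active"
  ids <- library$records$ligand_id[act]
  mols <- library$molecules[match(ids, ChemmineR::cid(library$molecules))]
  n <- length(ids)
  if (n == 0) stop("no active ligands to cluster.", call. = FALSE)

  d <- ligand_dissimilarity(mols, method)
  dimnames(d) <- list(ids, ids)

  if (n <= max_clusters) {
    member <- as.list(seq_len(n))
    cut_height <- 0
    hc <- NULL
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    cut_height <- choose_cut(hc, max_clusters)
    cl <- stats::cutree(hc, h = cut_height)
    member <- split(seq_len(n), cl)
  }

  # order clusters by decreasing size, ties by smallest member id
  ord <- order(
    -lengths(member),
    purrr::map_chr(member, function(ix) min(ids[ix]))
  )
  member <- member[ord]
  named <- utils::head(member, max_clusters)
  # singleton-only tail clusters beyond max_clusters fall into "other"
  labels <- rep("other", n)
  centers <- purrr::imap_dfr(named, function(ix, k) {
    lab <- LETTERS[match(list(ix), named)]
    labels[ix] <<- lab
    ss <- colSums(d[ix, ix, drop = FALSE])
    tied <- ids[ix][ss <= min(ss) + 1e-12]   # ties: smallest id wins
    tibble::tibble(chemotype = lab, center_id = min(tied), size = length(ix))
  })

  label_tbl <- tibble::tibble(ligand_id = ids, chemotype = labels)

  structure(
    list(
      labels = label_tbl, centers = centers, cut_height = cut_height,
      max_clusters = max_clusters, hclust = hc, matrix = d
    ),
    class = "chemotype_clustering"
  )
}

ligand_dissimilarity <- function(mols, method) {
  n <- length(mols)
  if (method == "atompair") {
    ap <- ChemmineR::sdf2ap(mols)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        s <- ChemmineR::cmp.similarity(ap[[i]], ap[[j]])
        d[i, j] <- d[j, i] <- 1 - s
      }
    }
  } else {
    fp <- ChemmineR::desc2fp(ChemmineR::sdf2ap(mols),
                             descnames = 1024, type = "FPset")
    d <- 1 - sapply(seq_len(n), function(i) {
      ChemmineR::fpSim(fp[i], fp, sorted = FALSE)
    })
  }
  d
}

# Cut selection: among heights where exactly k clusters of size >= 2 exist,
# prefer the one stranding the fewest singletons (ties: lowest height), so
# well-separated families are cut at family level rather than at the first
# height where k pairs happen to exist. Fallback: the cut giving k clusters.
choose_cut <- function(hc, k) {
  heights <- sort(unique(hc$height))
  gaps <- diff(c(0, heights))
  eps <- if (any(gaps > 0)) min(gaps[gaps > 0]) / 2 else 0
  best_h <- NA_real_
  best_orphans <- Inf
  for (h in heights) {
    sizes <- table(stats::cutree(hc, h = h + eps))
    if (sum(sizes >= 2) == k) {
      orphans <- sum(sizes[sizes < 2])
      if (orphans < best_orphans) {
        best_orphans <- orphans
        best_h <- h + eps
      }
    }
  }
  if (!is.na(best_h)) return(best_h)
  # fallback: cut just above the merge that leaves k clusters (or fewer,
  # when ties in height collapse further)
  all_h <- sort(hc$height)
  n <- length(all_h) + 1L
  if (n <= k) return(0)
  all_h[n - k] + eps
}

#' @export
print.chemotype_clustering <- function(x, ...) {
  cat(sprintf("<chemotype_clustering> cut height %.3f\n", x$cut_height))
  print(
    dplyr::left_join(
      dplyr::count(x$labels, .data$chemotype, name = "size"),
      dplyr::select(x$centers, "chemotype", "center_id"),
      by = "chemotype"
    )
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.chemotype_clustering <- function(x, ...) x$labels

#' @export
plot.chemotype_clustering <- function(x, ...) {
  if (is.null(x$hclust)) {
    stop("no dendrogram: library had <= max_clusters ligands.", call. = FALSE)
  }
  stats::plot(x$hclust, ylab = "1 - Tanimoto", xlab = "", sub = "", ...)
  stats::rect.hclust(x$hclust, h = x$cut_height)
  invisible(x)
}

#' Attach chemotype labels to a library or a score table
#'
#' @param data A `ligand_library` or a data frame with a `ligand_id` column.
#' @param clustering A `chemotype_clustering` from [cluster_chemotypes()].
#' @return The input with its `chemotype` column filled from the clustering
#'   (unmatched ids keep `"unassigned"` in a library, `"other"` in a table).
#' @export
assign_chemotypes <- function(data, clustering) {
  stopifnot(inherits(clustering, "chemotype_clustering"))
  lab <- clustering$labels
  if (inherits(data, "ligand_library")) {
    m <- match(data$records$ligand_id, lab$ligand_id)
    data$records$chemotype <- ifelse(is.na(m), "unassigned", lab$chemotype[m])
    return(data)
  }
  m <- match(data$ligand_id, lab$ligand_id)
  data$chemotype <- ifelse(is.na(m), "other", lab$chemotype[m])
  data
}

#' Annotate the cluster containing a reference (co-crystal) ligand
#'
#' Marks the chemotype cluster holding a given ligand with a tag, typically
#' the co-crystallized ligand's 3-letter chemical component code.
#'
#' @param clustering A `chemotype_clustering`.
#' @param ligand_id Id of the reference ligand.
#' @param tag Annotation string (e.g. a 3-letter ligand code).
#' @return The clustering with an `annotation` column on `centers`.
#' @export
annotate_cluster <- function(clustering, ligand_id, tag) {
  stopifnot(inherits(clustering, "chemotype_clustering"))
  m <- match(ligand_id, clustering$labels$ligand_id)
  if (is.na(m)) {
    stop(sprintf("ligand '%s' not in the clustering.", ligand_id),
         call. = FALSE)
  }
  chem <- clustering$labels$chemotype[m]
  if (!"annotation" %in% names(clustering$centers)) {
    clustering$centers$annotation <- NA_character_
  }
  clustering$centers$annotation[clustering$centers$chemotype == chem] <- tag
  clustering
}
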