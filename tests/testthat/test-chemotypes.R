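# Chemotype clustering: family recovery, determinism, partition properties.

make_clustered_library <- function(seed = 11, n_enantiomer_pairs = 0) {
  sim <- simulate_library(
    family_sizes = c(4, 3, 3, 2), stereo_fraction = 0.5,
    n_enantiomer_pairs = n_enantiomer_pairs,
    dir = withr::local_tempdir(.local_envir = parent.frame()), seed = seed
  )
  lib <- deduplicate(racemize_library(
    load_library(sim$sdf_file, sim$labels_file)
  ))
  list(lib = lib, truth = sim$truth)
}

test_that("well-separated scaffold families are recovered as A-D", {
  x <- make_clustered_library()
  cl <- cluster_chemotypes(x$lib)

  # oracle check on the dissimilarity matrix itself: within-family
  # dissimilarity strictly below between-family for every pair
  fam <- x$truth$family[match(rownames(cl$matrix), x$truth$ligand_id)]
  same <- outer(fam, fam, "==")
  diag(same) <- NA
  expect_lt(max(cl$matrix[which(same)]), min(cl$matrix[which(!same)]))

  sizes <- dplyr::count(tidy(cl), chemotype)
  expect_equal(sizes$n[match(c("A", "B", "C", "D"), sizes$chemotype)],
               c(4, 3, 3, 2))
  expect_false("other" %in% tidy(cl)$chemotype)

  # labels coincide with generating families
  joined <- dplyr::inner_join(tidy(cl), x$truth, by = "ligand_id")
  expect_equal(joined$chemotype, joined$family)
})

test_that("cluster labels are stable under input permutation", {
  x <- make_clustered_library(seed = 12)
  cl1 <- cluster_chemotypes(x$lib)

  sdf <- x$lib$molecules
  perm <- rev(seq_along(sdf))
  lib2 <- x$lib
  lib2$molecules <- sdf[perm]
  lib2$records <- x$lib$records[perm, ]
  cl2 <- cluster_chemotypes(lib2)

  j <- dplyr::inner_join(tidy(cl1), tidy(cl2), by = "ligand_id")
  expect_equal(j$chemotype.x, j$chemotype.y)
  expect_equal(cl1$centers, cl2$centers)
})

test_that("chemotype labels partition the library", {
  x <- make_clustered_library(seed = 13)
  cl <- cluster_chemotypes(x$lib)
  expect_setequal(tidy(cl)$ligand_id, x$lib$records$ligand_id)
  expect_equal(sum(dplyr::count(tidy(cl), chemotype)$n),
               nrow(x$lib$records))
})

test_that("each named cluster's medoid is a member of that cluster", {
  x <- make_clustered_library(seed = 14)
  cl <- cluster_chemotypes(x$lib)
  for (k in seq_len(nrow(cl$centers))) {
    members <- tidy(cl)$ligand_id[tidy(cl)$chemotype == cl$centers$chemotype[k]]
    expect_true(cl$centers$center_id[k] %in% members)
  }
})

test_that("degenerate libraries are handled: few ligands, identical ligands", {
  sim <- simulate_library(family_sizes = c(4), stereo_fraction = 0,
                          dir = withr::local_tempdir(), seed = 15)
  lib <- load_library(sim$sdf_file)

  # four distinct singletons with max_clusters = 4
  cl4 <- cluster_chemotypes(lib, max_clusters = 4)
  expect_equal(sort(unique(tidy(cl4)$chemotype)), c("A", "B", "C", "D"))
  expect_equal(cl4$centers$size, rep(1L, 4))
  expect_equal(sort(cl4$centers$center_id), sort(tidy(cl4)$ligand_id))

  # all-identical library collapses to a single cluster A
  sdf <- suppressWarnings(lib$molecules[rep(1L, 6)])
  ChemmineR::cid(sdf) <- sprintf("X%d", 1:6)
  same <- load_library(sdf)
  cl1 <- cluster_chemotypes(same)
  expect_equal(unique(tidy(cl1)$chemotype), "A")
})

test_that("the cluster holding the co-crystal ligand can be annotated", {
  x <- make_clustered_library(seed = 16)
  cl <- cluster_chemotypes(x$lib)
  ref <- tidy(cl)$ligand_id[1]
  ann <- annotate_cluster(cl, ref, "CGS")
  tagged <- ann$centers$annotation[
    ann$centers$chemotype == tidy(cl)$chemotype[1]
  ]
  expect_equal(tagged, "CGS")
  expect_error(annotate_cluster(cl, "ZZZ", "CGS"), "not in")
})

test_that("chemotype assignment propagates to score tables and libraries", {
  x <- make_clustered_library(seed = 17)
  cl <- cluster_chemotypes(x$lib)
  lib2 <- assign_chemotypes(x$lib, cl)
  expect_false(any(lib2$records$chemotype == "unassigned"))
  tbl <- tibble::tibble(ligand_id = c(tidy(cl)$ligand_id[1], "DEC1"))
  tbl <- assign_chemotypes(tbl, cl)
  expect_equal(tbl$chemotype[2], "other")
})
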