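# SDF ingestion, stereocenter bookkeeping, racemization and deduplication.

sim_lib <- function(...) {
  simulate_library(dir = withr::local_tempdir(.local_envir = parent.frame()),
                   ...)
}

test_that("malformed SDF records are skipped with a count", {
  sim <- simulate_library(family_sizes = c(3), stereo_fraction = 0,
                          dir = withr::local_tempdir(), seed = 1)
  txt <- readLines(sim$sdf_file)
  # corrupt the second record by destroying its counts line
  starts <- c(1, which(txt == "$$$$") + 1)
  txt[starts[2] + 3] <- "not a counts line"
  bad_file <- file.path(withr::local_tempdir(), "broken.sdf")
  writeLines(txt, bad_file)
  expect_warning(lib <- load_library(bad_file), "1 malformed")
  expect_equal(nrow(lib$records), 2)
  expect_error(load_library(file.path(tempdir(), "nope.sdf")), "not found")
})

test_that("stereocenters are perceived from constitution", {
  sim <- sim_lib(family_sizes = c(4, 3, 3, 2), stereo_fraction = 0.5, seed = 2)
  lib <- load_library(sim$sdf_file, sim$labels_file)
  m <- dplyr::inner_join(lib$records, sim$truth, by = "ligand_id")
  expect_equal(m$n_stereocenters.x, m$n_stereocenters.y)
  expect_equal(m$racemic_flag, m$n_stereocenters.y >= 1)
})

test_that("racemization sets 2^n multiplicities and is an identity on achiral records", {
  sim <- sim_lib(family_sizes = c(4, 3), stereo_fraction = 0.5, seed = 3)
  lib <- load_library(sim$sdf_file)
  rac <- racemize_library(lib)
  expect_equal(rac$records$enantiomer_multiplicity,
               as.integer(2^rac$records$n_stereocenters))
  achiral <- rac$records$n_stereocenters == 0
  expect_equal(rac$records$enantiomer_multiplicity[achiral],
               rep(1L, sum(achiral)))
  expect_true(all(rac$records$racemic_flag == (rac$records$n_stereocenters >= 1)))
  # multiplicity cap
  expect_warning(racemize_library(lib, max_multiplicity = 1L), "cap")
  expect_true(all(suppressWarnings(
    racemize_library(lib, max_multiplicity = 1L)
  )$records$enantiomer_multiplicity == 1L))
})

test_that("a fully achiral library carries no racemic flags", {
  sim <- sim_lib(family_sizes = c(3, 2), stereo_fraction = 0, seed = 4)
  lib <- load_library(sim$sdf_file)
  expect_false(any(lib$records$racemic_flag))
})

test_that("enantiomer doubles collapse to one record, counted once", {
  sim <- sim_lib(family_sizes = c(4, 3, 3, 2), stereo_fraction = 0.5,
                 n_enantiomer_pairs = 3, seed = 5)
  lib <- racemize_library(load_library(sim$sdf_file, sim$labels_file))
  expect_equal(nrow(lib$records), 15)
  ded <- deduplicate(lib)
  expect_equal(nrow(ded$records), 12)
  expect_false(any(duplicated(ded$records$constitution_key)))
  # the id map covers all inputs and routes each double to its original
  expect_equal(nrow(ded$id_map), 15)
  merged <- ded$id_map[ded$id_map$old_id != ded$id_map$new_id, ]
  expect_equal(sort(merged$old_id), sort(paste0(merged$new_id, "ENT")))
})

test_that("deduplicate is idempotent and an identity on distinct libraries", {
  sim <- sim_lib(family_sizes = c(3, 2), stereo_fraction = 0.4,
                 n_enantiomer_pairs = 1, seed = 6)
  lib <- racemize_library(load_library(sim$sdf_file))
  once <- deduplicate(lib)
  twice <- deduplicate(once)
  expect_equal(once$records, twice$records)

  distinct_lib <- racemize_library(
    load_library(sim_lib(family_sizes = c(3), stereo_fraction = 0,
                         seed = 7)$sdf_file)
  )
  expect_equal(deduplicate(distinct_lib)$records$ligand_id,
               distinct_lib$records$ligand_id)
})

test_that("merging conflicting class labels is an error naming the ids", {
  sim <- sim_lib(family_sizes = c(3), stereo_fraction = 0.4,
                 n_enantiomer_pairs = 1, seed = 8)
  labels <- utils::read.csv(sim$labels_file)
  labels$label[labels$ligand_id == "LIG001ENT"] <- "decoy"
  lib <- racemize_library(load_library(sim$sdf_file, labels))
  expect_error(deduplicate(lib), "LIG001")
})

test_that("three copies of one constitution merge into one with a full map", {
  sim <- sim_lib(family_sizes = c(2), stereo_fraction = 0, seed = 9)
  sdf <- ChemmineR::read.SDFset(sim$sdf_file)
  tripled <- suppressWarnings(sdf[c(1, 2, 1, 1)])
  ChemmineR::cid(tripled) <- c("L1", "L2", "L1b", "L1c")
  lib <- deduplicate(racemize_library(load_library(tripled)))
  expect_equal(nrow(lib$records), 2)
  expect_equal(sum(lib$id_map$new_id == "L1"), 3)
})
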