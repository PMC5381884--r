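# Complex loading, pocket definition, superposition and RMSD protocols.

test_that("load_complex strips waters, selects chains and resolves altlocs", {
  pdb <- write_tiny_pdb(file.path(withr::local_tempdir(), "tiny.pdb"))
  cx <- load_complex(pdb, "LIG", chains = "A")
  expect_false(any(cx$atoms$resid == "HOH"))
  expect_true(all(cx$atoms$chain == "A"))
  # altloc A (occupancy 0.6) retained over B (0.4)
  ca <- cx$atoms[cx$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$y, 0)
  expect_equal(cx$ligand$code, "LIG")
  expect_error(load_complex(pdb, "XYZ", chains = "A"), "not found")
  expect_error(load_complex(pdb, "LIG", chains = "Q"), "absent")
})

test_that("pocket membership respects the distance cutoff exactly", {
  gly_at <- function(d) {
    build_toy_complex(tibble::tibble(
      resname = "GLY", resno = 1L, anchor = "N8", distance = d,
      direction = list(c(1, 0, 0))
    ))
  }
  pk_in <- define_pocket(gly_at(4.9), radius = 5)
  expect_equal(pk_in$resno, 1L)
  expect_error(define_pocket(gly_at(5.1), radius = 5), "empty pocket")
  expect_equal(define_pocket(gly_at(5.1), radius = 5.2)$resno, 1L)
})

test_that("a group pocket is the union of member pockets", {
  near <- build_toy_complex(tibble::tibble(
    resname = "SER", resno = 1L, anchor = "N8", distance = 3.5,
    direction = list(c(1, 0, 0))
  ), complex_id = "near")
  far <- build_toy_complex(tibble::tibble(
    resname = "SER", resno = 1L, anchor = "N8", distance = 7,
    direction = list(c(1, 0, 0))
  ), complex_id = "far")
  expect_error(define_pocket(far, radius = 5), "empty pocket")
  grp <- define_pocket(list(near, far), radius = 5)
  expect_equal(grp$resno, 1L)   # union includes residue near in one member
  # group pocket contains every member pocket
  single <- define_pocket(near, radius = 5)
  expect_true(all(paste(single$resno, single$insert) %in%
                    paste(grp$resno, grp$insert)))
})

test_that("superposition undoes any rigid motion (property)", {
  cx <- build_toy_complex()
  set.seed(21)
  for (i in 1:5) {
    moved <- rigid_move(cx, random_rotation(), stats::rnorm(3, sd = 10))
    moved$complex_id <- "moved"
    grp <- superpose_group(list(cx, moved))
    expect_lt(grp$fit$fit_rmsd[2], 1e-6)
    expect_lt(ligand_rmsd(grp$complexes[[1]], grp$complexes[[2]]), 1e-6)
    expect_lt(
      as.numeric(pocket_rmsd(grp$complexes[[1]], grp$complexes[[2]],
                             grp$pocket)),
      1e-6
    )
  }
})

test_that("a moved side-chain does not perturb the backbone fit", {
  cx <- build_toy_complex()
  bent <- cx
  sc <- bent$atoms$resid == "SER" & bent$atoms$elety == "OG"
  bent$atoms$x[sc] <- bent$atoms$x[sc] + 1.5
  bent$complex_id <- "bent"
  grp <- superpose_group(list(cx, bent))
  expect_lt(grp$fit$fit_rmsd[2], 1e-6)
})

test_that("ligand RMSD reflects pure translation and argument order", {
  cx <- build_toy_complex()
  sh <- cx
  sh$ligand$atoms$x <- sh$ligand$atoms$x + 3
  expect_equal(ligand_rmsd(cx, sh), 3, tolerance = 1e-9)
  expect_equal(ligand_rmsd(sh, cx), ligand_rmsd(cx, sh))
  expect_equal(ligand_rmsd(cx, cx), 0)
})

test_that("topological symmetry is minimized over (carboxylate O swap)", {
  cx <- build_toy_complex()
  swapped <- cx
  ix <- match(c("O10", "O11"), swapped$ligand$atoms$name)
  swapped$ligand$atoms[ix, c("x", "y", "z")] <-
    swapped$ligand$atoms[rev(ix), c("x", "y", "z")]
  # same geometry under relabelling: symmetry-aware RMSD is zero
  expect_lt(ligand_rmsd(cx, swapped), 1e-9)
  # name matching alone would see a large displacement
  nm <- sqrt(mean(rowSums((
    as.matrix(cx$ligand$atoms[, c("x", "y", "z")]) -
      as.matrix(swapped$ligand$atoms[, c("x", "y", "z")])
  )^2)))
  expect_gt(nm, 0.5)
})

test_that("symmetry-minimized RMSD matches the brute-force oracle", {
  cx <- build_toy_complex()
  set.seed(31)
  for (i in 1:5) {
    jig <- cx
    pert <- matrix(stats::rnorm(nrow(jig$ligand$atoms) * 3, sd = 0.4), ncol = 3)
    jig$ligand$atoms$x <- jig$ligand$atoms$x + pert[, 1]
    jig$ligand$atoms$y <- jig$ligand$atoms$y + pert[, 2]
    jig$ligand$atoms$z <- jig$ligand$atoms$z + pert[, 3]
    ours <- ligand_rmsd(cx, jig)
    oracle <- brute_force_min_rmsd(cx$ligand, jig$ligand)
    expect_equal(ours, oracle, tolerance = 1e-9)
    # and never exceeds plain name matching
    nm <- sqrt(mean(rowSums(pert^2)))
    expect_lte(ours, nm + 1e-12)
  }
})

test_that("non-isomorphic ligand graphs are refused", {
  cx <- build_toy_complex()
  other <- cx
  other$ligand$bonds <- other$ligand$bonds[-1, ]
  expect_error(ligand_rmsd(cx, other), "not isomorphic")
})

test_that("pocket RMSD skips atoms missing from one complex", {
  cx <- build_toy_complex()
  grp <- superpose_group(list(cx, cx))
  incomplete <- grp$complexes[[2]]
  drop <- incomplete$atoms$resid == "ASP" &
    incomplete$atoms$elety %in% c("OD1", "OD2", "CG")
  incomplete$atoms <- incomplete$atoms[!drop, ]
  r <- pocket_rmsd(grp$complexes[[1]], incomplete, grp$pocket)
  expect_equal(as.numeric(r), 0)
  expect_equal(attr(r, "n_atoms"),
               nrow(dplyr::semi_join(grp$complexes[[1]]$atoms, grp$pocket,
                                     by = c("resno", "insert"))) - sum(drop))

  shifted <- grp$complexes[[2]]
  shifted$atoms$z <- shifted$atoms$z + 2
  expect_equal(as.numeric(pocket_rmsd(grp$complexes[[1]], shifted,
                                      grp$pocket)), 2, tolerance = 1e-9)
})

test_that("rmsd_matrices are symmetric with zero diagonals", {
  cx <- build_toy_complex()
  copy <- rigid_move(cx, random_rotation(), c(4, -2, 1))
  copy$complex_id <- "copy"
  third <- cx
  third$ligand$atoms$y <- third$ligand$atoms$y + 1
  third$complex_id <- "third"
  mats <- rmsd_matrices(superpose_group(list(cx, copy, third)))
  for (m in mats) {
    expect_equal(m, t(m))
    expect_equal(diag(m), stats::setNames(rep(0, 3), rownames(m)))
  }
  expect_lt(mats$ligand["toy1", "copy"], 1e-6)
  expect_equal(mats$ligand["toy1", "third"], 1, tolerance = 1e-9)
})

test_that("disulfide detection uses the S-S distance rule", {
  cx <- build_toy_complex()
  sg <- tibble::tibble(
    chain = "A", resno = c(70L, 71L, 72L), insert = "",
    resid = "CYS", elety = "SG", element = "S",
    x = c(30, 32.0, 40), y = 0, z = 0
  )
  cx$atoms <- dplyr::bind_rows(cx$atoms, sg)
  expect_equal(find_disulfides(cx), c(70L, 71L))  # 2.0 A apart; 72 is lone
})
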