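# Interaction fingerprints on constructed complexes with known contacts.

test_that("the default toy complex realizes exactly its intended bits", {
  cx <- build_toy_complex()
  ifp <- compute_ifp(cx, define_pocket(cx, radius = 20))
  row_of <- function(r) ifp[ifp$resno == r, ]

  asp <- row_of(10)   # carboxylate O 3.0 A from the ligand ammonium
  expect_true(asp$ionic)
  expect_true(asp$hbond_acceptor)
  expect_false(asp$hydrophobic)
  expect_false(asp$aromatic)

  lys <- row_of(20)   # ammonium 2.8 A from the ligand carboxylate
  expect_true(lys$ionic)
  expect_true(lys$hbond_donor)

  ser <- row_of(30)   # hydroxyl donating to a carboxylate oxygen
  expect_true(ser$hbond_donor)
  expect_false(ser$ionic)

  leu <- row_of(40)   # apolar carbon 4.0 A from the ligand methyl
  expect_true(leu$hydrophobic)
  expect_false(any(unlist(leu[c("hbond_donor", "hbond_acceptor", "ionic",
                                "aromatic")])))

  phe <- row_of(50)   # ring centroid 3.8 A over the ligand ring
  expect_true(phe$aromatic)

  gly <- row_of(60)   # 15 A away: all-false row
  expect_false(any(unlist(gly[setdiff(names(gly),
                                      c("resno", "insert", "resid"))])))
})

test_that("interactions vanish when no contact is within 6 A", {
  cx <- build_toy_complex(tibble::tibble(
    resname = c("ASP", "LEU"), resno = c(1L, 2L),
    anchor = c("N8", "C12"), distance = c(8, 9),
    direction = list(c(1, 0, 0), c(0, 1, 0))
  ))
  ifp <- compute_ifp(cx, define_pocket(cx, radius = 20))
  bits <- as.matrix(ifp[, setdiff(names(ifp), c("resno", "insert", "resid"))])
  expect_false(any(bits))
})

test_that("fingerprints are invariant under global rigid motion", {
  cx <- build_toy_complex()
  pk <- define_pocket(cx, radius = 20)
  base <- compute_ifp(cx, pk)
  set.seed(41)
  for (i in 1:3) {
    moved <- rigid_move(cx, random_rotation(), stats::rnorm(3, sd = 20))
    ifp <- compute_ifp(moved, pk)
    expect_equal(tibble::as_tibble(ifp), tibble::as_tibble(base))
  }
})

test_that("hydrogen bonds respect the antecedent angle", {
  # serine hydroxyl pointing its antecedent toward the acceptor fails the
  # >= 90 degree test at short range: emulate by flipping the residue so CB
  # sits between OG and the ligand oxygen
  cx <- build_toy_complex(tibble::tibble(
    resname = "SER", resno = 1L, anchor = "O11", distance = 3.0,
    direction = list(c(0, -1, 0))
  ))
  flipped <- cx
  ix_og <- flipped$atoms$elety == "OG"
  ix_cb <- flipped$atoms$elety == "CB"
  og <- unlist(flipped$atoms[ix_og, c("x", "y", "z")])
  cb <- unlist(flipped$atoms[ix_cb, c("x", "y", "z")])
  # mirror CB through OG so the O11-OG-CB angle collapses
  flipped$atoms[ix_cb, c("x", "y", "z")] <- as.list(2 * og - cb)
  pk <- define_pocket(cx, radius = 20)
  expect_true(compute_ifp(cx, pk)$hbond_donor)
  expect_false(compute_ifp(flipped, pk)$hbond_donor)
})

test_that("heatmaps align rows and localize single-bit differences", {
  cx <- build_toy_complex()
  pk <- define_pocket(cx, radius = 20)
  a <- compute_ifp(cx, pk)

  closer <- build_toy_complex(
    dplyr::mutate(toy_interaction_spec(),
                  distance = replace(distance, resname == "GLY", 4.0)),
    complex_id = "toy2"
  )
  b <- compute_ifp(closer, pk)

  hm <- ifp_heatmap(list(a, b))
  wide <- tidyr::pivot_wider(hm$table,
                             names_from = "complex_id",
                             values_from = "present")
  diff_cells <- wide[wide$toy1 != wide$toy2, ]
  expect_equal(nrow(diff_cells), 1)           # exactly one differing cell
  expect_equal(diff_cells$resno, 60)
  expect_equal(as.character(diff_cells$interaction), "hydrophobic")

  a2 <- a
  attr(a2, "complex_id") <- "toy1bis"
  same <- ifp_heatmap(list(a, a2))
  w2 <- tidyr::pivot_wider(same$table, names_from = "complex_id",
                           values_from = "present")
  expect_equal(w2$toy1, w2$toy1bis)

  expect_error(ifp_heatmap(list()), "empty")
  short <- compute_ifp(cx, define_pocket(cx, radius = 5))
  expect_error(ifp_heatmap(list(a, short)), "row sets")
})
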