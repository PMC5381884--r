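test_that("NSQ_AUC hits its analytic anchors for any class counts", {
  for (counts in list(c(2, 6), c(50, 1950), c(7, 13))) {
    n_tp <- counts[1]; n_fp <- counts[2]
    perfect <- tibble::tibble(
      score = seq_len(n_tp + n_fp),
      class_label = rep(c("active", "decoy"), c(n_tp, n_fp))
    )
    expect_equal(compute_roc(perfect)$nsq_auc, 100)

    worst <- tibble::tibble(
      score = seq_len(n_tp + n_fp),
      class_label = rep(c("decoy", "active"), c(n_fp, n_tp))
    )
    expect_equal(compute_roc(worst)$nsq_auc, -50)

    tied <- tibble::tibble(
      score = rep(0, n_tp + n_fp),
      class_label = rep(c("active", "decoy"), c(n_tp, n_fp))
    )
    tied_roc <- compute_roc(tied)
    expect_equal(tied_roc$nsq_auc, 0)      # exact diagonal
    expect_equal(tied_roc$auc, 0.5)
    expect_equal(nrow(tied_roc$points), 2) # single diagonal segment
  }
})

test_that("the four-compound example reproduces its hand-derived values", {
  tbl <- tibble::tibble(
    score = c(-30, -20, -10, -5),
    class_label = c("active", "decoy", "active", "decoy")
  )
  r <- compute_roc(tbl)
  expect_equal(r$auc, 0.75)
  # SQ_AUC = 0.5*sqrt(0.5) + (1 - sqrt(0.5)); NSQ = 150*SQ - 50
  expect_equal(r$sq_auc, 0.5 * sqrt(0.5) + 1 - sqrt(0.5))
  expect_equal(r$nsq_auc, 150 * r$sq_auc - 50, tolerance = 1e-12)
  expect_equal(r$nsq_auc, 46.97, tolerance = 1e-4)
})

test_that("step-curve AUC agrees with the pairwise-counting oracle", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    n_pos <- sample(1:(n - 1), 1)
    score <- sample(round(stats::rnorm(n), sample(0:2, 1)))  # forces ties
    lab <- rep(c("active", "decoy"), c(n_pos, n - n_pos))
    r <- compute_roc(tibble::tibble(score = score, class_label = lab))
    expect_equal(r$auc, pairwise_auc(score, lab == "active"),
                 tolerance = 1e-12)
  }
})

test_that("NSQ_AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  score <- stats::rnorm(40)
  lab <- rep(c("active", "decoy"), c(10, 30))
  base <- compute_roc(tibble::tibble(score = score, class_label = lab))
  for (f in list(function(s) 2 * s + 3, function(s) s^3,
                 function(s) -exp(-s))) {
    tr <- compute_roc(tibble::tibble(score = f(score), class_label = lab))
    expect_equal(tr$nsq_auc, base$nsq_auc, tolerance = 1e-12)
  }
})

test_that("early recovery is rewarded at fixed AUC", {
  # both rankings have AUC 0.5 over 2 actives x 8 decoys; the first
  # recovers one active immediately, the second buries both mid-list
  early <- rep("decoy", 10); early[c(1, 10)] <- "active"
  late <- rep("decoy", 10); late[c(5, 6)] <- "active"
  r_early <- compute_roc(tibble::tibble(score = 1:10, class_label = early))
  r_late <- compute_roc(tibble::tibble(score = 1:10, class_label = late))
  expect_equal(r_early$auc, r_late$auc)
  expect_gt(r_early$nsq_auc, r_late$nsq_auc)
})

test_that("score direction and degenerate inputs are handled", {
  tbl <- tibble::tibble(score = c(1, 3, 2), class_label = c("d", "a", "d"))
  r <- compute_roc(tbl, positive = "a", lower_is_better = FALSE)
  expect_equal(r$nsq_auc, 100)
  expect_error(
    compute_roc(tibble::tibble(score = 1:3, class_label = rep("active", 3))),
    "two class"
  )
  expect_error(
    compute_roc(tibble::tibble(score = 1:3,
                               class_label = c("x", "y", "x")),
                positive = "active"),
    "absent"
  )
})

test_that("curve points are a monotone path from (0,0) to (1,1)", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    tbl <- tibble::tibble(
      score = round(stats::rnorm(n), 1),
      class_label = sample(c("active", "decoy"), n, replace = TRUE)
    )
    if (dplyr::n_distinct(tbl$class_label) < 2) next
    p <- compute_roc(tbl)$points
    expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
    expect_equal(c(p$fpr[nrow(p)], p$tpr[nrow(p)]), c(1, 1))
    expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
  }
})

test_that("nsq_auc accepts raw curve points and the cognate-rank marker works", {
  grid <- tibble::tibble(fpr = seq(0, 1, length.out = 101),
                         tpr = seq(0, 1, length.out = 101))
  expect_equal(nsq_auc(grid), 0, tolerance = 1e-12)

  tbl <- tibble::tibble(
    ligand_id = c("cog", "d1", "d2", "a2", "d3"),
    score = c(-30, -25, -12, -10, -5),
    class_label = c("active", "decoy", "decoy", "active", "decoy")
  )
  expect_equal(ligand_rank_fpr(tbl, "cog"), 0)
  expect_equal(ligand_rank_fpr(tbl, "a2"), 2 / 3)
})
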