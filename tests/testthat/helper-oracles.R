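# Independent oracles and small builders shared across tests.

# Pairwise-counting AUC: fraction of (positive, negative) pairs where the
# positive outranks the negative, ties counting 1/2. Independent of the
# step-curve construction.
pairwise_auc <- function(score, is_pos, lower_is_better = TRUE) {
  s <- if (lower_is_better) -score else score
  pos <- s[is_pos]
  neg <- s[!is_pos]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct-counting enrichment factor for one chemotype.
counting_ef <- function(score, is_tp_chem, x_percent,
                        lower_is_better = TRUE) {
  n <- length(score)
  o <- order(if (lower_is_better) score else -score)
  n_x <- max(1, floor(x_percent * n / 100 + 0.5))
  tp <- sum(is_tp_chem)
  tp_x <- sum(is_tp_chem[o][seq_len(n_x)])
  (tp_x / n_x) / (tp / n)
}

# random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion to a gpcr_complex
rigid_move <- function(cx, rot = diag(3), shift = c(0, 0, 0)) {
  mv <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- m[, 1] + shift[1]
    df$y <- m[, 2] + shift[2]
    df$z <- m[, 3] + shift[3]
    df
  }
  cx$atoms <- mv(cx$atoms)
  cx$ligand$atoms <- mv(cx$ligand$atoms)
  cx
}

# Brute-force ligand correspondence oracle: all element- and
# adjacency-preserving bijections a -> b by backtracking, independent of
# igraph. Returns the minimum RMSD over them (NULL if none).
brute_force_min_rmsd <- function(lig_a, lig_b) {
  n <- nrow(lig_a$atoms)
  adj <- function(lig) {
    m <- matrix(FALSE, n, n)
    for (k in seq_len(nrow(lig$bonds))) {
      m[lig$bonds$a1[k], lig$bonds$a2[k]] <- TRUE
      m[lig$bonds$a2[k], lig$bonds$a1[k]] <- TRUE
    }
    m
  }
  aa <- adj(lig_a); ab <- adj(lig_b)
  ea <- lig_a$atoms$element; eb <- lig_b$atoms$element
  xa <- as.matrix(lig_a$atoms[, c("x", "y", "z")])
  xb <- as.matrix(lig_b$atoms[, c("x", "y", "z")])
  best <- Inf
  assign_next <- function(map, used) {
    i <- length(map) + 1L
    if (i > n) {
      r <- sqrt(mean(rowSums((xa - xb[map, , drop = FALSE])^2)))
      best <<- min(best, r)
      return(invisible())
    }
    for (j in which(!used & eb == ea[i])) {
      ok <- TRUE
      for (k in seq_len(i - 1L)) {
        if (aa[i, k] != ab[j, map[k]]) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(map, j), `[<-`(used, j, TRUE))
    }
  }
  assign_next(integer(), rep(FALSE, n))
  if (is.infinite(best)) NULL else best
}

# minimal PDB text fixture: two chains, a water, an altloc pair, a ligand
write_tiny_pdb <- function(path) {
  fmt <- function(serial, name, alt, resn, chain, resno, x, y, z, occ, elem,
                  record = "ATOM") {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            record, serial, name, alt, resn, chain, resno, x, y, z, occ,
            30.0, elem)
  }
  lines <- c(
    fmt(1, " N", " ", "GLY", "A", 1, 0, 0, 0, 1, "N"),
    fmt(2, " CA", "A", "GLY", "A", 1, 1.45, 0, 0, 0.6, "C"),
    fmt(3, " CA", "B", "GLY", "A", 1, 1.45, 0.5, 0, 0.4, "C"),
    fmt(4, " C", " ", "GLY", "A", 1, 2.0, 1.3, 0, 1, "C"),
    fmt(5, " O", " ", "GLY", "A", 1, 3.2, 1.4, 0, 1, "O"),
    fmt(6, " N", " ", "ALA", "B", 5, 8, 8, 8, 1, "N"),
    fmt(7, " CA", " ", "ALA", "B", 5, 9.45, 8, 8, 1, "C"),
    fmt(8, " O", " ", "HOH", "A", 101, 5, 5, 5, 1, "O", "HETATM"),
    fmt(9, " C1", " ", "LIG", "A", 900, 2.0, -2.0, 0, 1, "C", "HETATM"),
    fmt(10, " C2", " ", "LIG", "A", 900, 3.4, -2.0, 0, 1, "C", "HETATM"),
    "END"
  )
  writeLines(lines, path)
  path
}
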