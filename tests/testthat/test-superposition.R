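test_that("residue pairing handles identity, deletions, and matches an independent DP", {
  co <- helix_coords(50)
  m1 <- seq_model("A", paste(rep("ACDEFGHIKL", 5), collapse = ""), co)
  pr <- pair_residues(m1, "A", m1, "A")
  expect_equal(nrow(pr$pairs), 50L)
  expect_equal(pr$pairs$resno_a, pr$pairs$resno_b)

  # internal deletion: pairing skips the gap, numbering re-syncs after it
  s <- "ACDEFGHIKLMNPQRSTVWY"
  s_del <- paste0(substr(s, 1, 8), substr(s, 12, 20))   # drop residues 9-11
  m_full <- seq_model("A", s, helix_coords(20))
  m_del <- seq_model("B", s_del, helix_coords(17))
  pr2 <- pair_residues(m_full, "A", m_del, "B")
  expect_equal(nrow(pr2$pairs), 17L)
  expect_false(any(pr2$pairs$resno_a %in% 9:11))
  expect_equal(pr2$pairs$resno_b[pr2$pairs$resno_a == 12], 9L)

  # random 30-mers against the memoized-recursion oracle
  withr::with_seed(55, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:8) {
      sa <- paste(sample(aa, 30, replace = TRUE), collapse = "")
      sb <- paste(sample(aa, 30, replace = TRUE), collapse = "")
      ma <- seq_model("A", sa, helix_coords(30))
      mb <- seq_model("B", sb, helix_coords(30))
      got <- pair_residues(ma, "A", mb, "B")
      want <- oracle_align(sa, sb)
      expect_equal(got$score, want$score)
      expect_equal(cbind(got$pairs$resno_a, got$pairs$resno_b),
                   unname(want$pairs))
    }
  })

  short <- seq_model("A", "AC", helix_coords(2))
  expect_error(pair_residues(short, "A", short, "A"), "insufficient")
})

test_that("alignment score agrees with Biostrings under the same scoring scheme", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(66, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    sub_mat <- matrix(0, 20, 20, dimnames = list(aa, aa))
    diag(sub_mat) <- 1
    for (rep in 1:5) {
      sa <- paste(sample(aa, 25, replace = TRUE), collapse = "")
      sb <- paste(sample(aa, 28, replace = TRUE), collapse = "")
      got <- pair_residues(seq_model("A", sa, helix_coords(25)), "A",
                           seq_model("B", sb, helix_coords(28)), "B")
      ref <- Biostrings::pairwiseAlignment(
        sa, sb, type = "global", substitutionMatrix = sub_mat,
        gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)
      expect_equal(got$score, as.numeric(ref))
    }
  })
})

test_that("Kabsch fit recovers planted transforms and stays a proper rotation", {
  withr::with_seed(21, {
    A <- matrix(rnorm(30, sd = 8), ncol = 3)

    fit0 <- kabsch_fit(A, A)
    expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
    expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-9)
    expect_equal(fit0$rmsd, 0, tolerance = 1e-9)

    for (rep in 1:10) {
      R <- random_rotation(); t_vec <- rnorm(3, sd = 20)
      B <- sweep(A %*% t(R), 2, t_vec, "+")
      fit <- kabsch_fit(A, B)
      expect_equal(fit$rotation, R, tolerance = 1e-9)
      expect_equal(fit$translation, t_vec, tolerance = 1e-8)
      expect_lt(fit$rmsd, 1e-9)
      expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    }

    # mirror image: reflection branch corrected, still det = +1, rmsd > 0
    Bm <- A; Bm[, 1] <- -Bm[, 1]
    fitm <- kabsch_fit(A, Bm)
    expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
    expect_gt(fitm$rmsd, 0.1)

    # cross-check the minimized RMSD against bio3d's least-squares fit
    R <- random_rotation(); t_vec <- rnorm(3, sd = 5)
    B2 <- sweep(A %*% t(R), 2, t_vec, "+") + matrix(rnorm(30, sd = 0.4), ncol = 3)
    fit2 <- kabsch_fit(A, B2)
    ref <- bio3d::rmsd(as.numeric(t(B2)), as.numeric(t(A)), fit = TRUE)
    expect_equal(fit2$rmsd, ref, tolerance = 1e-3)   # bio3d prints 3 decimals

    line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
    expect_error(kabsch_fit(line, line), "rank-deficient")
    expect_error(kabsch_fit(A[1:2, ], A[1:2, ]), "at least 3")
  })
})

test_that("anchored superposition: identity, pure translation, and lower bound", {
  rod <- make_rod(4, n_res = 20, seed = 5)

  # mobile == reference -> all zeros
  res0 <- anchored_rmsd(rod$model, rod$model, rod$map, anchor = "M1")
  expect_true(all(res0$per_unit_rmsd < 1e-9))

  # translate unit 2 by exactly 3 A with the anchor untouched
  pert <- perturb_assembly(rod, list(M2 = list(t = c(3, 0, 0))), anchor = "M1")
  res <- anchored_rmsd(pert$model, rod$model, pert$map, rod$map, anchor = "M1")
  expect_equal(res$per_unit_rmsd[["M2"]], 3.0, tolerance = 1e-9)
  expect_equal(res$per_unit_rmsd[["M1"]], 0.0, tolerance = 1e-9)
  expect_equal(res$per_unit_rmsd[["M1"]], res$anchor_rmsd)

  # anchored per-unit RMSD can never beat that unit's dedicated fit
  withr::with_seed(31, {
    tfs <- list(M2 = list(R = random_rotation(), t = rnorm(3, sd = 2)),
                M3 = list(t = rnorm(3, sd = 4)),
                M4 = list(R = random_rotation(), t = rnorm(3)))
    pert2 <- perturb_assembly(rod, tfs, anchor = "M1")
    res2 <- anchored_rmsd(pert2$model, rod$model, pert2$map, rod$map,
                          anchor = "M1")
    uc <- pbsfret:::unit_chain_table(rod$map)
    for (u in c("M2", "M3", "M4")) {
      sel_chains <- uc$chain[uc$unit == u]
      mob <- pert2$model$atoms[pert2$model$atoms$chain %in% sel_chains &
                                 pert2$model$atoms$elety == "CA", ]
      ref <- rod$model$atoms[rod$model$atoms$chain %in% sel_chains &
                               rod$model$atoms$elety == "CA", ]
      ded <- kabsch_fit(as.matrix(mob[, c("x", "y", "z")]),
                        as.matrix(ref[, c("x", "y", "z")]))
      expect_gte(res2$per_unit_rmsd[[u]] + 1e-9, ded$rmsd)
    }
    # and results are invariant under a common rigid motion of the mobile set
    Rg <- random_rotation(); tg <- rnorm(3, sd = 30)
    moved <- pert2$model
    xyz <- as.matrix(moved$atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz %*% t(Rg), 2, tg, "+")
    moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]; moved$atoms$z <- xyz[, 3]
    res3 <- anchored_rmsd(moved, rod$model, pert2$map, rod$map, anchor = "M1")
    expect_equal(res3$per_unit_rmsd, res2$per_unit_rmsd, tolerance = 1e-6)
  })
})

test_that("planted per-unit displacements are recovered to analytic precision", {
  rod <- make_rod(5, n_res = 18, seed = 8)
  withr::with_seed(41, {
    tfs <- list(M2 = list(t = c(0, 4, 0)),
                M3 = list(R = random_rotation()),
                M5 = list(R = random_rotation(), t = rnorm(3, sd = 3)))
    pert <- perturb_assembly(rod, tfs, anchor = "M1")
  })
  res <- anchored_rmsd(pert$model, rod$model, pert$map, rod$map, anchor = "M1")
  manifest <- pert$manifest$units
  expect_equal(res$per_unit_rmsd[manifest$unit], setNames(manifest$rmsd, manifest$unit),
               tolerance = 1e-6)

  # survives a PDB round trip at format precision
  d <- withr::local_tempdir()
  pm <- write_fixture(pert, d, name = "mob")
  pb <- write_fixture(rod, d, name = "ref")
  res_rt <- anchored_rmsd(read_structure(pm$pdb), read_structure(pb$pdb),
                          pert$map, rod$map, anchor = "M1")
  expect_equal(res_rt$per_unit_rmsd[manifest$unit],
               setNames(manifest$rmsd, manifest$unit), tolerance = 1e-3)
})

test_that("region RMSD is zero on self and on rigid copies", {
  m <- seq_model("A", "ACDEFGHIKLMNPQRSTVWY", helix_coords(20))
  expect_equal(region_rmsd(m, "A", c(3, 15), m, "A", c(3, 15)), 0,
               tolerance = 1e-9)

  withr::with_seed(51, {
    R <- random_rotation(); t_vec <- rnorm(3, sd = 12)
    co2 <- sweep(helix_coords(20) %*% t(R), 2, t_vec, "+")
    m2 <- seq_model("B", "ACDEFGHIKLMNPQRSTVWY", co2)
    expect_equal(region_rmsd(m, "A", c(1, 20), m2, "B", c(1, 20)), 0,
                 tolerance = 1e-9)
  })
  expect_error(region_rmsd(m, "A", c(30, 40), m, "A", c(1, 20)), "empty")
})
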