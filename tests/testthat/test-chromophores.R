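test_that("extraction honours the map: counts, IDs, unmapped chains, empty models", {
  ring <- make_ring(6, 18, "radial")
  chroms <- extract_chromophores(ring$model, ring$map)
  expect_length(chroms, 6L)
  expect_equal(vapply(chroms, function(ch) ch$id$rendered, character(1)),
               ring$manifest$chromophores$id)

  # chain ordering in the file does not change the extracted set
  shuffled <- ring$model
  ord <- order(match(shuffled$atoms$chain, rev(model_chains(shuffled))))
  shuffled$atoms <- shuffled$atoms[ord, ]
  chroms2 <- extract_chromophores(shuffled, ring$map)
  expect_setequal(vapply(chroms2, function(ch) ch$id$rendered, character(1)),
                  ring$manifest$chromophores$id)

  # no ligand residues -> empty list
  rod <- make_rod(1, n_res = 10)
  expect_length(extract_chromophores(rod$model, rod$map), 0L)

  # ligand on an unmapped chain is skipped with a notice
  partial <- ring$map
  partial$chain_assignments <- partial$chain_assignments[-1, ]
  expect_message(ch3 <- extract_chromophores(ring$model, partial), "unmapped")
  expect_length(ch3, 5L)
})

test_that("ligands missing conjugated atoms are flagged, warned, and gated out of pairs", {
  ring <- make_ring(3, 20, "tangent")
  broken <- ring$model
  drop <- which(broken$atoms$chain == "A")[1:3]   # leaves 2 of 5 atoms
  broken$atoms <- broken$atoms[-drop, ]
  expect_warning(chroms <- extract_chromophores(broken, ring$map),
                 "incomplete")
  expect_length(chroms, 3L)
  flags <- vapply(chroms, function(ch) ch$incomplete, logical(1))
  expect_equal(sum(flags), 1L)
  pairs <- all_pairs(chroms, cutoff = 50)
  ids <- unique(c(pairs$donor_id, pairs$acceptor_id))
  expect_false(chroms[[which(flags)]]$id$rendered %in% ids)
  expect_equal(nrow(pairs), 1L)
})

test_that("attachment cysteine resolution uses the nearest SG within 2.5 A", {
  ring <- make_ring(2, 10, "axial")
  # plant a cysteine with SG 1.8 A from a ligand atom of chain A
  lig <- ring$model$atoms[ring$model$atoms$chain == "A", ][1, ]
  cys <- data.frame(chain = "A", resno = 84L, insert = "", resid = "CYS",
                    elety = "SG", elesy = "S",
                    x = lig$x + 1.8, y = lig$y, z = lig$z,
                    occ = 1, het = FALSE, stringsAsFactors = FALSE)
  model <- pbsfret:::new_structure_model("fix", rbind(ring$model$atoms, cys), "pdb")
  chroms <- extract_chromophores(model, ring$map)
  byid <- chroms[[which(vapply(chroms, function(c) c$parent_chain, character(1)) == "A")]]
  expect_equal(byid$id$attach_residue, 84L)
  expect_false(byid$attach_fallback)
  expect_match(byid$id$rendered, "-84$")
  other <- chroms[[which(vapply(chroms, function(c) c$parent_chain, character(1)) == "B")]]
  expect_true(other$attach_fallback)   # no SG near chain B's ligand
})

test_that("dipole assignment follows the principal axis and the sign rule", {
  # collinear atoms along +z, sign reference first -> last
  ch <- point_chromophore("Z1-a1-1", c(0, 0, 0), c(0, 0, 1))
  map <- assembly_map(data.frame(chain = "A", cylinder = "Z", unit_index = 1,
                                 role = "ApcA"),
                      conjugated_atoms = paste0("A", 1:5),
                      sign_reference = c("A1", "A5"))
  d <- assign_dipole(ch, map)
  expect_equal(d$direction, c(0, 0, 1), tolerance = 1e-9)

  # reversed sign reference flips the direction
  map_rev <- assembly_map(data.frame(chain = "A", cylinder = "Z",
                                     unit_index = 1, role = "ApcA"),
                          conjugated_atoms = paste0("A", 1:5),
                          sign_reference = c("A5", "A1"))
  expect_equal(assign_dipole(ch, map_rev)$direction, c(0, 0, -1),
               tolerance = 1e-9)

  # nearly isotropic atom cloud -> degenerate axis is an error
  iso <- ch
  iso$conjugated_coords <- rbind(diag(3), -diag(3))
  rownames(iso$conjugated_coords) <- paste0("A", 1:6)
  expect_error(assign_dipole(iso, map), "dipole axis undefined")
})

test_that("principal axis matches an independent characteristic-polynomial solver", {
  map <- assembly_map(data.frame(chain = "A", cylinder = "Z", unit_index = 1,
                                 role = "ApcA"),
                      conjugated_atoms = paste0("A", 1:8),
                      sign_reference = c("A1", "A8"))
  withr::with_seed(42, {
    for (rep in 1:20) {
      # planar zig-zag with a dominant axis, randomly rotated
      base <- cbind(seq(0, 7), rep(c(0, 0.8), 4), rep(0, 8))
      R <- random_rotation()
      coords <- base %*% t(R) + matrix(rnorm(3, sd = 20), 8, 3, byrow = TRUE)
      rownames(coords) <- paste0("A", 1:8)
      ch <- point_chromophore("Z1-a1-1", colMeans(coords), c(1, 0, 0))
      ch$conjugated_coords <- coords
      got <- assign_dipole(ch, map)$direction
      cv <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
      want <- oracle_principal_axis(cv)$vector
      if (sum(want * (coords[8, ] - coords[1, ])) < 0) want <- -want
      expect_lt(max(abs(got - want)), 1e-6)
    }
  })
})

test_that("dipole and centroid are equivariant under rigid motion", {
  map <- assembly_map(data.frame(chain = "A", cylinder = "Z", unit_index = 1,
                                 role = "ApcA"),
                      conjugated_atoms = paste0("A", 1:5),
                      sign_reference = c("A1", "A5"))
  withr::with_seed(11, {
    for (rep in 1:10) {
      ch <- point_chromophore("Z1-a1-1", rnorm(3, sd = 5), random_unit())
      R <- random_rotation(); t_vec <- rnorm(3, sd = 10)
      moved <- ch
      moved$conjugated_coords <- sweep(ch$conjugated_coords %*% t(R), 2, t_vec, "+")
      moved$centroid <- colMeans(moved$conjugated_coords)
      expect_equal(moved$centroid, as.numeric(R %*% ch$centroid) + t_vec,
                   tolerance = 1e-9)
      d0 <- assign_dipole(ch, map)$direction
      d1 <- assign_dipole(moved, map)$direction
      expect_equal(d1, as.numeric(R %*% d0), tolerance = 1e-6)
    }
  })
})

test_that("environment listing returns residues by ascending minimum distance", {
  ring <- make_ring(2, 50, "axial")
  lig_centroid <- ring$manifest$chromophores[1, c("cx", "cy", "cz")]
  res1 <- data.frame(chain = "P", resno = 992L, insert = "", resid = "PHE",
                     elety = "CA", elesy = "C",
                     x = as.numeric(lig_centroid[1]) + 3,
                     y = as.numeric(lig_centroid[2]),
                     z = as.numeric(lig_centroid[3]),
                     occ = 1, het = FALSE, stringsAsFactors = FALSE)
  res2 <- res1; res2$resno <- 10L; res2$resid <- "TYR"; res2$x <- res1$x + 1.5
  model <- pbsfret:::new_structure_model(
    "envfix", rbind(ring$model$atoms, res1, res2), "pdb")
  chroms <- extract_chromophores(model, ring$map)
  ch <- chroms[[1]]

  env0 <- chromophore_environment(ch, model, cutoff = 0.1)
  expect_equal(nrow(env0), 0L)

  env <- chromophore_environment(ch, model, cutoff = 5)
  expect_equal(env$residue[1], "Phe992/P")
  # constructed distance: nearest ligand atom sits 1 A above the centroid line
  expect_equal(env$min_dist[1], sqrt(3^2 + 0^2), tolerance = 1e-3)
  expect_true(all(diff(env$min_dist) >= 0))
  expect_true("Tyr10/P" %in% env$residue)
})

test_that("terminal emitters are recognised from role and attachment site", {
  ring <- make_ring(2, 30, "axial")
  chroms <- extract_chromophores(ring$model, ring$map)
  expect_length(find_terminal_emitters(chroms), 0L)
  chroms[[1]]$id$role <- "ApcE"; chroms[[1]]$id$attach_residue <- 198L
  chroms[[2]]$id$role <- "ApcD"; chroms[[2]]$id$attach_residue <- 81L
  expect_length(find_terminal_emitters(chroms), 2L)
})
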