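# Seeded generators for fixtures with analytic ground truth: rings of
# pseudo-chromophores (mimicking the geometry of allophycocyanin trimer
# rings), stacked rings (cylinder stacking), and multi-monomer rods with
# planted rigid perturbations (the crystal-vs-cryo-EM rearrangement scenario).
# Pseudo-chromophores are 5-atom collinear runs reusing the configured
# conjugated atom names, so principal-axis dipole assignment reproduces the
# intended direction exactly, and the fixtures survive PDB round trips.

fixture_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  if (n > length(pool)) stop("too many chains for single-character IDs")
  pool[seq_len(n)]
}

pseudo_bilin_atoms <- function(center, direction, atom_names, chain, resno,
                               ligand_code, spacing = 0.5) {
  k <- length(atom_names)
  offs <- spacing * (seq_len(k) - (k + 1) / 2)
  data.frame(chain = chain, resno = resno, insert = "",
             resid = ligand_code, elety = atom_names,
             elesy = "C",
             x = center[1] + offs * direction[1],
             y = center[2] + offs * direction[2],
             z = center[3] + offs * direction[3],
             occ = 1, het = TRUE, stringsAsFactors = FALSE)
}

ring_positions <- function(n, radius, phase = 0, z = 0, center = c(0, 0, 0)) {
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + radius * cos(ang),
        center[2] + radius * sin(ang),
        center[3] + z)
}

ring_direction <- function(ang, dipole_mode) {
  switch(dipole_mode,
         tangent = c(-sin(ang), cos(ang), 0),
         radial = c(cos(ang), sin(ang), 0),
         axial = c(0, 0, 1))
}

#' Generate a ring of pseudo-chromophores
#'
#' `n` pseudo-chromophores equally spaced on a circle of the given radius in
#' the z = `z_offset` plane, each a 5-atom collinear run oriented tangent,
#' radial, or axial. The manifest records exact centroids, dipoles, and the
#' analytic pairwise distances (chord lengths `2 R sin(k pi / n)`).
#'
#' @param n Number of chromophores (>= 2).
#' @param radius Ring radius in Angstrom (> 0).
#' @param dipole_mode `"tangent"`, `"radial"`, or `"axial"`.
#' @param seed Integer seed recorded in the manifest (ring geometry itself is
#'   deterministic).
#' @param phase Angular phase of the first chromophore (radians).
#' @param z_offset Ring plane height.
#' @param cylinder Cylinder label for the assembly map (default `"R"`).
#' @param ring_index Unit index for the assembly map.
#' @param chain_ids Optional chain IDs (default consecutive single characters
#'   starting at `chain_offset`).
#' @param chain_offset Index into the default chain-ID pool.
#' @return A `synthetic_assembly`: list with `model`, `map`, `manifest`
#'   (chromophores, distances), `seed`, `params`.
#' @export
make_ring <- function(n, radius, dipole_mode = c("tangent", "radial", "axial"),
                      seed = 1L, phase = 0, z_offset = 0, cylinder = "R",
                      ring_index = 1L, chain_ids = NULL, chain_offset = 0L) {
  dipole_mode <- match.arg(dipole_mode)
  if (!is.finite(n) || n < 2L) stop("n must be >= 2")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  n <- as.integer(n)

  atom_names <- default_conjugated_atoms()[1:5]
  if (is.null(chain_ids))
    chain_ids <- fixture_chain_ids(chain_offset + n)[chain_offset + seq_len(n)]
  pos <- ring_positions(n, radius, phase, z_offset)
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n

  atoms <- list(); dirs <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    dirs[k, ] <- ring_direction(ang[k], dipole_mode)
    atoms[[k]] <- pseudo_bilin_atoms(pos[k, ], dirs[k, ], atom_names,
                                     chain_ids[k], resno = 1L,
                                     ligand_code = "CYC")
  }
  model <- new_structure_model(
    sprintf("ring_n%d_r%g", n, radius), do.call(rbind, atoms), "pdb")

  map <- assembly_map(
    chains = data.frame(chain = chain_ids, cylinder = cylinder,
                        unit_index = ring_index, role = "ApcA",
                        subunit_number = seq_len(n),
                        stringsAsFactors = FALSE),
    conjugated_atoms = atom_names,
    sign_reference = c(atom_names[1], atom_names[5]))

  ids <- render_chromophore_id(cylinder, ring_index,
                               paste0("a", seq_len(n)), 1L)
  manifest <- list(
    chromophores = data.frame(id = ids, chain = chain_ids,
                              cx = pos[, 1], cy = pos[, 2], cz = pos[, 3],
                              dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                              stringsAsFactors = FALSE),
    distances = ring_distances(ids, n, radius))
  structure(list(model = model, map = map, manifest = manifest,
                 seed = as.integer(seed),
                 params = list(kind = "ring", n = n, radius = radius,
                               dipole_mode = dipole_mode, phase = phase,
                               z_offset = z_offset)),
            class = "synthetic_assembly")
}

ring_distances <- function(ids, n, radius, z = rep(0, n)) {
  out <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    chord <- 2 * radius * sin(abs(j - i) * pi / n)
    out[[length(out) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j],
      r = sqrt(chord^2 + (z[j] - z[i])^2), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.synthetic_assembly <- function(x, ...) {
  cat(sprintf("<synthetic_assembly> %s: %d atoms, %d chains, seed %d\n",
              x$params$kind, nrow(x$model$atoms),
              length(model_chains(x$model)), x$seed))
  invisible(x)
}

#' Generate stacked rings of pseudo-chromophores
#'
#' `n_rings` copies of [make_ring()] stacked along z at the given spacing,
#' each ring labelled as its own cylinder (`R1`, `R2`, ...). With aligned
#' phases the nearest inter-ring pair distance is exactly `spacing`. All
#' pairwise distances are analytic in the manifest.
#'
#' @param n_rings Number of rings (>= 1).
#' @param spacing Inter-ring z spacing in Angstrom (> 0).
#' @param n Chromophores per ring.
#' @param radius Ring radius.
#' @param dipole_mode Dipole orientation mode passed to each ring.
#' @param phases Angular phase per ring (recycled; default aligned).
#' @param seed Integer seed recorded in the manifest.
#' @return A `synthetic_assembly`.
#' @export
make_stacked_rings <- function(n_rings, spacing, n = 3, radius = 20,
                               dipole_mode = "tangent", phases = 0,
                               seed = 1L) {
  if (!is.finite(n_rings) || n_rings < 1L) stop("n_rings must be >= 1")
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  n_rings <- as.integer(n_rings)
  phases <- rep_len(phases, n_rings)

  rings <- lapply(seq_len(n_rings), function(i)
    make_ring(n, radius, dipole_mode, seed = seed, phase = phases[i],
              z_offset = (i - 1) * spacing, cylinder = paste0("R", i),
              ring_index = 1L, chain_offset = (i - 1L) * n))

  atoms <- do.call(rbind, lapply(rings, function(r) r$model$atoms))
  chains <- do.call(rbind, lapply(rings, function(r) r$map$chain_assignments))
  model <- new_structure_model(
    sprintf("stack_%dx%d_s%g", n_rings, n, spacing), atoms, "pdb")
  map <- assembly_map(chains = chains,
                      conjugated_atoms = rings[[1]]$map$conjugated_atoms,
                      sign_reference = rings[[1]]$map$sign_reference)

  chrom <- do.call(rbind, lapply(rings, function(r) r$manifest$chromophores))
  # analytic all-pairs distances across the whole stack
  dist_rows <- list()
  ncum <- nrow(chrom)
  for (i in seq_len(ncum - 1L)) for (j in seq((i + 1L), ncum)) {
    ri <- (i - 1L) %/% n; rj <- (j - 1L) %/% n
    ki <- (i - 1L) %% n; kj <- (j - 1L) %% n
    dphi <- (phases[rj + 1L] + 2 * pi * kj / n) -
      (phases[ri + 1L] + 2 * pi * ki / n)
    chord <- 2 * radius * abs(sin(dphi / 2))
    dz <- (rj - ri) * spacing
    dist_rows[[length(dist_rows) + 1L]] <- data.frame(
      id_a = chrom$id[i], id_b = chrom$id[j], r = sqrt(chord^2 + dz^2),
      stringsAsFactors = FALSE)
  }
  manifest <- list(chromophores = chrom, distances = do.call(rbind, dist_rows))
  structure(list(model = model, map = map, manifest = manifest,
                 seed = as.integer(seed),
                 params = list(kind = "stacked_rings", n_rings = n_rings,
                               spacing = spacing, n = n, radius = radius,
                               dipole_mode = dipole_mode, phases = phases)),
            class = "synthetic_assembly")
}

#' Generate a synthetic multi-monomer rod
#'
#' `n_units` alpha/beta monomers stacked along z. Each monomer holds two
#' chains (roles CpcA and CpcB) of `n_res` C-alpha-only residues laid out on a
#' coarse helix, with identical sequences across units (drawn once from the
#' seed), so residue pairing between corresponding units is the identity.
#' Optionally each beta chain carries one pseudo-bilin.
#'
#' @param n_units Number of monomers (>= 1, <= 13 for single-character chain
#'   IDs).
#' @param n_res Residues per chain (>= 8).
#' @param seed Integer seed for sequence and helix jitter.
#' @param rise Monomer-to-monomer z offset in Angstrom.
#' @param include_chromophores Attach one pseudo-bilin per beta chain.
#' @return A `synthetic_assembly` whose manifest includes a `units` table
#'   (unit label, planted RMSD, initially 0).
#' @export
make_rod <- function(n_units, n_res = 24, seed = 1L, rise = 30,
                     include_chromophores = FALSE) {
  if (!is.finite(n_units) || n_units < 1L) stop("n_units must be >= 1")
  if (!is.finite(n_res) || n_res < 8L) stop("n_res must be >= 8")
  n_units <- as.integer(n_units); n_res <- as.integer(n_res)

  aa3 <- c("ALA", "ARG", "ASN", "ASP", "GLN", "GLU", "GLY", "HIS", "ILE",
           "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR",
           "VAL")
  geom <- withr::with_seed(as.integer(seed), {
    list(seq_a = sample(aa3, n_res, replace = TRUE),
         seq_b = sample(aa3, n_res, replace = TRUE),
         jit_a = matrix(stats::rnorm(3L * n_res, sd = 0.3), ncol = 3),
         jit_b = matrix(stats::rnorm(3L * n_res, sd = 0.3), ncol = 3))
  })

  helix <- function(n, radius, twist, rise_per_res, offset, jitter) {
    i <- seq_len(n) - 1
    cbind(radius * cos(i * twist) + offset[1],
          radius * sin(i * twist) + offset[2],
          i * rise_per_res + offset[3]) + jitter
  }
  chain_atoms <- function(chain, seq3, coords) {
    data.frame(chain = chain, resno = seq_along(seq3), insert = "",
               resid = seq3, elety = "CA", elesy = "C",
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               occ = 1, het = FALSE, stringsAsFactors = FALSE)
  }

  chains <- fixture_chain_ids(2L * n_units +
                                if (include_chromophores) 0L else 0L)
  atoms <- list(); asn <- list()
  for (u in seq_len(n_units)) {
    base_z <- (u - 1) * rise
    ca_chain <- chains[2L * u - 1L]; cb_chain <- chains[2L * u]
    xa <- helix(n_res, 6, 1.75, 1.6, c(0, 0, base_z), geom$jit_a)
    xb <- helix(n_res, 6, 1.75, 1.6, c(9, 3, base_z + 2), geom$jit_b)
    atoms[[length(atoms) + 1L]] <- chain_atoms(ca_chain, geom$seq_a, xa)
    atoms[[length(atoms) + 1L]] <- chain_atoms(cb_chain, geom$seq_b, xb)
    if (include_chromophores)
      atoms[[length(atoms) + 1L]] <- pseudo_bilin_atoms(
        colMeans(xb) + c(4, -3, 0), c(0, 0, 1),
        default_conjugated_atoms()[1:5], cb_chain, resno = n_res + 1L,
        ligand_code = "CYC")
    asn[[length(asn) + 1L]] <- data.frame(
      chain = c(ca_chain, cb_chain), cylinder = "M", unit_index = u,
      role = c("CpcA", "CpcB"), subunit_number = 1L, stringsAsFactors = FALSE)
  }
  model <- new_structure_model(sprintf("rod_%dx%d", n_units, n_res),
                               do.call(rbind, atoms), "pdb")
  map <- assembly_map(chains = do.call(rbind, asn),
                      conjugated_atoms = default_conjugated_atoms()[1:5],
                      sign_reference = default_conjugated_atoms()[c(1, 5)])
  manifest <- list(units = data.frame(unit = paste0("M", seq_len(n_units)),
                                      rmsd = 0, stringsAsFactors = FALSE))
  structure(list(model = model, map = map, manifest = manifest,
                 seed = as.integer(seed),
                 params = list(kind = "rod", n_units = n_units, n_res = n_res,
                               rise = rise,
                               include_chromophores = include_chromophores)),
            class = "synthetic_assembly")
}

check_proper_rotation <- function(R) {
  if (!all(dim(R) == c(3L, 3L))) stop("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    stop("transform is not a proper rotation (orthogonal, det = +1)")
  invisible(R)
}

#' Apply planted rigid perturbations to a synthetic assembly
#'
#' Each named unit's atoms are transformed by the given proper rigid motion
#' (`list(R = 3x3, t = length-3)`; either component may be omitted). The
#' manifest's `units` table records, for every unit, the exact C-alpha RMSD
#' that an anchored superposition on `anchor` must recover: with anchor
#' transform `Ta` and unit transform `Tu`, the planted RMSD is
#' `rms(Ta^{-1} Tu x - x)` over the unit's C-alpha coordinates (for a pure
#' translation `t` of a unit with untouched anchor this is exactly `|t|`).
#'
#' @param base A `synthetic_assembly` with unit-grouped chains (see
#'   [make_rod()]).
#' @param unit_transforms Named list: unit label -> `list(R =, t =)`.
#' @param anchor Unit label the ground-truth RMSDs are anchored on
#'   (default first unit).
#' @param seed Integer seed recorded in the manifest.
#' @return A perturbed `synthetic_assembly`; manifest `units` has columns
#'   `unit`, `rmsd` plus the planted transforms in `attr(, "transforms")`.
#' @export
perturb_assembly <- function(base, unit_transforms, anchor = NULL,
                             seed = base$seed) {
  uc <- unit_chain_table(base$map)
  units <- unique(uc$unit)
  if (is.null(anchor)) anchor <- units[1]
  unknown <- setdiff(names(unit_transforms), units)
  if (length(unknown))
    stop("unknown unit label(s): ", paste(unknown, collapse = ", "))

  norm_tf <- function(tf) {
    R <- if (is.null(tf$R)) diag(3) else check_proper_rotation(tf$R)
    t_vec <- if (is.null(tf$t)) c(0, 0, 0) else as.numeric(tf$t)
    list(R = R, t = t_vec)
  }
  tfs <- lapply(stats::setNames(units, units), function(u)
    norm_tf(if (u %in% names(unit_transforms)) unit_transforms[[u]]
            else list()))

  atoms <- base$model$atoms
  for (u in units) {
    tf <- tfs[[u]]
    sel <- atoms$chain %in% uc$chain[uc$unit == u]
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    xyz <- apply_rigid(xyz, tf$R, tf$t)
    atoms$x[sel] <- xyz[, 1]; atoms$y[sel] <- xyz[, 2]; atoms$z[sel] <- xyz[, 3]
  }
  model <- new_structure_model(paste0(base$model$identifier, "_perturbed"),
                               atoms, base$model$source_format)

  ta <- tfs[[anchor]]
  rmsd <- vapply(units, function(u) {
    sel <- base$model$atoms$chain %in% uc$chain[uc$unit == u] &
      base$model$atoms$elety == "CA" & !base$model$atoms$het
    x <- as.matrix(base$model$atoms[sel, c("x", "y", "z")])
    moved <- apply_rigid(x, tfs[[u]]$R, tfs[[u]]$t)
    # undo the anchor transform, as the anchored fit will
    back <- sweep(moved, 2, ta$t) %*% ta$R
    rmsd_between(back, x)
  }, numeric(1))

  units_df <- data.frame(unit = units, rmsd = as.numeric(rmsd),
                         stringsAsFactors = FALSE)
  attr(units_df, "transforms") <- tfs
  manifest <- base$manifest
  manifest$units <- units_df
  manifest$anchor <- anchor
  structure(list(model = model, map = base$map, manifest = manifest,
                 seed = as.integer(seed),
                 params = c(base$params, list(perturbed = TRUE,
                                              anchor = anchor))),
            class = "synthetic_assembly")
}

#' Draw one isotropic donor/acceptor orientation pair
#'
#' Two independent uniform-on-sphere unit dipole directions (normalised 3D
#' standard normals) and a fixed-length separation vector; the freely rotating
#' averaging scenario behind the 2/3 isotropic mean of kappa-squared.
#'
#' @param seed Integer seed; identical seeds give identical draws.
#' @param r_length Separation length in Angstrom.
#' @return List with `mu_d`, `mu_a` (unit 3-vectors) and `r_vec`.
#' @export
sample_isotropic_pair <- function(seed, r_length = 20) {
  withr::with_seed(as.integer(seed), {
    mu_d <- stats::rnorm(3); mu_a <- stats::rnorm(3)
    list(mu_d = mu_d / sqrt(sum(mu_d^2)),
         mu_a = mu_a / sqrt(sum(mu_a^2)),
         r_vec = c(0, 0, r_length))
  })
}

#' Write a synthetic assembly to disk as a fixture bundle
#'
#' Writes the structure (PDB and/or mmCIF), the assembly-map config, and the
#' manifest tables (chromophores, distances, units — whichever exist) as TSV.
#'
#' @param assembly A `synthetic_assembly`.
#' @param dir Output directory (created if needed).
#' @param name Basename for the files (default the model identifier).
#' @param formats Structure formats to write.
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(assembly, dir, name = NULL,
                          formats = c("pdb")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(name)) name <- assembly$model$identifier
  paths <- list()
  for (fmt in formats) {
    ext <- if (fmt == "pdb") "pdb" else "cif"
    p <- file.path(dir, paste0(name, ".", ext))
    write_structure(assembly$model, p, fmt)
    paths[[fmt]] <- p
  }
  paths$map <- file.path(dir, paste0(name, ".map.cfg"))
  write_assembly_map(assembly$map, paths$map)
  for (tab in intersect(names(assembly$manifest),
                        c("chromophores", "distances", "units"))) {
    p <- file.path(dir, paste0(name, ".", tab, ".tsv"))
    utils::write.table(assembly$manifest[[tab]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths[[tab]] <- p
  }
  paths$seed <- assembly$seed
  invisible(paths)
}
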