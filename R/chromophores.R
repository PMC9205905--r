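# Chromophore extraction, naming, transition-dipole assignment, and local
# protein environment. Naming follows the field convention
# <cylinder+trimer><subunit descriptor><attachment cysteine>, e.g. C1-a1-84 for
# the alpha-84 bilin of trimer 1 in the C cylinder, A3-aLCM-198 for the
# terminal-emitter bilin on the core-membrane linker.

subunit_descriptor <- function(role, subunit_number) {
  switch(role,
         ApcA = paste0("a", subunit_number),
         CpcA = paste0("a", subunit_number),
         ApcB = paste0("b", subunit_number),
         CpcB = paste0("b", subunit_number),
         ApcD = "aApcD",
         ApcE = "aLCM",
         ApcF = "bApcF",
         role)
}

subunit_type <- function(role) {
  if (role %in% c("ApcA", "ApcD", "ApcE", "CpcA")) "alpha"
  else if (role %in% c("ApcB", "ApcF", "CpcB")) "beta"
  else "linker"
}

render_chromophore_id <- function(cylinder, unit_index, descriptor,
                                  attach_residue) {
  paste(paste0(cylinder, unit_index), descriptor, attach_residue, sep = "-")
}

#' Extract bilin chromophores from a structure
#'
#' One chromophore per hetero residue whose 3-letter code is in the map's
#' ligand codes. The chromophore ID is built from the chain's assembly-map
#' assignment plus the author number of the covalently linked cysteine: the
#' nearest SG atom within 2.5 Angstrom of the ligand's attachment carbon (or of
#' any ligand atom when no attachment atom is configured). When no cysteine
#' qualifies, the ligand's own author number is used and the chromophore is
#' flagged (`attach_fallback`). Ligands on chains absent from the map are
#' skipped with a notice. Ligands with fewer than 4 of the configured
#' conjugated atoms are flagged `incomplete` with a warning and excluded from
#' pair analysis downstream.
#'
#' @param model A `structure_model`.
#' @param map An `assembly_map`.
#' @param assign_dipoles Assign transition dipoles during extraction
#'   (default `TRUE`; requires a non-degenerate conjugated system).
#' @return List of `chromophore` objects.
#' @export
extract_chromophores <- function(model, map, assign_dipoles = TRUE) {
  a <- model$atoms
  lig <- a[a$het & a$resid %in% map$ligand_codes, , drop = FALSE]
  if (nrow(lig) == 0L) return(list())

  sg <- a[!a$het & a$elety == "SG", , drop = FALSE]
  ca <- map$chain_assignments

  keys <- unique(paste(lig$chain, lig$resno, lig$insert, sep = "\r"))
  out <- list()
  for (k in keys) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    chain <- parts[1]; resno <- as.integer(parts[2])
    insert <- if (length(parts) >= 3L) parts[3] else ""
    rows <- lig[lig$chain == chain & lig$resno == resno & lig$insert == insert, ,
                drop = FALSE]
    asn <- ca[ca$chain == chain, , drop = FALSE]
    if (nrow(asn) == 0L) {
      message("ligand ", rows$resid[1], " ", resno, " on unmapped chain '",
              chain, "' ignored")
      next
    }

    conj <- rows[rows$elety %in% map$conjugated_atoms, , drop = FALSE]
    coords <- as.matrix(conj[, c("x", "y", "z")])
    rownames(coords) <- conj$elety
    incomplete <- nrow(coords) < 4L
    if (incomplete)
      warning(sprintf(
        "chromophore %s %d (chain %s) has %d of %d conjugated atoms; flagged incomplete and excluded from pair analysis",
        rows$resid[1], resno, chain, nrow(coords),
        length(map$conjugated_atoms)), call. = FALSE)

    # Covalent attachment: nearest polymer SG within 2.5 A.
    probe <- if (!is.null(map$attachment_atom) &&
                 map$attachment_atom %in% rows$elety)
      rows[rows$elety == map$attachment_atom, , drop = FALSE] else rows
    attach <- find_attachment(probe, sg)

    chrom <- structure(list(
      id = list(cylinder = asn$cylinder, unit_index = asn$unit_index,
                role = asn$role,
                subunit = subunit_type(asn$role),
                descriptor = subunit_descriptor(asn$role, asn$subunit_number),
                attach_residue = if (is.null(attach)) resno else attach$resno,
                tentative = identical(asn$role, "ApcD")),
      parent_chain = chain,
      resno = resno,
      ligand_code = rows$resid[1],
      conjugated_coords = coords,
      centroid = if (nrow(coords)) colMeans(coords) else c(NA, NA, NA),
      dipole = NULL,
      incomplete = incomplete,
      attach_fallback = is.null(attach)), class = "chromophore")
    chrom$id$rendered <- render_chromophore_id(
      chrom$id$cylinder, chrom$id$unit_index, chrom$id$descriptor,
      chrom$id$attach_residue)
    if (assign_dipoles && !incomplete)
      chrom$dipole <- assign_dipole(chrom, map)
    out[[length(out) + 1L]] <- chrom
  }
  out
}

find_attachment <- function(lig_rows, sg) {
  if (nrow(sg) == 0L || nrow(lig_rows) == 0L) return(NULL)
  lp <- as.matrix(lig_rows[, c("x", "y", "z")])
  sp <- as.matrix(sg[, c("x", "y", "z")])
  d2 <- outer(rowSums(lp^2), rowSums(sp^2), "+") - 2 * lp %*% t(sp)
  mind <- sqrt(pmax(apply(d2, 2, min), 0))
  j <- which.min(mind)
  if (mind[j] <= 2.5) list(resno = sg$resno[j], chain = sg$chain[j]) else NULL
}

#' @export
print.chromophore <- function(x, ...) {
  cat(sprintf("<chromophore> %s  chain %s  %s %d  centroid (%.2f, %.2f, %.2f)%s\n",
              x$id$rendered, x$parent_chain, x$ligand_code, x$resno,
              x$centroid[1], x$centroid[2], x$centroid[3],
              if (x$incomplete) "  [incomplete]" else ""))
  invisible(x)
}

#' Assign a transition-dipole direction to a chromophore
#'
#' Direction is the principal axis of the conjugated atoms (unit eigenvector
#' of the largest eigenvalue of their 3x3 covariance), sign-oriented so that
#' its projection onto the vector from the ring-A-side to the ring-D-side
#' sign-reference atom is positive. This is a declared geometric stand-in for
#' the long-axis pi-pi* transition dipole of the bilin; the atom set and sign
#' pair are configurable through the assembly map. Magnitude defaults to 1 so
#' couplings are relative.
#'
#' @param chrom A `chromophore`.
#' @param map An `assembly_map` (supplies the sign-reference atom pair).
#' @param magnitude Relative dipole magnitude (> 0).
#' @return List with unit `direction` (length-3) and `magnitude`.
#' @export
assign_dipole <- function(chrom, map, magnitude = 1.0) {
  coords <- chrom$conjugated_coords
  if (is.null(coords) || nrow(coords) < 2L)
    stop("dipole axis undefined: too few conjugated atoms for ",
         chrom$id$rendered)
  stopifnot(magnitude > 0)
  cv <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= 0 ||
      (eg$values[1] - eg$values[2]) / eg$values[1] < 1e-6)
    stop("dipole axis undefined: degenerate conjugated-atom covariance for ",
         chrom$id$rendered)
  dir <- eg$vectors[, 1]
  dir <- dir / sqrt(sum(dir^2))

  ref <- map$sign_reference
  have <- ref %in% rownames(coords)
  sref <- if (all(have)) coords[ref[2], ] - coords[ref[1], ]
          else coords[nrow(coords), ] - coords[1, ]
  if (sum(dir * sref) < 0) dir <- -dir
  list(direction = dir, magnitude = magnitude)
}

#' Protein environment of a chromophore
#'
#' All polymer residues with any atom within `cutoff` Angstrom of any
#' conjugated atom of the chromophore, sorted by ascending minimum distance.
#' The chromophore's own attachment cysteine is excluded unless
#' `include_attachment = TRUE`.
#'
#' @param chrom A `chromophore`.
#' @param model The parent `structure_model`.
#' @param cutoff Distance cutoff in Angstrom (> 0).
#' @param include_attachment Keep the covalently linked cysteine in the list.
#' @return data.frame with `residue` (e.g. `"Phe992/E"`), `chain`, `resno`,
#'   `resid`, `min_dist`.
#' @export
chromophore_environment <- function(chrom, model, cutoff,
                                    include_attachment = FALSE) {
  stopifnot(cutoff > 0)
  empty <- data.frame(residue = character(), chain = character(),
                      resno = integer(), resid = character(),
                      min_dist = numeric(), stringsAsFactors = FALSE)
  coords <- chrom$conjugated_coords
  if (is.null(coords) || nrow(coords) == 0L) return(empty)

  prot <- model$atoms[!model$atoms$het, , drop = FALSE]
  if (nrow(prot) == 0L) return(empty)
  # coarse box pre-filter before exact distances
  lo <- apply(coords, 2, min) - cutoff
  hi <- apply(coords, 2, max) + cutoff
  prot <- prot[prot$x >= lo[1] & prot$x <= hi[1] &
                 prot$y >= lo[2] & prot$y <= hi[2] &
                 prot$z >= lo[3] & prot$z <= hi[3], , drop = FALSE]
  if (nrow(prot) == 0L) return(empty)

  pp <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(pp^2), rowSums(coords^2), "+") - 2 * pp %*% t(coords)
  dmin_atom <- sqrt(pmax(apply(d2, 1, min), 0))

  key <- paste(prot$chain, prot$resno, prot$insert, sep = "\r")
  dmin <- tapply(dmin_atom, key, min)
  first <- !duplicated(key)
  res <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                    resid = prot$resid[first],
                    key = key[first], stringsAsFactors = FALSE)
  res$min_dist <- as.numeric(dmin[res$key])
  res$key <- NULL
  res <- res[res$min_dist <= cutoff, , drop = FALSE]

  if (!include_attachment && !chrom$attach_fallback)
    res <- res[!(res$resno == chrom$id$attach_residue &
                   toupper(res$resid) == "CYS"), , drop = FALSE]

  if (nrow(res) == 0L) return(empty)
  cap <- function(s) paste0(toupper(substr(s, 1, 1)), tolower(substr(s, 2, 3)))
  res$residue <- paste0(cap(res$resid), res$resno, "/", res$chain)
  res <- res[order(res$min_dist, res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("residue", "chain", "resno", "resid", "min_dist")]
}

#' Tabulate a chromophore set
#'
#' Manifest view: ID, chain, ligand code, centroid and dipole components,
#' plus the `incomplete`/`tentative`/`attach_fallback` flags.
#'
#' @param chroms List of `chromophore` objects.
#' @return data.frame, one row per chromophore.
#' @export
chromophore_table <- function(chroms) {
  if (length(chroms) == 0L)
    return(data.frame(id = character(), chain = character(),
                      ligand_code = character(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      dx = numeric(), dy = numeric(), dz = numeric(),
                      incomplete = logical(), tentative = logical(),
                      attach_fallback = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(chroms, function(ch) {
    d <- if (is.null(ch$dipole)) c(NA_real_, NA_real_, NA_real_)
         else ch$dipole$direction
    data.frame(id = ch$id$rendered, chain = ch$parent_chain,
               ligand_code = ch$ligand_code,
               cx = ch$centroid[1], cy = ch$centroid[2], cz = ch$centroid[3],
               dx = d[1], dy = d[2], dz = d[3],
               incomplete = ch$incomplete, tentative = ch$id$tentative,
               attach_fallback = ch$attach_fallback,
               stringsAsFactors = FALSE)
  }))
}

#' Locate the terminal-emitter chromophores of a set
#'
#' Terminal emitters are the chromophore on the core-membrane linker
#' (role ApcE, attachment cysteine 198) and the one on ApcD (attachment
#' cysteine 81). Used as default sinks of the transfer network.
#'
#' @param chroms List of `chromophore` objects.
#' @return Character vector of rendered IDs (possibly empty).
#' @export
find_terminal_emitters <- function(chroms) {
  hits <- vapply(chroms, function(ch)
    (ch$id$role == "ApcE" && ch$id$attach_residue == 198L) ||
      (ch$id$role == "ApcD" && ch$id$attach_residue == 81L), logical(1))
  vapply(chroms[hits], function(ch) ch$id$rendered, character(1))
}
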