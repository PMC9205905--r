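#' Read an atomic structure from PDB or mmCIF
#'
#' Parses a coordinate file into a `structure_model`: a flat atom table plus
#' identifier and source format. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken by the alphabetically first
#' alt-loc ID), waters are dropped, hydrogens are ignored, and author residue
#' numbering is kept untouched. Only the first model of a multi-model file is
#' used (a notice is emitted).
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format Optional format override, `"pdb"` or `"mmcif"`. When `NULL`
#'   the format is sniffed from the file extension, then from the content.
#' @param keep_waters Keep water residues (default `FALSE`).
#' @return A `structure_model` object: list with `identifier`, `source_format`
#'   and `atoms` (data.frame with columns `chain`, `resno`, `insert`, `resid`,
#'   `elety`, `elesy`, `x`, `y`, `z`, `occ`, `het`).
#' @export
read_structure <- function(path, format = NULL, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) format <- sniff_format(path)
  format <- match.arg(format, c("pdb", "mmcif"))

  pdb <- tryCatch(
    if (format == "mmcif")
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    else
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE)),
    error = function(e) {
      stop(sprintf("cannot parse '%s' as %s: %s", path, format,
                   conditionMessage(e)), call. = FALSE)
    })

  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms in '", path, "'")
  if (!is.null(pdb$xyz) && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    message("multi-model file; using the first model only")

  atoms <- data.frame(
    chain  = ifelse(is.na(a$chain), "_", as.character(a$chain)),
    resno  = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    resid  = as.character(a$resid),
    elety  = as.character(a$elety),
    elesy  = ifelse(is.na(a$elesy), "", as.character(a$elesy)),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    occ = ifelse(is.na(a$o), 1, as.numeric(a$o)),
    alt = ifelse(is.na(a$alt), "", as.character(a$alt)),
    het = as.character(a$type) == "HETATM",
    stringsAsFactors = FALSE)

  if (!keep_waters)
    atoms <- atoms[!atoms$resid %in% c("HOH", "WAT", "DOD", "H2O"), , drop = FALSE]
  atoms <- atoms[!atoms$elesy %in% c("H", "D"), , drop = FALSE]
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL

  if (nrow(atoms) == 0L) stop("no atoms in '", path, "'")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in '", path, "'")

  new_structure_model(
    identifier = sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path),
                     ignore.case = TRUE),
    atoms = atoms, source_format = format)
}

new_structure_model <- function(identifier, atoms, source_format) {
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms,
                 source_format = source_format),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s (%s): %d atoms, %d chains\n",
              x$identifier, x$source_format, nrow(x$atoms),
              length(model_chains(x))))
  invisible(x)
}

sniff_format <- function(path) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) return("mmcif")
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_|^loop_|^_atom_site", head_lines))) "mmcif" else "pdb"
}

# Keep, per (chain, resno, insert, elety), the conformer with the highest
# occupancy; ties go to the alphabetically first alt-loc ID.
resolve_altloc <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, atoms$alt)
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

#' Chain IDs present in a model
#' @param model A `structure_model`.
#' @return Character vector of chain IDs, in file order.
#' @export
model_chains <- function(model) unique(model$atoms$chain)

#' One-letter sequence of a chain's polymer residues
#'
#' @param model A `structure_model`.
#' @param chain Chain ID.
#' @return Character scalar; unknown residues become `"X"`.
#' @export
chain_sequence <- function(model, chain) {
  res <- polymer_residues(model, chain)
  if (nrow(res) == 0L) return("")
  paste(bio3d::aa321(res$resid), collapse = "")
}

# Polymer residues of a chain in author order: data.frame(resno, insert, resid).
polymer_residues <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain & !model$atoms$het, , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(resno = integer(), insert = character(),
                      resid = character(), stringsAsFactors = FALSE))
  key <- paste(a$resno, a$insert, sep = "\r")
  a <- a[!duplicated(key), c("resno", "insert", "resid"), drop = FALSE]
  rownames(a) <- NULL
  a
}

# C-alpha records of a chain: resno, insert, aa (one-letter), x, y, z.
chain_calpha <- function(model, chain) {
  a <- model$atoms[model$atoms$chain == chain & !model$atoms$het &
                     model$atoms$elety == "CA", , drop = FALSE]
  data.frame(resno = a$resno, insert = a$insert,
             aa = bio3d::aa321(a$resid),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

allowed_subunit_roles <- c("ApcA", "ApcB", "ApcC", "ApcD", "ApcE", "ApcF",
                           "CpcA", "CpcB", "CpcC", "CpcD", "CpcG")

#' Default conjugated-atom names for phycocyanobilin (CYC)
#'
#' The ring B/C tetrapyrrole atoms plus the methine bridge carbons along the
#' conjugation path. The list is a configurable default: the conjugated
#' pi-system carries the transition dipole, and shipping the atom list as
#' configuration keeps the dipole convention editable.
#'
#' @return Character vector of atom names.
#' @export
default_conjugated_atoms <- function() {
  c("NB", "C1B", "C2B", "C3B", "C4B", "CHB", "CHC",
    "NC", "C1C", "C2C", "C3C", "C4C", "CHD")
}

#' Construct an assembly map
#'
#' An assembly map ties file-level chain IDs to the domain nomenclature
#' (cylinder, unit index, subunit role), and carries the ligand and dipole
#' conventions used downstream: which 3-letter hetero codes are chromophores,
#' which atoms form the conjugated system, and which atom pair
#' (ring-A side -> ring-D side) orients the transition dipole sign.
#'
#' @param chains data.frame with columns `chain`, `cylinder`, `unit_index`,
#'   `role` and optionally `subunit_number`. When `subunit_number` is absent,
#'   chains sharing (cylinder, unit_index, role) are numbered 1..k in order.
#' @param ligand_codes Character vector of 3-letter ligand codes
#'   (default `"CYC"`, phycocyanobilin).
#' @param conjugated_atoms Ordered atom names of the conjugated system.
#' @param sign_reference Length-2 atom names orienting the dipole
#'   (ring-A-side atom, ring-D-side atom).
#' @param attachment_atom Optional ligand atom name carrying the thioether
#'   link; when `NULL`, the covalent cysteine is searched near all ligand atoms.
#' @return An `assembly_map` object.
#' @export
assembly_map <- function(chains,
                         ligand_codes = "CYC",
                         conjugated_atoms = default_conjugated_atoms(),
                         sign_reference = c("CHB", "CHD"),
                         attachment_atom = NULL) {
  stopifnot(is.data.frame(chains),
            all(c("chain", "cylinder", "unit_index", "role") %in% names(chains)))
  chains$chain <- as.character(chains$chain)
  chains$cylinder <- as.character(chains$cylinder)
  chains$unit_index <- as.integer(chains$unit_index)
  chains$role <- as.character(chains$role)

  dup <- chains$chain[duplicated(chains$chain)]
  if (length(dup))
    stop("duplicate chain assignment: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(chains$role, allowed_subunit_roles)
  if (length(bad))
    stop("unknown subunit role(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed_subunit_roles, collapse = ", "))
  if (length(ligand_codes) == 0L ||
      !all(grepl("^[A-Za-z0-9]{1,3}$", ligand_codes)))
    stop("ligand codes must be 1-3 alphanumeric characters")
  if (length(conjugated_atoms) == 0L) stop("conjugated_atoms must be non-empty")
  if (length(sign_reference) != 2L) stop("sign_reference must name two atoms")

  if (is.null(chains$subunit_number) || all(is.na(chains$subunit_number))) {
    grp <- paste(chains$cylinder, chains$unit_index, chains$role, sep = "\r")
    chains$subunit_number <- stats::ave(seq_len(nrow(chains)), grp,
                                        FUN = seq_along)
  }
  chains$subunit_number <- as.integer(chains$subunit_number)
  rownames(chains) <- NULL

  structure(list(chain_assignments = chains,
                 ligand_codes = toupper(ligand_codes),
                 conjugated_atoms = conjugated_atoms,
                 sign_reference = sign_reference,
                 attachment_atom = attachment_atom),
            class = "assembly_map")
}

#' @export
print.assembly_map <- function(x, ...) {
  cat(sprintf("<assembly_map> %d chains, ligands {%s}, %d conjugated atoms\n",
              nrow(x$chain_assignments), paste(x$ligand_codes, collapse = ","),
              length(x$conjugated_atoms)))
  invisible(x)
}

#' Load an assembly map from a plain-text config file
#'
#' The format is INI-like: a `[chains]` section with lines
#' `chain = cylinder:unit_index:role[:subunit_number]`, an optional
#' `[ligands]` section (`codes = CYC ...`, `attachment_atom = NAME`), and an
#' optional `[dipole]` section (`conjugated_atoms = ...`,
#' `sign_reference = A D`). Blank lines and `#` comments are ignored.
#'
#' @param path Config file path.
#' @return An `assembly_map`.
#' @export
load_assembly_map <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  section <- ""
  chains <- list()
  opts <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L)
      stop("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (section == "chains") {
      parts <- trimws(strsplit(val, ":", fixed = TRUE)[[1]])
      if (length(parts) < 3L)
        stop("chain assignment must be cylinder:unit_index:role — '", ln, "'")
      chains[[length(chains) + 1L]] <- data.frame(
        chain = key, cylinder = parts[1],
        unit_index = as.integer(parts[2]), role = parts[3],
        subunit_number = if (length(parts) >= 4L) as.integer(parts[4]) else NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      opts[[paste(section, key, sep = ".")]] <- val
    }
  }
  if (length(chains) == 0L) stop("config has no [chains] section entries")
  chains <- do.call(rbind, chains)
  if (all(is.na(chains$subunit_number))) chains$subunit_number <- NULL

  split_words <- function(x) strsplit(trimws(x), "[,[:space:]]+")[[1]]
  assembly_map(
    chains = chains,
    ligand_codes = if (!is.null(opts[["ligands.codes"]]))
      split_words(opts[["ligands.codes"]]) else "CYC",
    conjugated_atoms = if (!is.null(opts[["dipole.conjugated_atoms"]]))
      split_words(opts[["dipole.conjugated_atoms"]]) else default_conjugated_atoms(),
    sign_reference = if (!is.null(opts[["dipole.sign_reference"]]))
      split_words(opts[["dipole.sign_reference"]]) else c("CHB", "CHD"),
    attachment_atom = opts[["ligands.attachment_atom"]])
}

#' Write an assembly map config file
#' @param map An `assembly_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_map <- function(map, path) {
  ca <- map$chain_assignments
  lines <- c(
    "[chains]",
    sprintf("%s = %s:%d:%s:%d", ca$chain, ca$cylinder, ca$unit_index,
            ca$role, ca$subunit_number),
    "",
    "[ligands]",
    paste("codes =", paste(map$ligand_codes, collapse = " ")),
    if (!is.null(map$attachment_atom))
      paste("attachment_atom =", map$attachment_atom),
    "",
    "[dipole]",
    paste("conjugated_atoms =", paste(map$conjugated_atoms, collapse = " ")),
    paste("sign_reference =", paste(map$sign_reference, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a donor/acceptor pair table as TSV
#'
#' Fixed column order (`donor_id`, `acceptor_id`, `r_angstrom`, `cos_theta_T`,
#' `cos_theta_D`, `cos_theta_A`, `kappa_sq`, `v_rel`, `weight`), floats with 4
#' decimals, rows sorted by descending weight with ties broken by donor then
#' acceptor ID. An empty pair set writes the header only.
#'
#' @param pairs A pair table from [all_pairs()] (possibly zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c("donor_id", "acceptor_id", "r_angstrom", "cos_theta_T",
            "cos_theta_D", "cos_theta_A", "kappa_sq", "v_rel", "weight")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    ord <- order(-pairs$weight, pairs$donor_id, pairs$acceptor_id)
    p <- pairs[ord, , drop = FALSE]
    rows <- sprintf("%s\t%s\t%.4f\t%.4f\t%.4f\t%.4f\t%.4f\t%.4g\t%.4g",
                    p$donor_id, p$acceptor_id, p$r, p$cos_theta_T,
                    p$cos_theta_D, p$cos_theta_A, p$kappa_sq, p$v_rel,
                    p$weight)
    writeLines(rows, con)
  }
  invisible(path)
}

#' Write a structure model to PDB or mmCIF
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param format `"pdb"` (via bio3d) or `"mmcif"` (minimal `atom_site` loop).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(a$het, "HETATM", "ATOM"),
      resno = a$resno, resid = a$resid, chain = a$chain,
      insert = ifelse(nzchar(a$insert), a$insert, NA),
      eleno = seq_len(nrow(a)), elety = a$elety,
      o = a$occ, b = rep(0, nrow(a)), elesy = a$elesy)
  } else {
    # canonical RCSB atom_site column order (bio3d's reader relies on it)
    header <- c(
      paste0("data_", gsub("[^A-Za-z0-9_-]", "_", model$identifier)),
      "#", "loop_",
      paste0("_atom_site.",
             c("group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
               "auth_comp_id", "auth_asym_id", "auth_atom_id",
               "pdbx_PDB_model_num")))
    rows <- sprintf(
      "%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)),
      ifelse(nzchar(a$elesy), a$elesy, "C"), a$elety, a$resid, a$chain,
      a$resno, ifelse(nzchar(a$insert), a$insert, "?"),
      a$x, a$y, a$z, a$occ, 0, a$resno, a$resid, a$chain, a$elety)
    writeLines(c(header, rows, "#"), path)
  }
  invisible(path)
}
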