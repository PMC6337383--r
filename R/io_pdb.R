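# PDB coordinate reader/writer. ATOM records form the protein; HETATM records
# (excluding waters) form the ligand. MODEL/ENDMDL blocks are returned as
# trajectory frames; binary trajectory formats are out of scope (convert to
# multi-model PDB upstream).

parse_pdb_atoms <- function(lines, lineno) {
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stopf("PDB line %d: missing or unparseable coordinates", lineno[bad[1]])
  el <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  # fall back to the atom-name convention when the element column is blank
  guess <- sub("^[0-9]*", "", name)
  guess <- ifelse(substr(guess, 1, 2) %in% c("CL", "BR"),
                  substr(guess, 1, 2), substr(guess, 1, 1))
  el <- ifelse(nzchar(el), el, guess)
  chg_raw <- trimws(substr(lines, 79, 80))
  fc <- integer(length(lines))
  has_chg <- grepl("^[0-9][+-]$", chg_raw)
  fc[has_chg] <- as.integer(substr(chg_raw[has_chg], 1, 1)) *
    ifelse(substr(chg_raw[has_chg], 2, 2) == "-", -1L, 1L)
  data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = suppressWarnings(as.integer(substr(lines, 7, 11))),
    atom_name = name,
    resname = trimws(substr(lines, 18, 20)),
    chain = trimws(substr(lines, 22, 22)),
    resno = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    x = x, y = y, z = z,
    element = normalize_element(el),
    formal_charge = fc)
}

ligand_from_het <- function(het) {
  at <- het[, c("element", "x", "y", "z", "formal_charge")]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- cross_dist(xyz, xyz)
  cut <- matrix(1.85, nrow(at), nrow(at))
  ish <- at$element == "H"
  cut[ish, ] <- 1.25; cut[, ish] <- 1.25
  pairs <- which(d > 0.1 & d <= cut & upper.tri(d), arr.ind = TRUE)
  bonds <- if (nrow(pairs))
    data.frame(a1 = pairs[, 1], a2 = pairs[, 2], order = 1L) else NULL
  molecule(het$resname[1] %||% "LIG", at, bonds)
}

split_structure <- function(atoms) {
  is_water <- atoms$resname %in% c("HOH", "WAT", "SOL")
  is_het <- atoms$record == "HETATM" & !is_water
  prot <- protein_structure(atoms[!is_het, , drop = FALSE])
  lig <- if (any(is_het)) ligand_from_het(atoms[is_het, , drop = FALSE]) else NULL
  list(protein = prot, ligand = lig)
}

#' Read a PDB file
#'
#' Single-model files yield a `ProteinStructure` (any non-water HETATM ligand
#' is attached as attribute `"ligand"`). Multi-model files yield a list of
#' `TrajectoryFrame`, one per MODEL; when the file carries no time annotation
#' frames are stamped 0, `dt`, 2`dt`, ... ps (`dt = 2` ps, the customary MD
#' save interval).
#'
#' @param path PDB file path.
#' @param dt frame spacing in ps used when the file has no time annotation.
#' @return `ProteinStructure` or list of `TrajectoryFrame`.
#' @export
read_pdb <- function(path, dt = 2) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM", "ATOM", "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) <= 1L) {
    idx <- which(is_atom)
    if (!length(idx)) stopf("PDB file '%s': no coordinate records", path)
    atoms <- parse_pdb_atoms(lines[idx], idx)
    parts <- split_structure(atoms)
    out <- parts$protein
    attr(out, "ligand") <- parts$ligand
    return(out)
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    stopf("PDB file '%s': unbalanced MODEL/ENDMDL", path)
  frames <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    span <- model_starts[m]:model_ends[m]
    idx <- span[is_atom[span]]
    atoms <- parse_pdb_atoms(lines[idx], idx)
    parts <- split_structure(atoms)
    tm <- (m - 1) * dt
    rem <- grep("^REMARK +TIME", lines[span], value = TRUE)
    if (length(rem)) {
      tv <- suppressWarnings(as.numeric(sub("^REMARK +TIME +", "", rem[1])))
      if (!is.na(tv)) tm <- tv
    }
    frames[[m]] <- trajectory_frame(tm, parts$protein, parts$ligand)
  }
  frames
}

format_pdb_atoms <- function(atoms, start_serial = 1L) {
  n <- nrow(atoms)
  record <- if (is.null(atoms$record)) rep("ATOM", n) else atoms$record
  nm <- atoms$atom_name
  nm4 <- ifelse(nchar(nm) >= 4, substr(nm, 1, 4), sprintf(" %-3s", nm))
  sprintf("%-6s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, start_serial + seq_len(n) - 1L, nm4, atoms$resname,
          ifelse(atoms$chain == "", "A", atoms$chain), atoms$resno,
          ifelse(is.null(atoms$icode), "", atoms$icode),
          atoms$x, atoms$y, atoms$z, 1, 0, toupper(atoms$element))
}

frame_pdb_lines <- function(protein, ligand = NULL) {
  out <- format_pdb_atoms(protein$atoms)
  if (!is.null(ligand)) {
    la <- ligand$atoms
    het <- data.frame(record = "HETATM", atom_name = paste0(la$element,
                                                            seq_len(nrow(la))),
                      resname = "LIG", chain = "L", resno = 1L, icode = "",
                      x = la$x, y = la$y, z = la$z, element = la$element)
    out <- c(out, format_pdb_atoms(het, start_serial = nrow(protein$atoms) + 1L))
  }
  out
}

#' Write a protein structure or trajectory to PDB
#'
#' @param x `ProteinStructure` or list of `TrajectoryFrame`.
#' @param path output path.
#' @param ligand optional `Molecule`/`LigandPose` written as HETATM records.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, ligand = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "ProteinStructure")) {
    lig <- ligand %||% attr(x, "ligand")
    if (inherits(lig, "LigandPose")) lig <- lig$molecule
    writeLines(c(frame_pdb_lines(x, lig), "END"), con)
  } else {
    for (m in seq_along(x)) {
      fr <- x[[m]]
      lig <- fr$ligand
      if (inherits(lig, "LigandPose")) lig <- lig$molecule
      writeLines(sprintf("MODEL     %4d", m), con)
      writeLines(sprintf("REMARK  TIME %.3f", fr$time), con)
      writeLines(frame_pdb_lines(fr$protein, lig), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}
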