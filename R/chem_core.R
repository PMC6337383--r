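#' @title Core chemistry containers
#'
#' @description
#' Lightweight S3 containers for ligands, docked poses, protein structures and
#' trajectory frames. Coordinates are Angstrom everywhere, energies kcal/mol,
#' time ps. Atom indices are 1-based. Residue numbering is preserved verbatim
#' from the source PDB so reports read like "F252" or "S66".
#'
#' @name chem_core
NULL

HALOGENS <- c("F", "Cl", "Br", "I")
SUPPORTED_ELEMENTS <- c("H", "C", "N", "O", "S", "P", HALOGENS)
FEATURE_KINDS <- c("H", "HBD", "HBA", "AR", "PI", "NI")

normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

#' Construct a Molecule
#'
#' @param name molecule identifier (conformers of one molecule share a name).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and optionally
#'   `formal_charge` (integer e, default 0) and `aromatic` (logical).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2, 3; 4 denotes aromatic) and optionally `aromatic` (logical).
#' @param properties named list of string properties (e.g. pIC50, LogP).
#' @return object of class `Molecule`.
#' @export
molecule <- function(name, atoms, bonds = NULL, properties = list()) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- normalize_element(atoms$element)
  bad <- setdiff(unique(atoms$element), SUPPORTED_ELEMENTS)
  if (length(bad)) stopf("unsupported element(s): %s", paste(bad, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("molecule '%s': non-finite coordinates", name)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(bonds)) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical())
  } else {
    bonds <- as.data.frame(bonds)
    bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
    bonds$order <- as.integer(bonds$order)
    if (is.null(bonds$aromatic)) bonds$aromatic <- bonds$order == 4L
    n <- nrow(atoms)
    if (nrow(bonds) && (any(bonds$a1 < 1 | bonds$a1 > n | bonds$a2 < 1 | bonds$a2 > n)))
      stopf("molecule '%s': bond endpoint out of range", name)
  }
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 properties = properties),
            class = "Molecule")
}

#' Heavy-atom count of a molecule
#'
#' The number of non-hydrogen atoms (HAC).
#' @param mol a `Molecule`.
#' @return integer HAC.
#' @export
hac <- function(mol) sum(mol$atoms$element != "H")

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule %s: %d atoms (%d heavy), %d bonds, %d properties>\n",
              x$name, nrow(x$atoms), hac(x), nrow(x$bonds),
              length(x$properties)))
  invisible(x)
}

#' Coordinate matrix of a molecule
#' @param mol a `Molecule`.
#' @return n x 3 numeric matrix (A).
#' @export
coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

heavy_idx <- function(mol) which(mol$atoms$element != "H")

# adjacency list over all atoms (list of integer vectors)
adjacency <- function(mol) {
  adj <- vector("list", nrow(mol$atoms))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Hydrophobic atom typing
#'
#' An atom is hydrophobic when it is S, Cl, Br or I, or a carbon whose bonded
#' neighbours are exclusively carbon, hydrogen, sulfur or halogen. This treats
#' aryl chlorines as hydrophobic-feature carriers, consistent with their role
#' in halogenated inhibitor series.
#'
#' @param mol a `Molecule`.
#' @return logical vector over atoms.
#' @export
hydrophobic_atoms <- function(mol) {
  el <- mol$atoms$element
  adj <- adjacency(mol)
  apolar <- c("C", "H", "S", HALOGENS)
  out <- el %in% c("S", "Cl", "Br", "I")
  for (i in which(el == "C")) {
    nb <- adj[[i]]
    out[i] <- length(nb) == 0L || all(el[nb] %in% apolar)
  }
  out
}

#' Hydrogen-bond donor / acceptor / halogen role flags
#'
#' Donors are N or O heavy atoms carrying at least one explicit hydrogen; when
#' the molecule has no explicit hydrogens at all, any nitrogen with
#' non-negative formal charge is assumed protonated (amines at physiological
#' pH). Acceptors are all oxygens plus nitrogens with formal charge <= 0 and
#' at most two heavy neighbours. Halogen-bond donors are C-bound Cl/Br/I.
#'
#' @param mol a `Molecule`.
#' @return data.frame with logical columns `donor`, `acceptor`, `halogen`.
#' @export
atom_roles <- function(mol) {
  el <- mol$atoms$element
  fc <- mol$atoms$formal_charge
  adj <- adjacency(mol)
  has_h <- any(el == "H")
  n <- length(el)
  donor <- acceptor <- halogen <- logical(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    nb_el <- el[nb]
    heavy_deg <- sum(nb_el != "H")
    if (el[i] %in% c("N", "O")) {
      donor[i] <- if (has_h) any(nb_el == "H") else (el[i] == "N" && fc[i] >= 0)
      acceptor[i] <- if (el[i] == "O") TRUE else (fc[i] <= 0 && heavy_deg <= 2L)
    }
    if (el[i] %in% c("Cl", "Br", "I")) halogen[i] <- any(nb_el == "C")
  }
  data.frame(donor = donor, acceptor = acceptor, halogen = halogen)
}

#' Construct a docked ligand pose
#'
#' @param ligand_id ligand identifier shared by all poses of one ligand.
#' @param pose_id unique pose identifier within the ensemble.
#' @param mol `Molecule` holding the single docked conformation.
#' @param scaffold_map ordered integer vector of heavy-atom indices defining
#'   the common core; the ordering establishes atom correspondence between
#'   poses of different ligands.
#' @param scores named numeric vector of engine scores.
#' @return object of class `LigandPose`.
#' @export
ligand_pose <- function(ligand_id, pose_id, mol, scaffold_map,
                        scores = numeric()) {
  scaffold_map <- as.integer(scaffold_map)
  if (anyDuplicated(scaffold_map)) stopf("scaffold_map has duplicate indices")
  if (any(scaffold_map < 1L | scaffold_map > nrow(mol$atoms)))
    stopf("scaffold_map index out of range")
  if (any(mol$atoms$element[scaffold_map] == "H"))
    stopf("scaffold_map must reference heavy atoms")
  structure(list(ligand_id = ligand_id, pose_id = pose_id, molecule = mol,
                 scaffold_map = scaffold_map, scores = scores),
            class = "LigandPose")
}

#' @export
print.LigandPose <- function(x, ...) {
  cat(sprintf("<LigandPose %s/%s: %d scaffold atoms>\n",
              x$ligand_id, x$pose_id, length(x$scaffold_map)))
  invisible(x)
}

scaffold_coords <- function(pose) coords(pose$molecule)[pose$scaffold_map, , drop = FALSE]

#' Construct a protein structure
#'
#' @param atoms data.frame with columns `atom_name`, `resname`, `chain`,
#'   `resno`, `icode`, `element`, `x`, `y`, `z` (one row per atom, residues
#'   contiguous and ordered as in the source file).
#' @return object of class `ProteinStructure`.
#' @export
protein_structure <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("atom_name", "resname", "chain", "resno", "element", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$element <- normalize_element(atoms$element)
  structure(list(atoms = atoms), class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat(sprintf("<ProteinStructure: %d atoms, %d residues>\n",
              nrow(x$atoms), length(unique(residue_key(x)))))
  invisible(x)
}

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

#' Residue labels in one-letter + number convention
#'
#' Residue 252 of PHE renders as "F252" (the convention used in structure-based
#' reports). Unknown residue names keep their three-letter code. When several
#' chains are present the chain id is prefixed ("B:F252").
#'
#' @param protein a `ProteinStructure`.
#' @return character vector, one label per atom row.
#' @export
residue_key <- function(protein) {
  at <- protein$atoms
  one <- unname(AA1[at$resname])
  one[is.na(one)] <- at$resname[is.na(one)]
  key <- paste0(one, at$resno, ifelse(at$icode == "", "", at$icode))
  if (length(unique(at$chain[at$chain != ""])) > 1L)
    key <- paste0(at$chain, ":", key)
  key
}

#' Unique residue labels of a structure
#' @param protein a `ProteinStructure`.
#' @return character vector in structure order.
#' @export
residue_ids <- function(protein) unique(residue_key(protein))

protein_coords <- function(protein) as.matrix(protein$atoms[, c("x", "y", "z")])

protein_heavy <- function(protein) which(protein$atoms$element != "H")

#' Protein hydrophobic-atom flags
#'
#' PDB files carry no bond table, so intra-residue bonds are inferred from
#' covalent distance (heavy-heavy <= 1.85 A) and the ligand hydrophobic rule
#' is applied: C with only C/H/S/halogen neighbours, plus S and heavy halogens.
#'
#' @param protein a `ProteinStructure`.
#' @return logical vector over atom rows.
#' @export
protein_hydrophobic <- function(protein) {
  at <- protein$atoms
  out <- logical(nrow(at))
  key <- paste(at$chain, at$resno, at$icode)
  apolar <- c("C", "H", "S", HALOGENS)
  for (res in split(seq_len(nrow(at)), key)) {
    el <- at$element[res]
    xyz <- as.matrix(at[res, c("x", "y", "z")])
    d <- cross_dist(xyz, xyz)
    for (k in seq_along(res)) {
      if (el[k] %in% c("S", "Cl", "Br", "I")) { out[res[k]] <- TRUE; next }
      if (el[k] != "C") next
      nb <- which(d[k, ] <= 1.85 & seq_along(res) != k)
      out[res[k]] <- all(el[nb] %in% apolar)
    }
  }
  out
}

#' Protein H-bond role flags
#'
#' Donors: backbone/side-chain nitrogens plus hydroxyl oxygens (OG, OG1, OH,
#' and water O). Acceptors: all oxygens. Explicit hydrogens are not required
#' (detection falls back to the distance-only rule).
#' @param protein a `ProteinStructure`.
#' @return data.frame with logical columns `donor`, `acceptor`.
#' @export
protein_roles <- function(protein) {
  at <- protein$atoms
  donor <- at$element == "N" |
    (at$element == "O" & at$atom_name %in% c("OG", "OG1", "OH", "OW"))
  acceptor <- at$element == "O"
  data.frame(donor = donor, acceptor = acceptor)
}

#' Construct a trajectory frame
#'
#' @param time time stamp in ps.
#' @param protein `ProteinStructure` snapshot.
#' @param ligand `LigandPose` (or bare `Molecule`, wrapped as a pose).
#' @return object of class `TrajectoryFrame`.
#' @export
trajectory_frame <- function(time, protein, ligand = NULL) {
  if (inherits(ligand, "Molecule"))
    ligand <- ligand_pose(ligand$name, ligand$name, ligand,
                          heavy_idx(ligand))
  structure(list(time = time, protein = protein, ligand = ligand),
            class = "TrajectoryFrame")
}
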