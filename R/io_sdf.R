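# SDF (MDL V2000) reader/writer. Only the fields the pipeline touches are
# modelled: coordinates, elements, bond orders (4 = aromatic), M CHG charge
# lines and the data-item property block.

#' Read a (multi-record) V2000 SDF file
#'
#' Multi-conformer input is conventional: repeated molecule names denote
#' conformers of one molecule (see [group_conformers()]).
#'
#' @param path SDF file path.
#' @return list of `Molecule`.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split into records on "$$$$"
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mols <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    rec <- rec[cumsum(trimws(rec) == "$$$$") == 0L]
    if (length(rec) < 4L) stopf("SDF record %d: truncated header", r)
    name <- trimws(rec[1])
    counts <- rec[4]
    natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(natoms) || is.na(nbonds))
      stopf("SDF record %d: malformed counts line '%s'", r, counts)
    if (length(rec) < 4L + natoms + nbonds)
      stopf("SDF record %d: fewer atom/bond lines than counts line declares", r)
    at_lines <- rec[4L + seq_len(natoms)]
    x <- as.numeric(substr(at_lines, 1, 10))
    y <- as.numeric(substr(at_lines, 11, 20))
    z <- as.numeric(substr(at_lines, 21, 30))
    el <- trimws(substr(at_lines, 32, 34))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stopf("SDF record %d: unparseable atom coordinates", r)
    bonds <- NULL
    if (nbonds > 0L) {
      bd_lines <- rec[4L + natoms + seq_len(nbonds)]
      bonds <- data.frame(
        a1 = as.integer(substr(bd_lines, 1, 3)),
        a2 = as.integer(substr(bd_lines, 4, 6)),
        order = as.integer(substr(bd_lines, 7, 9)))
      bonds$aromatic <- bonds$order == 4L
    }
    fc <- integer(natoms)
    chg_lines <- grep("^M  CHG", rec, value = TRUE)
    for (cl in chg_lines) {
      toks <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
      nn <- toks[1]
      for (k in seq_len(nn)) fc[toks[2 * k]] <- toks[2 * k + 1]
    }
    atoms <- data.frame(element = el, x = x, y = y, z = z, formal_charge = fc)
    props <- list()
    pi <- grep("^>", rec)
    for (p in pi) {
      pname <- sub(".*<([^>]+)>.*", "\\1", rec[p])
      val <- character()
      q <- p + 1L
      while (q <= length(rec) && nzchar(trimws(rec[q])) &&
             !startsWith(rec[q], ">")) {
        val <- c(val, rec[q]); q <- q + 1L
      }
      props[[pname]] <- paste(val, collapse = "\n")
    }
    mol <- molecule(name, atoms, bonds, props)
    # mark endpoints of aromatic bonds
    if (nrow(mol$bonds) && any(mol$bonds$aromatic)) {
      ar <- unique(c(mol$bonds$a1[mol$bonds$aromatic],
                     mol$bonds$a2[mol$bonds$aromatic]))
      mol$atoms$aromatic[ar] <- TRUE
    }
    mols[[r]] <- mol
  }
  mols
}

#' Write molecules to a V2000 SDF file
#'
#' @param mols a `Molecule` or list of `Molecule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "Molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    at <- mol$atoms; bd <- mol$bonds
    writeLines(c(mol$name, "  dynophoreR", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(at), nrow(bd)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z, at$element), con)
    if (nrow(bd))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", bd$a1, bd$a2, bd$order), con)
    chg <- which(at$formal_charge != 0L)
    if (length(chg)) {
      # M CHG lines carry at most 8 atom/charge pairs
      for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp,
                                         at$formal_charge[grp]),
                                 collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    for (pname in names(mol$properties)) {
      writeLines(c(sprintf(">  <%s>", pname),
                   as.character(mol$properties[[pname]]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Group a molecule list into conformer sets by shared name
#'
#' @param mols list of `Molecule` (e.g. from [read_sdf()]).
#' @return named list; each element is the list of conformers of one molecule.
#' @export
group_conformers <- function(mols) {
  nm <- vapply(mols, function(m) m$name, "")
  split(mols, factor(nm, levels = unique(nm)))
}
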