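#' @title Multi-model nucleic-acid structure I/O
#' @description
#' NMR-style coordinate ensembles (multi-MODEL PDB or mmCIF) are read into a
#' uniform `StructureEnsemble`: a shared atom topology table plus one n x 3
#' coordinate matrix per model. Supported residue types are DA, DC, DG, DT
#' and DI (2'-deoxyinosine, hypoxanthine base). Hydrogens are retained.
#' @name structio
NULL

.SUPPORTED_RESTYPES <- c("DA", "DC", "DG", "DT", "DI")

.PURINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
.PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

.ring_atoms_for <- function(restype) {
  if (restype %in% c("DA", "DG", "DI")) .PURINE_RING else .PYRIMIDINE_RING
}

.element_from_name <- function(atom) {
  e <- sub("^([0-9]*)([A-Za-z]).*$", "\\2", atom)
  toupper(e)
}

#' Construct a StructureEnsemble
#'
#' @param atoms data.frame with columns chain, resno, restype, atom, element
#' @param coords list of n_atoms x 3 numeric matrices (one per model)
#' @param source provenance string
#' @param format source format label
#' @param validate run topology validation
#' @return object of class `StructureEnsemble`
#' @export
structure_ensemble <- function(atoms, coords, source = "in-memory",
                               format = "memory", validate = TRUE) {
  stopifnot(is.data.frame(atoms), is.list(coords), length(coords) >= 1)
  atoms$element <- atoms$element %||% .element_from_name(atoms$atom)
  ens <- structure(list(atoms = atoms, coords = coords,
                        source = source, format = format),
                   class = "StructureEnsemble")
  if (validate) validate_ensemble(ens)
  ens
}

#' Validate ensemble topology
#'
#' Checks: finite coordinates in every model, consistent atom counts,
#' supported residue types, and the full base ring atom set for every
#' nucleotide residue.
#' @param ens StructureEnsemble
#' @return invisibly TRUE; structured error otherwise
#' @export
validate_ensemble <- function(ens) {
  at <- ens$atoms
  n <- nrow(at)
  if (n == 0) stop("empty ensemble: no atoms")
  for (m in seq_along(ens$coords)) {
    xyz <- ens$coords[[m]]
    if (!is.matrix(xyz) || nrow(xyz) != n || ncol(xyz) != 3)
      stop(sprintf("model %d: coordinate matrix does not match topology (%d atoms)",
                   m, n))
    if (!all(is.finite(xyz)))
      stop(sprintf("model %d: non-finite coordinates", m))
  }
  bad <- setdiff(unique(at$restype), .SUPPORTED_RESTYPES)
  if (length(bad))
    stop("unsupported residue type(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(.SUPPORTED_RESTYPES, collapse = ", "), ")")
  key <- paste(at$chain, at$resno)
  for (k in unique(key)) {
    sel <- key == k
    rt <- at$restype[sel][1]
    missing <- setdiff(.ring_atoms_for(rt), at$atom[sel])
    if (length(missing))
      stop(sprintf("residue %s %s (chain %s, resno %s): missing base ring atom(s) %s",
                   rt, k, at$chain[sel][1], at$resno[sel][1],
                   paste(missing, collapse = ",")))
  }
  invisible(TRUE)
}

#' Number of models in an ensemble
#' @param ens StructureEnsemble
#' @export
n_models <- function(ens) length(ens$coords)

#' Extract one model as a flat atom table
#'
#' @param ens StructureEnsemble
#' @param i model index (1-based)
#' @return data.frame chain, resno, restype, atom, element, x, y, z
#' @export
get_model <- function(ens, i = 1) {
  stopifnot(i >= 1, i <= n_models(ens))
  df <- ens$atoms
  xyz <- ens$coords[[i]]
  df$x <- xyz[, 1]; df$y <- xyz[, 2]; df$z <- xyz[, 3]
  df
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  key <- paste(x$atoms$chain, x$atoms$resno)
  cat(sprintf("StructureEnsemble: %d model(s), %d chain(s), %d residue(s), %d atoms\n",
              n_models(x), length(unique(x$atoms$chain)),
              length(unique(key)), nrow(x$atoms)))
  cat("  source:", x$source, sprintf("(%s)\n", x$format))
  invisible(x)
}

# resolve altlocs to highest occupancy, then first listed
.resolve_altloc <- function(atom_df) {
  if (!"alt" %in% names(atom_df)) return(atom_df)
  alt <- atom_df$alt
  alt[is.na(alt)] <- ""
  if (all(alt %in% c("", "A"))) return(atom_df[alt %in% c("", "A"), , drop = FALSE])
  key <- paste(atom_df$chain, atom_df$resno, atom_df$elety)
  keep <- unlist(lapply(split(seq_len(nrow(atom_df)), key), function(ix) {
    if (length(ix) == 1) return(ix)
    occ <- atom_df$o[ix]
    occ[is.na(occ)] <- 1
    ix[which.max(occ)]
  }))
  atom_df[sort(keep), , drop = FALSE]
}

.read_pdb_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  at <- .resolve_altloc(at)
  sel <- which(paste(pdb$atom$chain, pdb$atom$resno, pdb$atom$elety) %in%
                 paste(at$chain, at$resno, at$elety))
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- .element_from_name(at$elety)
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      restype = trimws(at$resid), atom = trimws(at$elety),
                      element = trimws(elem), stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- lapply(seq_len(nrow(xyz)), function(m) {
    matrix(xyz[m, ], ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
  })
  list(atoms = atoms, coords = coords)
}

# minimal mmCIF atom_site reader (multi-model via pdbx_PDB_model_num);
# written here because no installed R package parses multi-model mmCIF
.read_cif_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  li <- grep("^_atom_site\\.", lines)
  if (!length(li)) stop("no _atom_site loop found in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[li]))
  start <- max(li) + 1
  rows <- list()
  for (i in start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") ||
        startsWith(ln, "_")) break
    rows[[length(rows) + 1L]] <- strsplit(ln, "\\s+")[[1]]
  }
  m <- do.call(rbind, rows)
  colnames(m) <- fields[seq_len(ncol(m))]
  getf <- function(nm, alt = NULL) {
    if (nm %in% colnames(m)) return(m[, nm])
    if (!is.null(alt) && alt %in% colnames(m)) return(m[, alt])
    rep(NA_character_, nrow(m))
  }
  atom <- gsub('"', "", getf("label_atom_id", "auth_atom_id"))
  df <- data.frame(
    chain = getf("auth_asym_id", "label_asym_id"),
    resno = as.integer(getf("auth_seq_id", "label_seq_id")),
    restype = getf("label_comp_id", "auth_comp_id"),
    atom = atom,
    element = getf("type_symbol"),
    model = as.integer(getf("pdbx_PDB_model_num")),
    x = as.numeric(getf("Cartn_x")), y = as.numeric(getf("Cartn_y")),
    z = as.numeric(getf("Cartn_z")), stringsAsFactors = FALSE)
  if (all(is.na(df$model))) df$model <- 1L
  models <- sort(unique(df$model))
  ref <- df[df$model == models[1], ]
  atoms <- ref[, c("chain", "resno", "restype", "atom", "element")]
  coords <- lapply(models, function(mm) {
    sub <- df[df$model == mm, ]
    if (nrow(sub) != nrow(ref))
      stop(sprintf("model %d: %d atoms, expected %d (inconsistent topology)",
                   mm, nrow(sub), nrow(ref)))
    as.matrix(sub[, c("x", "y", "z")])
  })
  list(atoms = atoms, coords = coords)
}

#' Read a coordinate ensemble (PDB or mmCIF)
#'
#' All MODEL blocks are retained; hydrogens are kept; altlocs are resolved
#' to the highest-occupancy conformer. HETATM nucleotides are accepted.
#'
#' @param path input file
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`
#' @return StructureEnsemble
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- if (format == "pdb") .read_pdb_ensemble(path) else .read_cif_ensemble(path)
  structure_ensemble(parsed$atoms, parsed$coords, source = path, format = format)
}

.fmt_pdb_atom <- function(i, atom, restype, chain, resno, xyz, element) {
  name <- if (nchar(atom) < 4) sprintf(" %-3s", atom) else sprintf("%-4s", atom)
  sprintf("ATOM  %5d %s %-3s%2s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          i %% 100000, name, restype, substr(chain, 1, 1), resno,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

.write_pdb_ensemble <- function(ens, path) {
  at <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models(ens))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- ens$coords[[m]]
    lines <- vapply(seq_len(nrow(at)), function(i) {
      .fmt_pdb_atom(i, at$atom[i], at$restype[i], at$chain[i], at$resno[i],
                    xyz[i, ], at$element[i])
    }, character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.write_cif_ensemble <- function(ens, path) {
  at <- ens$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_tetrahelix", "loop_",
               "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
               "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.pdbx_PDB_model_num"), con)
  k <- 0
  for (m in seq_len(n_models(ens))) {
    xyz <- ens$coords[[m]]
    lines <- vapply(seq_len(nrow(at)), function(i) {
      aname <- if (grepl("'", at$atom[i])) sprintf('"%s"', at$atom[i]) else at$atom[i]
      sprintf("ATOM %d %s %s %s %s %d %.3f %.3f %.3f %d",
              k + i, at$element[i], aname, at$restype[i], at$chain[i],
              at$resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], m)
    }, character(1))
    writeLines(lines, con)
    k <- k + nrow(at)
  }
  writeLines("#", con)
}

#' Write a coordinate ensemble
#'
#' The emitted file re-parses (via [read_structure()]) to an equal ensemble
#' with coordinates preserved to 3 decimals. PDB output falls back to mmCIF
#' chain naming only through the cif format; chains longer than one
#' character require `format = "cif"`.
#'
#' @param ens StructureEnsemble
#' @param path output file
#' @param format `"pdb"` or `"cif"`
#' @export
write_structure <- function(ens, path, format = c("pdb", "cif")) {
  format <- match.arg(format)
  validate_ensemble(ens)
  if (format == "pdb" && any(nchar(ens$atoms$chain) > 1))
    stop("chain ids longer than 1 character cannot be encoded in PDB; use format='cif'")
  if (format == "pdb") .write_pdb_ensemble(ens, path) else .write_cif_ensemble(ens, path)
  invisible(path)
}

# split a model table into residues, ordered by (chain, resno)
.split_residues <- function(model) {
  key <- paste(model$chain, model$resno, sep = ":")
  res <- split(model, factor(key, levels = unique(key)))
  ord <- order(vapply(res, function(r) r$chain[1], character(1)),
               vapply(res, function(r) r$resno[1], numeric(1)))
  res[ord]
}

.res_atom <- function(res_df, atom) {
  i <- match(atom, res_df$atom)
  if (is.na(i)) return(NULL)
  as.numeric(res_df[i, c("x", "y", "z")])
}
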