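#' @title NOE-derived distance restraints and companion restraints
#' @description
#' NOE cross-peak volumes are calibrated against intra-nucleotide H8-H1'
#' correlations of residues in clear anti orientation, whose averaged
#' volume is referenced to 3.9 Angstrom. Distances are then estimated by
#' the isolated-spin-pair inverse-sixth-power relation
#' `r = 3.9 * (V_ref / V)^(1/6)` and binned into the four standard classes
#' strong (1.8-3.6), medium (2.6-5.0), weak (3.5-6.5) and very weak
#' (4.5-7.5 Angstrom). Glycosidic torsion restraints use the anti windows
#' 170-280 degrees (purines) and 170-310 degrees (pyrimidines). Hydrogen
#' bond and planarity restraints are derived from classified pairs and
#' quartets.
#' @name restraints
NULL

.NOE_BOUNDS <- list(strong = c(1.8, 3.6), medium = c(2.6, 5.0),
                    weak = c(3.5, 6.5), very_weak = c(4.5, 7.5))
.NOE_CLASSES <- names(.NOE_BOUNDS)

#' Calibrate the NOE reference volume
#'
#' Arithmetic mean of the intra-nucleotide H8-H1' peak volumes over the
#' residues supplied as being in clear anti orientation; this mean volume
#' corresponds to a distance of `ref_distance` (3.9 Angstrom).
#'
#' @param peaks data.frame with columns res_i, atom_i, res_j, atom_j,
#'   volume (chain columns optional)
#' @param anti_residues residue numbers in anti orientation
#' @param ref_distance calibration distance (Angstrom)
#' @return list(reference_volume, ref_distance, n_used)
#' @export
calibrate_reference <- function(peaks, anti_residues, ref_distance = 3.9) {
  stopifnot(all(c("res_i", "atom_i", "res_j", "atom_j", "volume") %in%
                  names(peaks)))
  if (any(peaks$volume <= 0)) stop("peak volumes must be positive")
  intra <- peaks$res_i == peaks$res_j &
    ((peaks$atom_i == "H8" & peaks$atom_j == "H1'") |
       (peaks$atom_i == "H1'" & peaks$atom_j == "H8")) &
    peaks$res_i %in% anti_residues
  if (!any(intra)) {
    stop("NOE calibration failed: no intra-nucleotide H8-H1' peak among the ",
         "supplied anti residues. Check the anti residue list and the peak ",
         "atom names (expected H8 / H1').")
  }
  list(reference_volume = mean(peaks$volume[intra]),
       ref_distance = ref_distance, n_used = sum(intra))
}

#' Estimate a distance from an NOE volume
#'
#' Isolated-spin-pair approximation: `r = ref_distance * (V_ref / V)^(1/6)`.
#' @param volume peak volume (> 0)
#' @param reference calibration from [calibrate_reference()] (or a number,
#'   taken as the reference volume for 3.9 Angstrom)
#' @return estimated distance (Angstrom)
#' @export
noe_distance <- function(volume, reference) {
  if (is.numeric(reference)) reference <- list(reference_volume = reference,
                                               ref_distance = 3.9)
  stopifnot(volume > 0)
  reference$ref_distance * (reference$reference_volume / volume)^(1 / 6)
}

#' Classify an NOE peak into a distance restraint
#'
#' Class cutoffs on the estimated distance (strong < `cutoffs[1]`, medium <
#' `cutoffs[2]`, weak < `cutoffs[3]`, else very weak) are configurable; the
#' class bin bounds themselves are fixed at the standard values.
#'
#' @param peak one-row peak data.frame (res_i, atom_i, res_j, atom_j, volume)
#' @param reference calibration from [calibrate_reference()]
#' @param cutoffs length-3 increasing distance cutoffs (Angstrom)
#' @param force_constant metadata, kcal mol^-1 A^-2
#' @return one-row data.frame: atom references, r_est, class, lower, upper,
#'   force_constant
#' @export
classify_noe <- function(peak, reference, cutoffs = c(3.0, 4.2, 5.5),
                         force_constant = 20) {
  stopifnot(length(cutoffs) == 3, !is.unsorted(cutoffs))
  r <- noe_distance(peak$volume, reference)
  cls <- .NOE_CLASSES[findInterval(r, cutoffs) + 1L]
  b <- .NOE_BOUNDS[[cls]]
  data.frame(type = "distance",
             chain_i = peak$chain_i %||% "A", res_i = peak$res_i,
             atom_i = peak$atom_i,
             chain_j = peak$chain_j %||% "A", res_j = peak$res_j,
             atom_j = peak$atom_j,
             r_est = r, class = cls, lower = b[1], upper = b[2],
             force_constant = force_constant, stringsAsFactors = FALSE)
}

#' Distance restraints for a whole peak table
#'
#' @param peaks peak data.frame
#' @param reference calibration from [calibrate_reference()]
#' @param exclude logical vector of peaks to skip (e.g. H2'/H2'' peaks
#'   flagged as unusable references)
#' @param ... passed to [classify_noe()]
#' @return data.frame of distance restraints
#' @export
noe_restraints <- function(peaks, reference, exclude = NULL, ...) {
  if (!is.null(exclude)) peaks <- peaks[!exclude, , drop = FALSE]
  out <- lapply(seq_len(nrow(peaks)), function(i)
    classify_noe(peaks[i, , drop = FALSE], reference, ...))
  res <- do.call(rbind, out) %||% data.frame()
  rownames(res) <- NULL
  res
}

#' Glycosidic torsion restraints for anti residues
#'
#' anti purine: chi in \[170, 280\]; anti pyrimidine: chi in \[170, 310\];
#' syn and other residues yield no restraint.
#'
#' @param residues data.frame with columns chain, resno, restype and
#'   chi_class (e.g. from [torsion_table()])
#' @param force_constant metadata, kcal mol^-1 rad^-2
#' @return data.frame of torsion restraints
#' @export
chi_restraints <- function(residues, force_constant = 200) {
  out <- list()
  for (i in seq_len(nrow(residues))) {
    if (!identical(residues$chi_class[i], "anti")) next
    purine <- residues$restype[i] %in% c("DA", "DG", "DI")
    out[[length(out) + 1L]] <- data.frame(
      type = "torsion", chain = residues$chain[i], resno = residues$resno[i],
      angle_name = "chi", lower = 170, upper = if (purine) 280 else 310,
      force_constant = force_constant, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(type = character(0), chain = character(0), resno = numeric(0),
               angle_name = character(0), lower = numeric(0),
               upper = numeric(0), force_constant = numeric(0))
  rownames(res) <- NULL
  res
}

#' Hydrogen-bond distance restraints from classified pairs
#'
#' One heavy-atom restraint (bounds 2.7-3.1 Angstrom, force constant 20)
#' per pattern hydrogen bond of every classified (non-OTHER) pair.
#'
#' @param pairs classified pair table from [find_pairs()]
#' @param hbonds hydrogen bonds from [find_hbonds()]
#' @return data.frame of hbond distance restraints
#' @export
hbond_restraints <- function(pairs, hbonds) {
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    if (pairs$class[k] == "OTHER") next
    hb <- .hbonds_between(hbonds, c(pairs$chain_i[k], pairs$res_i[k]),
                          c(pairs$chain_j[k], pairs$res_j[k]))
    pat <- .pair_patterns()
    psig <- paste(pat$base_d, pat$donor, pat$base_a, pat$acceptor)
    sig <- paste(vapply(hb$restype_d, function(rt) .BASE_LETTER[[rt]] %||% "?",
                        character(1)), hb$donor,
                 vapply(hb$restype_a, function(rt) .BASE_LETTER[[rt]] %||% "?",
                        character(1)), hb$acceptor)
    cls <- pat$class[match(sig, psig)]
    hb <- hb[!is.na(cls) & cls == pairs$class[k], , drop = FALSE]
    for (i in seq_len(nrow(hb))) {
      out[[length(out) + 1L]] <- data.frame(
        type = "hbond", chain_i = hb$chain_d[i], res_i = hb$res_d[i],
        atom_i = hb$donor[i], chain_j = hb$chain_a[i], res_j = hb$res_a[i],
        atom_j = hb$acceptor[i], r_est = hb$distance[i],
        class = pairs$class[k], lower = 2.7, upper = 3.1,
        force_constant = 20, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(type = character(0), chain_i = character(0),
               res_i = numeric(0), atom_i = character(0),
               chain_j = character(0), res_j = numeric(0),
               atom_j = character(0), r_est = numeric(0),
               class = character(0), lower = numeric(0), upper = numeric(0),
               force_constant = numeric(0))
  rownames(res) <- NULL
  res
}

#' Planarity restraint groups
#'
#' One planarity group (force constant 50) per GAGA-quartet and per G-G
#' pair in N1-carbonyl symmetric geometry; no other quartet or pair class
#' receives one.
#'
#' @param quartets quartet table from [assemble_quartets()]
#' @param pairs classified pair table from [find_pairs()]
#' @param force_constant metadata, kcal mol^-1 rad^-2
#' @return data.frame: group, members (comma-joined chain:resno),
#'   force_constant
#' @export
planarity_restraints <- function(quartets, pairs, force_constant = 50) {
  out <- list()
  for (k in seq_len(nrow(quartets))) {
    if (quartets$quartet_class[k] != "GAGA") next
    out[[length(out) + 1L]] <- data.frame(
      type = "planarity", group = "GAGA_quartet",
      members = quartets$residues[k], force_constant = force_constant,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(pairs))) {
    if (pairs$class[k] != "GG_N1_CARBONYL") next
    out[[length(out) + 1L]] <- data.frame(
      type = "planarity", group = "GG_N1_carbonyl_pair",
      members = paste(.res_key(pairs$chain_i[k], pairs$res_i[k]),
                      .res_key(pairs$chain_j[k], pairs$res_j[k]), sep = ","),
      force_constant = force_constant, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||%
    data.frame(type = character(0), group = character(0),
               members = character(0), force_constant = numeric(0))
  rownames(res) <- NULL
  res
}

#' Bundle restraints into a RestraintSet
#'
#' @param distance,torsion,hbond,planarity restraint data.frames (possibly
#'   empty)
#' @param provenance named list recorded verbatim (calibration parameters,
#'   cutoffs, ...)
#' @return object of class RestraintSet
#' @export
restraint_set <- function(distance = NULL, torsion = NULL, hbond = NULL,
                          planarity = NULL, provenance = list()) {
  structure(list(distance = distance %||% data.frame(),
                 torsion = torsion %||% data.frame(),
                 hbond = hbond %||% data.frame(),
                 planarity = planarity %||% data.frame(),
                 provenance = provenance),
            class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf(paste0("RestraintSet: %d distance, %d torsion, %d hbond, ",
                     "%d planarity restraint(s)\n"),
              nrow(x$distance), nrow(x$torsion), nrow(x$hbond),
              nrow(x$planarity)))
  if (length(x$provenance)) {
    cat("  provenance:",
        paste(names(x$provenance),
              vapply(x$provenance, function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Count restraints per category
#' @param set RestraintSet
#' @return named integer vector
#' @export
restraint_counts <- function(set) {
  c(distance = nrow(set$distance), torsion = nrow(set$torsion),
    hbond = nrow(set$hbond), planarity = nrow(set$planarity))
}

.flatten_restraints <- function(set) {
  blocks <- list()
  for (kind in c("distance", "torsion", "hbond", "planarity")) {
    df <- set[[kind]]
    if (!nrow(df)) next
    common <- data.frame(type = kind,
                         atom_i = NA_character_, atom_j = NA_character_,
                         lower = NA_real_, upper = NA_real_,
                         class = NA_character_, force_constant = NA_real_,
                         stringsAsFactors = FALSE)[rep(1, nrow(df)), ]
    if (kind %in% c("distance", "hbond")) {
      common$atom_i <- paste0(df$chain_i, ":", df$res_i, ":", df$atom_i)
      common$atom_j <- paste0(df$chain_j, ":", df$res_j, ":", df$atom_j)
      common$class <- df$class
    } else if (kind == "torsion") {
      common$atom_i <- paste0(df$chain, ":", df$resno, ":", df$angle_name)
      common$class <- "anti"
    } else {
      common$atom_i <- df$members
      common$class <- df$group
    }
    common$lower <- df$lower %||% NA_real_
    common$upper <- df$upper %||% NA_real_
    common$force_constant <- df$force_constant
    blocks[[length(blocks) + 1L]] <- common
  }
  res <- do.call(rbind, blocks) %||%
    data.frame(type = character(0), atom_i = character(0),
               atom_j = character(0), lower = numeric(0), upper = numeric(0),
               class = character(0), force_constant = numeric(0))
  rownames(res) <- NULL
  res
}

#' Write a RestraintSet to disk
#'
#' `tsv`: one tab-separated table with columns type, atom_i, atom_j, lower,
#' upper, class, force_constant. `flat_list`: one restraint per line in
#' fixed-width fields. Both dialects round-trip through
#' [read_restraints()].
#'
#' @param set RestraintSet
#' @param path output file
#' @param dialect `"tsv"` or `"flat_list"`
#' @export
write_restraints <- function(set, path, dialect = c("tsv", "flat_list")) {
  dialect <- match.arg(dialect)
  flat <- .flatten_restraints(set)
  if (dialect == "tsv") {
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ".")
  } else {
    lines <- sprintf("%-10s %-24s %-24s %8s %8s %-22s %8s",
                     flat$type, flat$atom_i,
                     ifelse(is.na(flat$atom_j), ".", flat$atom_j),
                     ifelse(is.na(flat$lower), ".", sprintf("%.3f", flat$lower)),
                     ifelse(is.na(flat$upper), ".", sprintf("%.3f", flat$upper)),
                     ifelse(is.na(flat$class), ".", flat$class),
                     sprintf("%.1f", flat$force_constant))
    header <- sprintf("%-10s %-24s %-24s %8s %8s %-22s %8s",
                      "type", "atom_i", "atom_j", "lower", "upper", "class",
                      "force_constant")
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

#' Read back a serialized restraint table
#'
#' @param path file written by [write_restraints()]
#' @param dialect `"tsv"` or `"flat_list"`
#' @return data.frame in the flattened layout
#' @export
read_restraints <- function(path, dialect = c("tsv", "flat_list")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  } else {
    raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             na.strings = ".")
    df <- raw
  }
  df
}
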