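#' @title Helical, torsional and groove geometry
#' @description
#' Per-residue backbone/glycosidic torsions and sugar pseudorotation,
#' per-pair and per-step helical parameters, quartet non-planarity
#' ("quartet buckle": the angle between the mean planes of the two
#' constituent base pairs) and cross-strand phosphate groove widths.
#' @name geometry
NULL

# dihedral angle (degrees, (-180, 180]) for four points
.dihedral <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4))
}

#' Base frames for every residue of a model
#'
#' @param model model atom table from [get_model()]
#' @return named list of frames, keyed `"chain:resno"`
#' @export
base_frames <- function(model) {
  res <- .split_residues(model)
  lapply(res, fit_base_frame)
}

#' Sugar pseudorotation from the five endocyclic torsions
#'
#' Altona-Sundaralingam formalism: `tan(P) = ((nu4+nu1)-(nu3+nu0)) /
#' (2 nu2 (sin 36 + sin 72))`, amplitude `tau_m = nu2 / cos(P)`.
#'
#' @param nu numeric length-5 vector (nu0..nu4, degrees)
#' @return list(phase in [0, 360), amplitude >= 0)
#' @export
pseudorotation <- function(nu) {
  stopifnot(length(nu) == 5)
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(.deg2rad(36)) + sin(.deg2rad(72)))
  P <- .rad2deg(atan2(num, den)) %% 360
  amp <- nu[3] / cos(.deg2rad(P))
  list(phase = P, amplitude = abs(amp))
}

#' Sugar pucker class from pseudorotation phase
#'
#' North = P in [324, 360) or [0, 36] (~C3'-endo); South = P in [108, 180]
#' (~C2'-endo); otherwise `"other"`.
#' @param P phase in degrees
#' @return `"North"`, `"South"` or `"other"`
#' @export
pucker_class <- function(P) {
  P <- P %% 360
  if (P >= 324 || P <= 36) return("North")
  if (P >= 108 && P <= 180) return("South")
  "other"
}

#' Glycosidic torsion class
#'
#' syn for chi in (0, 120); anti for chi in [170, 280] (the anti restraint
#' window used for purines in structure calculation); high_anti for chi in
#' (280, 320]; `"other"` elsewhere. chi is taken in [0, 360).
#' @param chi glycosidic torsion in degrees
#' @return class label
#' @export
chi_class <- function(chi) {
  x <- chi %% 360
  if (x > 0 && x < 120) return("syn")
  if (x >= 170 && x <= 280) return("anti")
  if (x > 280 && x <= 320) return("high_anti")
  "other"
}

.tors_atoms <- list(
  alpha = c("O3'-", "P", "O5'", "C5'"),
  beta = c("P", "O5'", "C5'", "C4'"),
  gamma = c("O5'", "C5'", "C4'", "C3'"),
  delta = c("C5'", "C4'", "C3'", "O3'"),
  epsilon = c("C4'", "C3'", "O3'", "P+"),
  zeta = c("C3'", "O3'", "P+", "O5'+"))

.sugar_ring <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'"))

.get_tors_atom <- function(name, res, prev, nxt) {
  if (endsWith(name, "-")) {
    if (is.null(prev)) return(NULL)
    return(.res_atom(prev, sub("-$", "", name)))
  }
  if (endsWith(name, "+")) {
    if (is.null(nxt)) return(NULL)
    return(.res_atom(nxt, sub("\\+$", "", name)))
  }
  .res_atom(res, name)
}

#' Backbone/glycosidic torsion and sugar pucker profile of one residue
#'
#' IUPAC atom quadruples; angles mapped to [0, 360). Terminal residues have
#' undefined alpha or epsilon/zeta, reported as NA. chi uses
#' O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines.
#'
#' @param res residue atom table
#' @param prev,nxt 5' and 3' neighbour residue tables (or NULL at termini)
#' @return one-row data.frame with torsions, chi class, pucker phase,
#'   amplitude and class
#' @export
torsion_profile <- function(res, prev = NULL, nxt = NULL) {
  sugar <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  missing_sugar <- setdiff(sugar, res$atom)
  if (length(missing_sugar))
    stop(sprintf("residue %s:%s: missing sugar atom(s) %s",
                 res$chain[1], res$resno[1],
                 paste(missing_sugar, collapse = ",")))
  ang <- vapply(names(.tors_atoms), function(tn) {
    pts <- lapply(.tors_atoms[[tn]], .get_tors_atom, res = res,
                  prev = prev, nxt = nxt)
    if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
    .dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]) %% 360
  }, numeric(1))
  purine <- res$restype[1] %in% c("DA", "DG", "DI")
  chi_atoms <- if (purine) c("O4'", "C1'", "N9", "C4") else c("O4'", "C1'", "N1", "C2")
  chp <- lapply(chi_atoms, .res_atom, res_df = res)
  chi <- if (any(vapply(chp, is.null, logical(1)))) NA_real_ else
    .dihedral(chp[[1]], chp[[2]], chp[[3]], chp[[4]]) %% 360
  nu <- vapply(.sugar_ring, function(a) {
    pts <- lapply(a, .res_atom, res_df = res)
    .dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }, numeric(1))
  pk <- pseudorotation(nu)
  data.frame(chain = res$chain[1], resno = res$resno[1],
             restype = res$restype[1],
             alpha = ang["alpha"], beta = ang["beta"], gamma = ang["gamma"],
             delta = ang["delta"], epsilon = ang["epsilon"],
             zeta = ang["zeta"], chi = chi,
             chi_class = if (is.na(chi)) NA_character_ else chi_class(chi),
             pucker_phase = pk$phase, pucker_amplitude = pk$amplitude,
             pucker_class = pucker_class(pk$phase),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Torsion/pucker table for every residue of a model
#'
#' Residues lacking sugar atoms (bases-only synthetic models) are skipped.
#' @param model model atom table
#' @return data.frame, one row per residue with a complete sugar
#' @export
torsion_table <- function(model) {
  res <- .split_residues(model)
  out <- list()
  for (i in seq_along(res)) {
    r <- res[[i]]
    if (!all(c("C1'", "C2'", "C3'", "C4'", "O4'") %in% r$atom)) next
    prev <- if (i > 1 && res[[i - 1]]$chain[1] == r$chain[1] &&
                res[[i - 1]]$resno[1] == r$resno[1] - 1) res[[i - 1]] else NULL
    nxt <- if (i < length(res) && res[[i + 1]]$chain[1] == r$chain[1] &&
               res[[i + 1]]$resno[1] == r$resno[1] + 1) res[[i + 1]] else NULL
    out[[length(out) + 1L]] <- torsion_profile(r, prev, nxt)
  }
  do.call(rbind, out) %||% data.frame()
}

#' Quartet planarity parameters
#'
#' `quartet_buckle` is the angle (degrees, [0, 90]) between the mean planes
#' of the quartet's two constituent base pairs (best-fit planes through
#' their base ring atoms); `plane_rmsd` is the rms deviation of all ring
#' atoms from the single best-fit quartet plane.
#'
#' @param model model atom table
#' @param residues list of four `c(chain, resno)` pairs ordered as
#'   (pair1 res1, pair1 res2, pair2 res1, pair2 res2)
#' @return list(quartet_buckle, plane_rmsd)
#' @export
quartet_params <- function(model, residues) {
  stopifnot(length(residues) == 4)
  ring_xyz <- function(idx) {
    X <- lapply(idx, function(r) {
      sub <- model[model$chain == r[1] & model$resno == as.numeric(r[2]), ]
      ring <- .ring_atoms_for(sub$restype[1])
      as.matrix(sub[sub$atom %in% ring, c("x", "y", "z")])
    })
    do.call(rbind, X)
  }
  p1 <- .fit_plane(ring_xyz(residues[1:2]))
  p2 <- .fit_plane(ring_xyz(residues[3:4]))
  ang <- .rad2deg(acos(min(1, abs(sum(p1$normal * p2$normal)))))
  all_fit <- .fit_plane(ring_xyz(residues))
  list(quartet_buckle = ang, plane_rmsd = all_fit$rmsd)
}

#' Cross-strand phosphate-phosphate groove widths
#'
#' Groove width convention: P-P distance minus 5.8 Angstrom (twice the
#' phosphate group radius). Labels: narrow < 4, medium 4-9, wide > 9
#' (configurable).
#'
#' @param model model atom table
#' @param strand_pairs optional list of `c(chain_a, chain_b)` pairs to
#'   restrict to; default all distinct chain pairs
#' @param max_distance only report P-P pairs closer than this (Angstrom)
#' @param thresholds length-2 numeric: narrow/medium and medium/wide cuts
#' @return data.frame chain_a, res_a, chain_b, res_b, p_p_distance, width,
#'   label
#' @export
groove_widths <- function(model, strand_pairs = NULL, max_distance = 30,
                          thresholds = c(4, 9)) {
  ph <- model[model$atom == "P", , drop = FALSE]
  chains <- unique(ph$chain)
  if (is.null(strand_pairs)) {
    strand_pairs <- list()
    if (length(chains) >= 2) {
      cmb <- utils::combn(chains, 2)
      strand_pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
    }
  }
  out <- list()
  for (sp in strand_pairs) {
    a <- ph[ph$chain == sp[1], , drop = FALSE]
    b <- ph[ph$chain == sp[2], , drop = FALSE]
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      d <- .vnorm(as.numeric(a[i, c("x", "y", "z")]) -
                    as.numeric(b[j, c("x", "y", "z")]))
      if (d > max_distance) next
      w <- d - 5.8
      out[[length(out) + 1L]] <- data.frame(
        chain_a = sp[1], res_a = a$resno[i], chain_b = sp[2], res_b = b$resno[j],
        p_p_distance = d, width = w,
        label = if (w < thresholds[1]) "narrow"
                else if (w <= thresholds[2]) "medium" else "wide",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(chain_a = character(0), res_a = numeric(0),
               chain_b = character(0), res_b = numeric(0),
               p_p_distance = numeric(0), width = numeric(0),
               label = character(0))
  rownames(res) <- NULL
  res
}

#' Unit frames and step parameters along a labelled layer stack
#'
#' Convenience for generated stacks (or any model with a layer labelling):
#' computes the unit frame of every layer (see [unit_frame()]; bases
#' ordered by chain) and the step parameters between consecutive layers.
#'
#' @param model model atom table
#' @param residues data.frame with columns chain, resno, layer (e.g. the
#'   `truth$residues` of [build_quartet_stack()])
#' @return list(frames = per-layer frames, steps = data.frame of step
#'   parameters between layers k and k+1)
#' @export
stack_steps <- function(model, residues) {
  layers <- sort(unique(residues$layer))
  frames <- lapply(layers, function(k) {
    sub <- residues[residues$layer == k, , drop = FALSE]
    sub <- sub[order(sub$chain), , drop = FALSE]
    fs <- lapply(seq_len(nrow(sub)), function(i)
      fit_base_frame(model[model$chain == sub$chain[i] &
                             model$resno == sub$resno[i], , drop = FALSE]))
    unit_frame(fs)
  })
  steps <- NULL
  if (length(layers) > 1) {
    steps <- do.call(rbind, lapply(seq_len(length(layers) - 1), function(k) {
      st <- step_params(frames[[k]], frames[[k + 1]])
      data.frame(layer_from = layers[k], layer_to = layers[k + 1],
                 t(st), stringsAsFactors = FALSE)
    }))
  }
  list(frames = stats::setNames(frames, layers), steps = steps)
}

#' Mean and SD of numeric parameter tables across models
#'
#' @param tabs list of data.frames with identical row identity; numeric
#'   columns are aggregated, the first table supplies identifier columns
#' @return data.frame with `<col>_mean` and `<col>_sd` columns
#' @export
ensemble_stats <- function(tabs) {
  stopifnot(length(tabs) >= 1)
  num <- vapply(tabs[[1]], is.numeric, logical(1))
  ids <- tabs[[1]][, !num, drop = FALSE]
  out <- ids
  for (cn in names(tabs[[1]])[num]) {
    if (cn %in% c("resno", "res_a", "res_b", "model")) {
      out[[cn]] <- tabs[[1]][[cn]]
      next
    }
    M <- vapply(tabs, function(t) t[[cn]], numeric(nrow(tabs[[1]])))
    M <- matrix(M, nrow = nrow(tabs[[1]]))
    out[[paste0(cn, "_mean")]] <- rowMeans(M)
    out[[paste0(cn, "_sd")]] <- apply(M, 1, stats::sd)
  }
  out
}
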