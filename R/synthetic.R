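#' @title Ground-truth synthetic fixtures
#' @description
#' Generates idealized quartet-stack coordinate ensembles (with controllable
#' rise, twist, buckle and propeller and known pair/quartet classes),
#' random sequences with planted consensus motifs, and NOE volume tables
#' following the inverse-sixth-power distance law -- each with
#' machine-readable truth, so detectors and estimators can be validated
#' end to end without any external data.
#'
#' Layer geometries are solved deterministically at first use: base 2 (and
#' the second pair of a quartet) is placed in the base-1 plane by
#' minimizing deviations of the class's hydrogen bonds from ideal geometry
#' (donor-acceptor 2.9 Angstrom, near-linear donor-H-acceptor) under a
#' steric penalty, starting from a fixed grid. Solutions are cached per
#' session.
#' @name synthetic
NULL

.LAYER_CLASSES <- c("GAGA", "GGGG", "GCGC_MINOR", "GCGC_MAJOR",
                    "GG_PAIR", "GC_PAIR", "GA_PAIR", "GI_PAIR")

.FLIP <- diag(c(1, -1, -1))

# hydrogens covalently attached to a heavy atom in the template (<= 1.2 A)
.template_hydrogens <- function(tpl, heavy_atom) {
  hv <- tpl[tpl$atom == heavy_atom, c("x", "y", "z")]
  hs <- tpl[tpl$element == "H", , drop = FALSE]
  d <- sqrt((hs$x - hv$x[1])^2 + (hs$y - hv$y[1])^2 + (hs$z - hv$z[1])^2)
  hs[d <= 1.2, , drop = FALSE]
}

# hydrogen-bond objective for a set of placed bases.
# bases: list of list(tpl = template df, R, o); bonds: list of
# list(d = base index, donor, a = base index, acceptor)
.layer_objective <- function(bases, bonds) {
  placed <- lapply(bases, function(b) {
    xyz <- t(b$R %*% t(as.matrix(b$tpl[, c("x", "y", "z")]))) +
      rep(b$o, each = nrow(b$tpl))
    list(tpl = b$tpl, xyz = xyz)
  })
  atom_xyz <- function(k, name) placed[[k]]$xyz[match(name, placed[[k]]$tpl$atom), ]
  obj <- 0
  bonded <- list()
  for (bd in bonds) {
    D <- atom_xyz(bd$d, bd$donor)
    A <- atom_xyz(bd$a, bd$acceptor)
    dda <- .vnorm(D - A)
    obj <- obj + 10 * (dda - 2.9)^2
    hs <- .template_hydrogens(bases[[bd$d]]$tpl, bd$donor)
    if (nrow(hs)) {
      best <- -Inf
      for (hi in seq_len(nrow(hs))) {
        H <- as.numeric(bases[[bd$d]]$R %*% as.numeric(hs[hi, c("x", "y", "z")])) +
          bases[[bd$d]]$o
        v1 <- D - H; v2 <- A - H
        ang <- .rad2deg(acos(max(-1, min(1, sum(v1 * v2) /
                                           (.vnorm(v1) * .vnorm(v2))))))
        best <- max(best, ang)
      }
      obj <- obj + (max(0, 160 - best) / 30)^2
    }
    bonded[[length(bonded) + 1L]] <- c(bd$d, match(bd$donor, placed[[bd$d]]$tpl$atom),
                                       bd$a, match(bd$acceptor, placed[[bd$a]]$tpl$atom))
  }
  # steric clash between heavy atoms of different bases (hbond pairs exempt)
  nb <- length(bases)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    hi <- which(placed[[i]]$tpl$element != "H")
    hj <- which(placed[[j]]$tpl$element != "H")
    Xi <- placed[[i]]$xyz[hi, , drop = FALSE]
    Xj <- placed[[j]]$xyz[hj, , drop = FALSE]
    D2 <- outer(rowSums(Xi^2), rowSums(Xj^2), `+`) - 2 * Xi %*% t(Xj)
    D <- sqrt(pmax(D2, 0))
    for (bk in bonded) {
      if (bk[1] == i && bk[3] == j) {
        D[match(bk[2], hi), match(bk[4], hj)] <- Inf
      } else if (bk[1] == j && bk[3] == i) {
        D[match(bk[4], hi), match(bk[2], hj)] <- Inf
      }
    }
    obj <- obj + 20 * sum(pmax(0, 3.1 - D)^2)
  }
  obj
}

.pair_recipe <- function(class) {
  switch(class,
    GC_PAIR = list(bases = c("DG", "DC"),
                   bonds = list(list(d = 1, donor = "N1", a = 2, acceptor = "N3"),
                                list(d = 1, donor = "N2", a = 2, acceptor = "O2"),
                                list(d = 2, donor = "N4", a = 1, acceptor = "O6")),
                   analytic = TRUE),
    GG_PAIR = list(bases = c("DG", "DG"),
                   bonds = list(list(d = 1, donor = "N1", a = 2, acceptor = "O6"),
                                list(d = 2, donor = "N1", a = 1, acceptor = "O6")),
                   flips = c(FALSE, TRUE)),
    GA_PAIR = list(bases = c("DG", "DA"),
                   bonds = list(list(d = 1, donor = "N1", a = 2, acceptor = "N7"),
                                list(d = 2, donor = "N6", a = 1, acceptor = "O6")),
                   flips = c(TRUE, FALSE)),
    GI_PAIR = list(bases = c("DG", "DI"),
                   bonds = list(list(d = 1, donor = "N1", a = 2, acceptor = "N7"),
                                list(d = 1, donor = "N2", a = 2, acceptor = "O6")),
                   flips = c(TRUE, FALSE)),
    stop("unknown pair class: ", class))
}

# solve in-plane placement of base 2 relative to base 1 (at identity)
.solve_pair <- function(class) {
  cache <- .pkg_env$pair_layouts %||% list()
  if (!is.null(cache[[class]])) return(cache[[class]])
  rc <- .pair_recipe(class)
  tpl1 <- .template_for(rc$bases[1], base_only = TRUE)
  tpl2 <- .template_for(rc$bases[2], base_only = TRUE)
  if (isTRUE(rc$analytic)) {
    layout <- list(bases = list(
      list(restype = rc$bases[1], R = diag(3), o = c(0, 0, 0)),
      list(restype = rc$bases[2], R = .FLIP, o = c(0, 0, 0))),
      bonds = rc$bonds, class = class)
  } else {
    flips <- rc$flips %||% TRUE
    best <- NULL
    for (fl in flips) {
      Fm <- if (fl) .FLIP else diag(3)
      fobj <- function(p) {
        R2 <- rot_z(p[1]) %*% Fm
        .layer_objective(list(list(tpl = tpl1, R = diag(3), o = c(0, 0, 0)),
                              list(tpl = tpl2, R = R2, o = c(p[2], p[3], 0))),
                         rc$bonds)
      }
      grid <- expand.grid(theta = seq(0, 345, by = 15),
                          tx = seq(-8, 8, by = 2),
                          ty = seq(-8, 8, by = 2))
      vals <- apply(grid, 1, fobj)
      starts <- grid[order(vals)[1:10], , drop = FALSE]
      for (s in seq_len(nrow(starts))) {
        fit <- stats::optim(as.numeric(starts[s, ]), fobj,
                            method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12))
        fit <- stats::optim(fit$par, fobj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-12))
        if (is.null(best) || fit$value < best$value) best <- c(fit, flip = fl)
      }
    }
    p <- best$par
    Fm <- if (isTRUE(best$flip)) .FLIP else diag(3)
    layout <- list(bases = list(
      list(restype = rc$bases[1], R = diag(3), o = c(0, 0, 0)),
      list(restype = rc$bases[2], R = rot_z(p[1]) %*% Fm,
           o = c(p[2], p[3], 0))),
      bonds = rc$bonds, class = class, objective = best$value)
  }
  cache[[class]] <- layout
  .pkg_env$pair_layouts <- cache
  layout
}

# 180-degree rotation about the z axis through (cx, cy)
.c2z <- function(cx, cy) {
  R <- rot_z(180)
  list(R = R, o = c(2 * cx, 2 * cy, 0))
}

.apply_rigid <- function(base, R, o) {
  list(restype = base$restype, R = R %*% base$R,
       o = as.numeric(R %*% base$o) + o)
}

.quartet_recipe <- function(class) {
  switch(class,
    GAGA = list(pair = "GA_PAIR",
                cross = list(list(d_atom = "N6", d_base = 2, a_atom = "N7", a_base = 1))),
    GCGC_MINOR = list(pair = "GC_PAIR",
                      cross = list(list(d_atom = "N2", d_base = 1, a_atom = "O2", a_base = 2))),
    GCGC_MAJOR = list(pair = "GC_PAIR",
                      cross = list(list(d_atom = "N4", d_base = 2, a_atom = "O6", a_base = 1))),
    stop("unknown quartet class: ", class))
}

.solve_quartet <- function(class) {
  cache <- .pkg_env$quartet_layouts %||% list()
  if (!is.null(cache[[class]])) return(cache[[class]])
  if (class == "GGGG") {
    tpl <- .template_for("DG", base_only = TRUE)
    bonds <- list()
    for (k in 1:4) {
      nxt <- k %% 4 + 1
      bonds <- c(bonds, list(list(d = k, donor = "N1", a = nxt, acceptor = "O6"),
                             list(d = k, donor = "N2", a = nxt, acceptor = "N7")))
    }
    fobj <- function(p) {
      psi <- p[1]; cx <- p[2]; cy <- p[3]
      bases <- lapply(0:3, function(k) {
        Rk <- rot_z(90 * k)
        o0 <- c(0, 0, 0)
        list(tpl = tpl, R = Rk %*% rot_z(psi),
             o = as.numeric(Rk %*% (o0 - c(cx, cy, 0))) + c(cx, cy, 0))
      })
      .layer_objective(bases, bonds)
    }
    grid <- expand.grid(psi = seq(0, 330, by = 30),
                        cx = seq(-7, 7, by = 2), cy = seq(-7, 7, by = 2))
    vals <- apply(grid, 1, fobj)
    starts <- grid[order(vals)[1:6], , drop = FALSE]
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- stats::optim(as.numeric(starts[s, ]), fobj,
                          method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    p <- best$par
    bases <- lapply(0:3, function(k) {
      Rk <- rot_z(90 * k)
      list(restype = "DG", R = Rk %*% rot_z(p[1]),
           o = as.numeric(Rk %*% (c(0, 0, 0) - c(p[2], p[3], 0))) +
             c(p[2], p[3], 0))
    })
    layout <- list(bases = bases, bonds = bonds, class = "GGGG",
                   pair_split = list(1:2, 3:4), objective = best$value)
  } else {
    rc <- .quartet_recipe(class)
    pl <- .solve_pair(rc$pair)
    tpls <- lapply(pl$bases, function(b) .template_for(b$restype, base_only = TRUE))
    # cross bonds: donor in one pair copy, acceptor in the C2-related copy
    cross_bonds <- list()
    for (cb in rc$cross) {
      cross_bonds <- c(cross_bonds,
        list(list(d = cb$d_base, donor = cb$d_atom,
                  a = cb$a_base + 2, acceptor = cb$a_atom),
             list(d = cb$d_base + 2, donor = cb$d_atom,
                  a = cb$a_base, acceptor = cb$a_atom)))
    }
    fobj <- function(p) {
      c2 <- .c2z(p[1], p[2])
      bases <- c(
        lapply(seq_along(pl$bases), function(i)
          list(tpl = tpls[[i]], R = pl$bases[[i]]$R, o = pl$bases[[i]]$o)),
        lapply(seq_along(pl$bases), function(i) {
          b <- .apply_rigid(pl$bases[[i]], c2$R, c2$o)
          list(tpl = tpls[[i]], R = b$R, o = b$o)
        }))
      .layer_objective(bases, cross_bonds)
    }
    grid <- expand.grid(cx = seq(-9, 9, by = 1.5), cy = seq(-9, 9, by = 1.5))
    vals <- apply(grid, 1, fobj)
    starts <- grid[order(vals)[1:6], , drop = FALSE]
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- stats::optim(as.numeric(starts[s, ]), fobj,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    c2 <- .c2z(best$par[1], best$par[2])
    bases <- c(pl$bases, lapply(pl$bases, .apply_rigid, R = c2$R, o = c2$o))
    # all bonds: within-pair bonds of both copies + cross links
    bonds <- pl$bonds
    bonds2 <- lapply(pl$bonds, function(b) { b$d <- b$d + 2; b$a <- b$a + 2; b })
    layout <- list(bases = bases, bonds = c(bonds, bonds2, cross_bonds),
                   class = class, pair_split = list(1:2, 3:4),
                   objective = best$value)
  }
  cache[[class]] <- layout
  .pkg_env$quartet_layouts <- cache
  layout
}

# layer layout with the layer's unit frame normalized to the identity
.layer_layout <- function(class) {
  cache <- .pkg_env$layer_layouts %||% list()
  if (!is.null(cache[[class]])) return(cache[[class]])
  if (class %in% c("GG_PAIR", "GC_PAIR", "GA_PAIR", "GI_PAIR")) {
    layout <- .solve_pair(class)
    layout$pair_split <- list(1:2)
  } else {
    layout <- .solve_quartet(class)
  }
  bframes <- lapply(unlist(layout$pair_split), function(i)
    list(origin = layout$bases[[i]]$o, axes = layout$bases[[i]]$R))
  uf <- unit_frame(bframes)
  Rinv <- t(uf$axes)
  layout$bases <- lapply(layout$bases, .apply_rigid, R = Rinv,
                         o = as.numeric(-Rinv %*% uf$origin))
  cache[[class]] <- layout
  .pkg_env$layer_layouts <- cache
  layout
}

#' Build a synthetic quartet/pair stack ensemble
#'
#' Layers (quartets or base pairs) of the requested classes are stacked
#' along z with the given per-step rise and twist; per-layer buckle and
#' propeller are injected exactly through the mid-frame construction, so
#' recovered parameters equal the injected ones (pair layers; for quartet
#' layers `buckle` is applied between the two constituent pairs and equals
#' the resulting quartet buckle). Every hydrogen bond of each layer class
#' is present with near-ideal geometry.
#'
#' @param layer_classes character vector over
#'   GAGA, GGGG, GCGC_MINOR, GCGC_MAJOR, GG_PAIR, GC_PAIR, GA_PAIR, GI_PAIR
#' @param rise per-step rise (Angstrom, recycled; first element unused
#'   offset convention: step k is between layers k and k+1)
#' @param twist per-step twist (degrees, recycled)
#' @param buckle,propeller per-layer injected angles (degrees, recycled)
#' @param noise_sigma isotropic Gaussian coordinate noise (Angstrom)
#' @param seed RNG seed (fixes all randomness)
#' @param n_models number of models in the ensemble
#' @param backbone attach the idealized sugar-phosphate moiety
#' @return list(ensemble = StructureEnsemble, truth = list(layers, residues))
#' @export
build_quartet_stack <- function(layer_classes, rise = 3.4, twist = 25,
                                buckle = 0, propeller = 0, noise_sigma = 0,
                                seed = 1, n_models = 1, backbone = FALSE) {
  stopifnot(length(layer_classes) >= 1)
  bad <- setdiff(layer_classes, .LAYER_CLASSES)
  if (length(bad)) stop("unknown layer class(es): ", paste(bad, collapse = ", "))
  nl <- length(layer_classes)
  rise <- rep_len(rise, nl)
  twist <- rep_len(twist, nl)
  buckle <- rep_len(buckle, nl)
  propeller <- rep_len(propeller, nl)
  stopifnot(all(rise > 0))
  z <- cumsum(c(0, rise[-nl]))
  ang <- cumsum(c(0, twist[-nl]))
  chains <- c("A", "B", "C", "D")
  rows <- list()
  layer_truth <- list()
  res_truth <- list()
  for (k in seq_len(nl)) {
    layout <- .layer_layout(layer_classes[k])
    bases <- layout$bases
    npairs <- length(layout$pair_split)
    if (buckle[k] != 0 || propeller[k] != 0) {
      if (npairs == 1) {
        inv <- frame_step_inverse(tilt = buckle[k], roll = propeller[k])
        ps <- layout$pair_split[[1]]
        bases[[ps[1]]] <- .apply_rigid(bases[[ps[1]]], inv$f2$axes, inv$f2$origin)
        bases[[ps[2]]] <- .apply_rigid(bases[[ps[2]]], inv$f1$axes, inv$f1$origin)
      } else {
        # quartet: buckle = angle between the two pair planes
        Rq <- rot_x(buckle[k])
        for (i in layout$pair_split[[2]])
          bases[[i]] <- .apply_rigid(bases[[i]], Rq, c(0, 0, 0))
      }
    }
    Gk <- rot_z(ang[k])
    tk <- c(0, 0, z[k])
    for (i in seq_along(bases)) {
      b <- .apply_rigid(bases[[i]], Gk, tk)
      rows[[length(rows) + 1L]] <- .place_template(
        b$restype, b$R, b$o, chain = chains[i], resno = k,
        base_only = !backbone)
      res_truth[[length(res_truth) + 1L]] <- data.frame(
        chain = chains[i], resno = k, restype = b$restype, layer = k,
        layer_class = layer_classes[k], stringsAsFactors = FALSE)
    }
    layer_truth[[k]] <- data.frame(
      layer = k, class = layer_classes[k],
      rise = if (k < nl) rise[k] else NA_real_,
      twist = if (k < nl) twist[k] else NA_real_,
      buckle = buckle[k], propeller = propeller[k],
      stringsAsFactors = FALSE)
  }
  atoms_df <- do.call(rbind, rows)
  atoms <- atoms_df[, c("chain", "resno", "restype", "atom", "element")]
  xyz0 <- as.matrix(atoms_df[, c("x", "y", "z")])
  set.seed(seed)
  coords <- lapply(seq_len(n_models), function(m) {
    if (noise_sigma > 0) {
      xyz0 + matrix(stats::rnorm(length(xyz0), 0, noise_sigma), ncol = 3)
    } else xyz0
  })
  ens <- structure_ensemble(atoms, coords,
                            source = sprintf("synthetic stack (seed %d)", seed),
                            format = "synthetic")
  list(ensemble = ens,
       truth = list(layers = do.call(rbind, layer_truth),
                    residues = do.call(rbind, res_truth)))
}

#' Add isotropic Gaussian noise to ensemble coordinates
#'
#' @param ens StructureEnsemble
#' @param sigma noise standard deviation (Angstrom); 0 returns the input
#' @param seed RNG seed
#' @return perturbed ensemble
#' @export
perturb_coordinates <- function(ens, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(ens)
  set.seed(seed)
  ens$coords <- lapply(ens$coords, function(xyz)
    xyz + matrix(stats::rnorm(length(xyz), 0, sigma), ncol = 3))
  ens
}

#' Plant consensus motifs into random background sequences
#'
#' @param n_sequences number of sequences
#' @param sequence_length length of each (nt)
#' @param n_planted motifs planted per sequence
#' @param spacer_range spacer length range for the planted motif
#' @param composition background base probabilities (A, C, G, T)
#' @param mutation_rate per-base substitution probability applied to the
#'   whole sequence after planting
#' @param seed RNG seed
#' @param word repeat word (default AGCGA)
#' @param n_repeats repeats per planted motif
#' @return list(sequences = named character vector, truth = data.frame with
#'   exact planted intervals, 0-based half-open)
#' @export
plant_sequence_motifs <- function(n_sequences = 10, sequence_length = 500,
                                  n_planted = 1, spacer_range = c(1, 20),
                                  composition = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                  mutation_rate = 0, seed = 1,
                                  word = "AGCGA", n_repeats = 4) {
  set.seed(seed)
  stopifnot(spacer_range[1] >= 0, spacer_range[2] >= spacer_range[1])
  alph <- c("A", "C", "G", "T")
  w <- nchar(word)
  max_motif <- n_repeats * w + (n_repeats - 1) * spacer_range[2]
  if (max_motif > sequence_length)
    stop("infeasible packing: motif can reach ", max_motif,
         " nt but sequences are ", sequence_length, " nt")
  seqs <- character(n_sequences)
  names(seqs) <- sprintf("synth%03d", seq_len(n_sequences))
  truth <- list()
  for (s in seq_len(n_sequences)) {
    bg <- sample(alph, sequence_length, replace = TRUE, prob = composition)
    occupied <- rep(FALSE, sequence_length)
    for (p in seq_len(n_planted)) {
      spacers <- sample(seq(spacer_range[1], spacer_range[2]),
                        n_repeats - 1, replace = TRUE)
      motif_len <- n_repeats * w + sum(spacers)
      placed <- FALSE
      for (try in 1:200) {
        start <- sample.int(sequence_length - motif_len + 1, 1) - 1L
        if (any(occupied[(start + 1):(start + motif_len)])) next
        pos <- start
        rst <- integer(n_repeats)
        for (r in seq_len(n_repeats)) {
          rst[r] <- pos
          bg[(pos + 1):(pos + w)] <- strsplit(word, "")[[1]]
          pos <- pos + w + if (r < n_repeats) spacers[r] else 0
        }
        occupied[(start + 1):(start + motif_len)] <- TRUE
        truth[[length(truth) + 1L]] <- data.frame(
          seq_id = names(seqs)[s], start = start, end = start + motif_len,
          repeat_starts = paste(rst, collapse = ","),
          spacer_lengths = paste(spacers, collapse = ","),
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) stop("infeasible packing: could not place motif ", p,
                        " in sequence ", s)
    }
    if (mutation_rate > 0) {
      mut <- stats::runif(sequence_length) < mutation_rate
      if (any(mut)) {
        bg[mut] <- vapply(bg[mut], function(b)
          sample(setdiff(alph, b), 1), character(1))
      }
    }
    seqs[s] <- paste(bg, collapse = "")
  }
  list(sequences = seqs,
       truth = do.call(rbind, truth) %||%
         data.frame(seq_id = character(0), start = integer(0),
                    end = integer(0), repeat_starts = character(0),
                    spacer_lengths = character(0)))
}

#' Simulate NOE cross-peak volumes from a model
#'
#' `V = scale * r^-6 * exp(eps)`, `eps ~ Normal(0, noise_cv)`; `noise_cv =
#' 0` gives exact inverse-sixth-power volumes.
#'
#' @param model model atom table (must contain hydrogens)
#' @param proton_pairs optional data.frame (chain_i, res_i, atom_i, chain_j,
#'   res_j, atom_j); default: all H-H pairs within `max_distance`
#' @param scale volume scale factor
#' @param noise_cv log-normal noise level
#' @param seed RNG seed
#' @param max_distance cutoff for the default pair enumeration (Angstrom)
#' @param min_distance geminal/covalent proton pairs below this separation
#'   are excluded from the default enumeration; such cross-peaks are not
#'   used for distance restraints
#' @return list(peaks = data.frame with volume column, truth = data.frame
#'   with the underlying distances)
#' @export
simulate_noe_volumes <- function(model, proton_pairs = NULL, scale = 1,
                                 noise_cv = 0, seed = 1, max_distance = 6,
                                 min_distance = 1.8) {
  hs <- model[model$element == "H", , drop = FALSE]
  if (!nrow(hs)) stop("model contains no protons")
  if (is.null(proton_pairs)) {
    X <- as.matrix(hs[, c("x", "y", "z")])
    D2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * X %*% t(X)
    idx <- which(upper.tri(D2) & D2 <= max_distance^2 &
                   D2 >= min_distance^2, arr.ind = TRUE)
    proton_pairs <- data.frame(
      chain_i = hs$chain[idx[, 1]], res_i = hs$resno[idx[, 1]],
      atom_i = hs$atom[idx[, 1]],
      chain_j = hs$chain[idx[, 2]], res_j = hs$resno[idx[, 2]],
      atom_j = hs$atom[idx[, 2]], stringsAsFactors = FALSE)
  }
  key <- paste(model$chain, model$resno, model$atom)
  getxyz <- function(ch, rn, at)
    as.numeric(model[match(paste(ch, rn, at), key), c("x", "y", "z")])
  r <- vapply(seq_len(nrow(proton_pairs)), function(i) {
    .vnorm(getxyz(proton_pairs$chain_i[i], proton_pairs$res_i[i],
                  proton_pairs$atom_i[i]) -
             getxyz(proton_pairs$chain_j[i], proton_pairs$res_j[i],
                    proton_pairs$atom_j[i]))
  }, numeric(1))
  if (any(r == 0)) stop("zero interproton distance")
  set.seed(seed)
  eps <- if (noise_cv > 0) stats::rnorm(length(r), 0, noise_cv) else
    rep(0, length(r))
  peaks <- proton_pairs
  peaks$volume <- scale * r^-6 * exp(eps)
  truth <- proton_pairs
  truth$distance <- r
  list(peaks = peaks, truth = truth)
}
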