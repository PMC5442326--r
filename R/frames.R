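#' @title Base reference frames and mid-frame helical parameters
#' @description
#' Each base is assigned a right-handed orthonormal reference frame by
#' least-squares superposition of an idealized base template (expressed in
#' the standard nucleic-acid base reference frame) onto the observed ring
#' atoms. Intra-pair (shear, stretch, stagger, buckle, propeller, opening)
#' and inter-step (shift, slide, rise, tilt, roll, twist) parameters are
#' computed with the mid-frame (CEHS-style) formalism, so values are
#' comparable with mainstream helical-analysis tools.
#' @name frames
NULL

#' Load the idealized base templates
#'
#' Idealized nucleotide geometries (base + hydrogens + sugar-phosphate)
#' derived from the PDB Chemical Component Dictionary and expressed in the
#' standard base reference frame; shipped as
#' `extdata/base_templates.tsv`.
#'
#' @return data.frame restype, atom, element, x, y, z
#' @export
base_templates <- function() {
  tab <- .pkg_env$templates
  if (is.null(tab)) {
    tab <- utils::read.delim(.extdata("base_templates.tsv"),
                             stringsAsFactors = FALSE)
    .pkg_env$templates <- tab
  }
  tab
}

.template_for <- function(restype, atoms = NULL, base_only = FALSE) {
  tab <- base_templates()
  t <- tab[tab$restype == restype, , drop = FALSE]
  if (base_only) t <- t[!grepl("'", t$atom) & !(t$atom %in% c("P", "OP1", "OP2")), ]
  if (!is.null(atoms)) t <- t[t$atom %in% atoms, , drop = FALSE]
  t
}

#' Fit the standard reference frame to an observed base
#'
#' Least-squares (Kabsch) superposition of the template ring atoms onto the
#' observed ring atoms: `observed ~= R \%*\% template + origin`.
#'
#' @param res_df one residue's atom table (chain, resno, restype, atom, x, y, z)
#' @return list(origin, axes, rmsd, restype, distorted); `axes` columns are
#'   the frame x/y/z axes; `distorted` flags fit RMSD > 0.5 Angstrom
#' @export
fit_base_frame <- function(res_df) {
  restype <- res_df$restype[1]
  ring <- .ring_atoms_for(restype)
  tpl <- .template_for(restype, atoms = ring)
  obs <- res_df[match(tpl$atom, res_df$atom), , drop = FALSE]
  if (anyNA(obs$x))
    stop(sprintf("residue %s %s:%s: missing ring atom(s) for frame fit",
                 restype, res_df$chain[1], res_df$resno[1]))
  P <- as.matrix(tpl[, c("x", "y", "z")])
  Q <- as.matrix(obs[, c("x", "y", "z")])
  fit <- .kabsch(P, Q)
  list(origin = fit$t, axes = fit$R, rmsd = fit$rmsd, restype = restype,
       distorted = fit$rmsd > 0.5)
}

#' Flip a base frame (rotate 180 degrees about its x axis)
#'
#' Applied to the strand-II base of a pair before parameter computation,
#' following the standard reference frame convention in which an ideal
#' Watson-Crick partner occupies the flipped frame.
#' @param f frame
#' @return flipped frame
#' @export
flip_frame <- function(f) {
  f$axes[, 2] <- -f$axes[, 2]
  f$axes[, 3] <- -f$axes[, 3]
  f
}

# CEHS mid-frame step between two frames. Returns the six rigid-body
# parameters (translations in the mid frame; rotations tilt/roll/twist about
# the mid-frame x/y/z) plus the mid frame itself.
frame_step_full <- function(f1, f2) {
  z1 <- f1$axes[, 3]; z2 <- f2$axes[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- .rad2deg(acos(cg))
  cr <- .cross(z1, z2)
  if (gamma < 1e-7 || .vnorm(cr) < 1e-10) {
    gamma <- 0
    h <- f1$axes[, 1]
  } else {
    h <- .unit(cr)
  }
  A1 <- rot_axis(h, gamma / 2) %*% f1$axes
  A2 <- rot_axis(h, -gamma / 2) %*% f2$axes
  zm <- .unit(A1[, 3] + A2[, 3])
  twist <- .signed_angle(A1[, 2], A2[, 2], zm)
  ysum <- A1[, 2] + A2[, 2]
  ym <- if (.vnorm(ysum) > 1e-8) .unit(ysum) else
    as.numeric(rot_axis(zm, twist / 2) %*% A1[, 2])  # 180-degree twist
  xm <- .unit(.cross(ym, zm))
  Rm <- cbind(xm, ym, zm)
  phi <- .signed_angle(h, ym, zm)
  roll <- gamma * cos(.deg2rad(phi))
  tilt <- gamma * sin(.deg2rad(phi))
  tr <- as.numeric(t(Rm) %*% (f2$origin - f1$origin))
  mid <- list(origin = (f1$origin + f2$origin) / 2, axes = Rm)
  list(params = c(shift = tr[1], slide = tr[2], rise = tr[3],
                  tilt = tilt, roll = roll, twist = twist),
       mid = mid)
}

#' Rigid-body step parameters between two unit frames
#'
#' @param f1,f2 frames of consecutive units (bases, base pairs or quartets),
#'   lower unit first
#' @return named vector shift, slide, rise (Angstrom), tilt, roll, twist (degrees)
#' @export
step_params <- function(f1, f2) frame_step_full(f1, f2)$params

#' Intra-base-pair parameters
#'
#' For the usual antiparallel pair (opposing base normals) the strand-II
#' frame is flipped about its x axis, then the mid-frame step from the
#' flipped strand-II frame to the strand-I frame is reported as
#' shear/stretch/stagger (x/y/z translations) and buckle/propeller/opening
#' (x/y/z rotations). An ideal Watson-Crick pair scores zero on all six.
#' Pairs whose base normals already agree (parallel-type geometries such as
#' the C2-symmetric G-G N1-carbonyl pair) are not flipped; such pairs show
#' a characteristic opening near 180 degrees.
#'
#' @param f_i strand-I base frame
#' @param f_j strand-II base frame
#' @return named vector shear, stretch, stagger, buckle, propeller, opening
#' @export
pair_params <- function(f_i, f_j) {
  if (sum(f_i$axes[, 3] * f_j$axes[, 3]) < 0) f_j <- flip_frame(f_j)
  st <- frame_step_full(f_j, f_i)$params
  c(shear = unname(st["shift"]), stretch = unname(st["slide"]),
    stagger = unname(st["rise"]), buckle = unname(st["tilt"]),
    propeller = unname(st["roll"]), opening = unname(st["twist"]))
}

#' Mean frame of a base pair
#'
#' Quaternion average of the strand-I frame and the strand-II frame, the
#' latter flipped about its x axis when the base normals oppose; origin
#' midway between base origins.
#' @param f_i,f_j the two base frames
#' @return frame
#' @export
pair_frame <- function(f_i, f_j) {
  fj <- if (sum(f_i$axes[, 3] * f_j$axes[, 3]) < 0) flip_frame(f_j) else f_j
  list(origin = (f_i$origin + fj$origin) / 2,
       axes = .mean_rotation(list(f_i$axes, fj$axes)))
}

#' Average several frames (quaternion mean)
#' @param frames list of frames
#' @return frame
#' @export
mean_frame <- function(frames) {
  list(origin = Reduce(`+`, lapply(frames, `[[`, "origin")) / length(frames),
       axes = .mean_rotation(lapply(frames, `[[`, "axes")))
}

#' Unit frame of a pair or quartet layer
#'
#' Two base frames give the pair frame. Four base frames (ordered as pair
#' 1 residue 1/2, pair 2 residue 1/2) give the quartet frame: origin at the
#' centroid of the two pair-frame origins, orientation taken from the first
#' constituent pair. The orientation of a C2-symmetric quartet is only
#' defined modulo 180 degrees; anchoring it to the first pair makes step
#' twists between stacked quartets deterministic.
#'
#' @param frames list of 2 or 4 base frames
#' @return frame
#' @export
unit_frame <- function(frames) {
  if (length(frames) == 2) return(pair_frame(frames[[1]], frames[[2]]))
  stopifnot(length(frames) == 4)
  p1 <- pair_frame(frames[[1]], frames[[2]])
  p2 <- pair_frame(frames[[3]], frames[[4]])
  list(origin = (p1$origin + p2$origin) / 2, axes = p1$axes)
}

# inverse of frame_step_full: construct (f1, f2) about the identity mid
# frame realizing the given parameters exactly
frame_step_inverse <- function(shift = 0, slide = 0, rise = 0,
                               tilt = 0, roll = 0, twist = 0) {
  gamma <- sqrt(tilt^2 + roll^2)
  phi <- .rad2deg(atan2(tilt, roll))
  h <- as.numeric(rot_z(-phi) %*% c(0, 1, 0))
  R1 <- rot_z(-twist / 2)
  R2 <- rot_z(twist / 2)
  if (gamma > 1e-12) {
    R1 <- rot_axis(h, -gamma / 2) %*% R1
    R2 <- rot_axis(h, gamma / 2) %*% R2
  }
  d <- c(shift, slide, rise)
  list(f1 = list(origin = -d / 2, axes = R1),
       f2 = list(origin = d / 2, axes = R2))
}

#' Transform a frame by a global rotation/translation
#' @param f frame
#' @param R 3x3 rotation
#' @param t length-3 translation
#' @return transformed frame
#' @export
transform_frame <- function(f, R = diag(3), t = c(0, 0, 0)) {
  list(origin = as.numeric(R %*% f$origin) + t, axes = R %*% f$axes)
}

# place template atoms of `restype` with frame (R, o); returns residue df
.place_template <- function(restype, axes, origin, chain, resno,
                            base_only = TRUE) {
  tpl <- .template_for(restype, base_only = base_only)
  xyz <- t(axes %*% t(as.matrix(tpl[, c("x", "y", "z")]))) +
    rep(origin, each = nrow(tpl))
  data.frame(chain = chain, resno = resno, restype = restype,
             atom = tpl$atom, element = tpl$element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
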