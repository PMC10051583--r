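#' Amide 15N chemical shift anisotropy tensor
#'
#' Constructor with validity checks for the \eqn{^{15}}N CSA tensor of a
#' backbone amide, given as principal values (ppm, ordered
#' sigma11 <= sigma22 <= sigma33) and the orientation of the principal
#' axis system in the amide frame: the sigma33 axis lies in the peptide
#' plane at \code{beta_nh} degrees from the N-H bond, sigma22 is
#' perpendicular to the peptide plane, and sigma11 completes the triad.
#'
#' @param sigma11,sigma22,sigma33 principal values in ppm.
#' @param beta_nh angle (degrees) between the sigma33 axis and the N-H
#'   bond, measured in the peptide plane.
#' @return Object of class \code{csa_tensor}.
#' @examples
#' csa_tensor()  # literature defaults (57, 81, 227) ppm, beta = 17 deg
#' @export
csa_tensor <- function(sigma11 = 57, sigma22 = 81, sigma33 = 227,
                       beta_nh = 17) {
  if (!(sigma11 <= sigma22 && sigma22 <= sigma33))
    stop("principal values must satisfy sigma11 <= sigma22 <= sigma33")
  structure(list(sigma11 = sigma11, sigma22 = sigma22, sigma33 = sigma33,
                 beta_nh = beta_nh,
                 iso = (sigma11 + sigma22 + sigma33) / 3),
            class = "csa_tensor")
}

#' @export
print.csa_tensor <- function(x, ...) {
  cat(sprintf(
    "15N CSA tensor: (%.1f, %.1f, %.1f) ppm, iso %.1f ppm, beta_NH %.1f deg\n",
    x$sigma11, x$sigma22, x$sigma33, x$iso, x$beta_nh))
  invisible(x)
}

#' Gaussian motional model for oriented-sample averaging
#'
#' Independent Gaussian fluctuations of the helix orientation: wobble of
#' the tilt angle about its nominal value (SD \code{wobble_sd} degrees)
#' and azimuthal fluctuation, i.e. rotation about the helix long axis
#' (SD \code{azimuth_sd} degrees). Averaging of the resonance values is
#' by Gauss-Hermite quadrature with \code{n_points} nodes per dimension.
#'
#' @param wobble_sd,azimuth_sd Gaussian standard deviations in degrees
#'   (>= 0); defaults 10 and 18.
#' @param n_points quadrature nodes per dimension (>= 3), default 21.
#' @return Object of class \code{motion_model}.
#' @export
motion_model <- function(wobble_sd = 10, azimuth_sd = 18, n_points = 21) {
  if (wobble_sd < 0 || azimuth_sd < 0)
    stop("fluctuation SDs must be >= 0")
  if (n_points < 3)
    stop("configuration error: n_points must be >= 3")
  structure(list(wobble_sd = wobble_sd, azimuth_sd = azimuth_sd,
                 n_points = n_points), class = "motion_model")
}

#' Helix orientation relative to the membrane normal
#'
#' The tilt angle is the angle between the helix long axis and the
#' membrane normal (0 = transmembrane, 90 = in-plane); the pitch angle is
#' the rotation of the helix about its own long axis, measured from the
#' model's azimuth reference (residue 1's Calpha-to-Cbeta projection).
#'
#' @param tilt degrees in [0, 180].
#' @param pitch degrees, reduced modulo 360.
#' @return Object of class \code{orientation}.
#' @export
orientation <- function(tilt, pitch) {
  if (tilt < 0 || tilt > 180) stop("tilt must lie in [0, 180] degrees")
  structure(list(tilt = tilt, pitch = pitch %% 360), class = "orientation")
}

# CSA tensor of one amide as a symmetric 3x3 matrix in the helix frame
# (model coordinates, axis along z)
tensor_in_helix_frame <- function(frame, tensor) {
  b <- deg2rad(tensor$beta_nh)
  # sigma33 in the peptide plane at beta from N-H, rotated towards the
  # in-plane perpendicular; sigma22 along the plane normal
  e33 <- cos(b) * frame$nh_unit + sin(b) * frame$in_plane_perp
  e22 <- frame$plane_normal
  e11 <- pracma::cross(e22, e33)
  tensor$sigma11 * tcrossprod(e11) +
    tensor$sigma22 * tcrossprod(e22) +
    tensor$sigma33 * tcrossprod(e33)
}

# magnetic field unit vector expressed in the helix frame for a given
# orientation: the membrane normal is along the laboratory z axis; the
# molecule is rotated by pitch about its own axis then tilted, so in the
# molecular frame the field direction is
#   b = Rz(-pitch) Ry(-tilt) z = (-sin(tilt) cos(pitch),
#                                  sin(tilt) sin(pitch), cos(tilt))
field_in_helix_frame <- function(tilt_deg, pitch_deg) {
  t <- deg2rad(tilt_deg); p <- deg2rad(pitch_deg)
  c(-sin(t) * cos(p), sin(t) * sin(p), cos(t))
}

#' Static oriented-sample chemical shift
#'
#' The observed chemical shift of one amide \eqn{^{15}}N in a uniaxially
#' oriented sample with the magnetic field along the membrane normal, for
#' a rigid helix at the given orientation: the quadratic form b' S b of
#' the lab-frame field direction with the CSA tensor. The result always
#' lies within [sigma11, sigma33].
#'
#' @param frame an \code{\link{amide_frame}}.
#' @param tensor a \code{\link{csa_tensor}}.
#' @param orient an \code{\link{orientation}}.
#' @return Chemical shift in ppm.
#' @export
static_shift <- function(frame, tensor, orient) {
  stopifnot(inherits(frame, "amide_frame"), inherits(tensor, "csa_tensor"),
            inherits(orient, "orientation"))
  S <- tensor_in_helix_frame(frame, tensor)
  b <- field_in_helix_frame(orient$tilt, orient$pitch)
  as.numeric(b %*% S %*% b)
}

# vectorised static shift over tilt/pitch vectors (matrix result)
static_shift_grid <- function(S, tilt_deg, pitch_deg) {
  t <- deg2rad(tilt_deg); p <- deg2rad(pitch_deg)
  st <- sin(t); ct <- cos(t)
  cp <- cos(p); sp <- sin(p)
  # outer grids: rows = tilt, cols = pitch
  bx <- -outer(st, cp); by <- outer(st, sp); bz <- matrix(ct, length(t), length(p))
  S[1, 1] * bx * bx + S[2, 2] * by * by + S[3, 3] * bz * bz +
    2 * (S[1, 2] * bx * by + S[1, 3] * bx * bz + S[2, 3] * by * bz)
}

# Gauss-Hermite nodes/weights scaled for a Gaussian with SD sd:
# E[f(X)] = sum w_i f(mu + sqrt(2) sd x_i) / sqrt(pi)
gh_rule <- function(sd, n_points) {
  if (sd == 0 || n_points == 1)
    return(list(offsets = 0, weights = 1))
  gh <- pracma::gaussHermite(n_points)
  list(offsets = sqrt(2) * sd * gh$x, weights = gh$w / sqrt(pi))
}

# motionally averaged shift surface over full tilt/pitch grids for one
# residue's helix-frame tensor S; quadrature over tilt wobble and
# azimuthal (pitch) fluctuation
averaged_shift_grid <- function(S, tilt_deg, pitch_deg, motion) {
  gw <- gh_rule(motion$wobble_sd, motion$n_points)
  ga <- gh_rule(motion$azimuth_sd, motion$n_points)
  acc <- matrix(0, length(tilt_deg), length(pitch_deg))
  for (j in seq_along(gw$offsets)) {
    for (k in seq_along(ga$offsets)) {
      acc <- acc + gw$weights[j] * ga$weights[k] *
        static_shift_grid(S, tilt_deg + gw$offsets[j],
                          pitch_deg + ga$offsets[k])
    }
  }
  acc
}

#' Motionally averaged oriented-sample chemical shift
#'
#' Gaussian-weighted mean of \code{\link{static_shift}} over independent
#' tilt wobble and azimuthal fluctuation about the helix long axis,
#' computed by two-dimensional Gauss-Hermite quadrature over the resonance
#' values (the shifts themselves are averaged, not the tensor components).
#' With both SDs zero this reduces exactly to the static shift.
#'
#' @inheritParams static_shift
#' @param motion a \code{\link{motion_model}}.
#' @return Averaged chemical shift in ppm.
#' @export
averaged_shift <- function(frame, tensor, orient, motion) {
  stopifnot(inherits(frame, "amide_frame"), inherits(tensor, "csa_tensor"),
            inherits(orient, "orientation"), inherits(motion, "motion_model"))
  S <- tensor_in_helix_frame(frame, tensor)
  as.numeric(averaged_shift_grid(S, orient$tilt, orient$pitch, motion))
}
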