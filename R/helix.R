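#' @importFrom stats sd optim rnorm setNames wilcox.test
#' @importFrom utils read.delim write.table head
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# rotation matrix about unit axis u by angle (radians), Rodrigues form
rot_axis <- function(u, theta) {
  u <- unitv(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# natural-extension reference frame: place atom d bonded to c with given
# internal coordinates relative to chain a-b-c
nerf_place <- function(a, b, c, bond, angle_deg, dihedral_deg) {
  ang <- deg2rad(angle_deg)
  dih <- deg2rad(dihedral_deg)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  bc <- unitv(c - b)
  n <- unitv(pracma::cross(b - a, bc))
  m <- cbind(bc, pracma::cross(n, bc), n)
  as.numeric(m %*% d_local + c)
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- unitv(p3 - p2); b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  rad2deg(atan2(sum(pracma::cross(b1, v) * w), sum(v * w)))
}

#' Build an ideal alpha-helix model
#'
#' Constructs a poly-peptide backbone (N, Calpha, C', O, amide H, plus a
#' single Cbeta direction per residue) from uniform backbone dihedrals by
#' internal-coordinate chain extension with fixed bond lengths and angles
#' (the \code{helix} block of \code{\link{memtopo_config}}). The helix axis
#' is fitted to the Calpha trace by a total-least-squares line fit and the
#' coordinates are re-expressed in a frame with the axis along +z (oriented
#' N- to C-terminus) and residue 1's Calpha-to-Cbeta projection defining
#' azimuth zero.
#'
#' @param sequence one-letter amino-acid string (length >= 4 for the axis
#'   fit to be defined).
#' @param phi,psi,omega backbone dihedrals in degrees; \code{omega}
#'   defaults to 180 (trans peptide bonds).
#' @param config configuration list; only the \code{helix} block's bond
#'   lengths/angles are used (the dihedral arguments take precedence).
#' @return An object of class \code{helix_model}: a list with
#'   \code{sequence}, \code{phi}, \code{psi}, \code{omega}, \code{coords}
#'   (a data frame of residue, atom, x, y, z in Angstrom),
#'   \code{twist_per_residue} and \code{rise_per_residue},
#'   \code{residues_per_turn}, and \code{residue_azimuth} (degrees in
#'   [0, 360), one per residue).
#' @examples
#' hm <- build_ideal_helix(strrep("A", 20), -65, -45)
#' hm$residues_per_turn
#' @export
build_ideal_helix <- function(sequence, phi = -65, psi = -45, omega = 180,
                              config = memtopo_config()) {
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) < 2) stop("sequence must have at least 2 residues")
  bad <- setdiff(res, AA1)
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  n_res <- length(res)
  g <- config$helix

  # chain extension: seed residue 1 in an arbitrary frame
  N <- CA <- C <- O <- H <- CB <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  # seed C' in the xy-plane at the N-CA-C angle
  ang <- deg2rad(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi)
      # amide H in the peptide plane, trans to the carbonyl O
      H[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                           g$b_n_h, g$a_c_n_h, 0)
    }
    CB[i, ] <- nerf_place(N[i, ], C[i, ], CA[i, ],
                          g$b_ca_cb, g$a_c_ca_cb, g$d_n_c_ca_cb)
  }
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the following amide nitrogen in the peptide plane
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi + 180)
  }

  if (n_res < 4)
    stop("axis-fit error: need >= 4 residues to define helix twist and rise")

  # Axis by total least squares on the Calpha second differences: for a
  # helix the vectors d_i = CA_{i+1} - CA_i have a constant component
  # along the axis, so the second differences e_i = d_{i+1} - d_i lie
  # exactly in the plane perpendicular to the axis; the axis is the null
  # direction of their TLS plane fit (smallest right singular vector).
  # A plain line fit through the CA trace suffers end effects for a
  # fractional number of turns; this fit is exact for an ideal helix.
  d <- diff(CA)
  e <- diff(d)
  sv <- svd(e)
  axis <- sv$v[, 3]
  if (sum(axis * (CA[n_res, ] - CA[1, ])) < 0) axis <- -axis
  ctr <- colMeans(CA)

  # rotate the axis onto +z
  z <- c(0, 0, 1)
  cr <- pracma::cross(axis, z)
  if (vnorm(cr) < 1e-12) {
    R <- if (sum(axis * z) > 0) diag(3) else rot_axis(c(1, 0, 0), pi)
  } else {
    R <- rot_axis(cr, acos(max(-1, min(1, sum(axis * z)))))
  }
  tf <- function(m) t(R %*% (t(m) - ctr))
  N <- tf(N); CA <- tf(CA); C <- tf(C); O <- tf(O); CB <- tf(CB)
  H[2:n_res, ] <- tf(H[2:n_res, , drop = FALSE])

  # azimuth of the Calpha -> Cbeta direction about the axis (z)
  side <- CB - CA
  azi_raw <- rad2deg(atan2(side[, 2], side[, 1]))
  # rotate about z so residue 1 is at azimuth 0
  Rz <- rot_axis(z, -deg2rad(azi_raw[1]))
  tf2 <- function(m) t(Rz %*% t(m))
  N <- tf2(N); CA <- tf2(CA); C <- tf2(C); O <- tf2(O); CB <- tf2(CB)
  H[2:n_res, ] <- tf2(H[2:n_res, , drop = FALSE])
  side <- CB - CA
  azimuth <- (rad2deg(atan2(side[, 2], side[, 1]))) %% 360
  azimuth[azimuth > 360 - 1e-9] <- 0

  # twist from the azimuthal progression of the side-chain directions
  # about the axis (the screw rotation advances it by exactly the twist
  # per residue), rise from the Calpha z progression
  dth <- diff(rad2deg(atan2(side[, 2], side[, 1]))) %% 360
  twist <- mean(dth)
  rise <- mean(diff(CA[, 3]))
  if (!(twist > 0) || !(rise > 0))
    stop("axis-fit error: degenerate twist/rise for this geometry")

  atoms <- c("N", "CA", "C", "O", "H", "CB")
  coords <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    m <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ], H[i, ], CB[i, ])
    data.frame(residue = i, residue_type = res[i], atom = atoms,
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  coords <- coords[!(coords$atom == "H" & coords$residue == 1), ]
  rownames(coords) <- NULL

  structure(list(
    sequence = paste(res, collapse = ""),
    phi = phi, psi = psi, omega = omega,
    coords = coords,
    twist_per_residue = twist,
    rise_per_residue = rise,
    residues_per_turn = 360 / twist,
    residue_azimuth = azimuth
  ), class = "helix_model")
}

#' @export
print.helix_model <- function(x, ...) {
  cat("Ideal helix model:", nchar(x$sequence), "residues\n")
  cat(sprintf("  phi/psi/omega: %.1f / %.1f / %.1f deg\n",
              x$phi, x$psi, x$omega))
  cat(sprintf("  twist %.2f deg/residue, rise %.2f A, %.2f residues/turn\n",
              x$twist_per_residue, x$rise_per_residue, x$residues_per_turn))
  invisible(x)
}

helix_atom <- function(model, residue, atom) {
  co <- model$coords
  row <- co[co$residue == residue & co$atom == atom, ]
  if (nrow(row) != 1) stop("atom ", atom, " of residue ", residue,
                           " not present in model")
  as.numeric(row[, c("x", "y", "z")])
}

#' Per-residue azimuths about the helix axis
#'
#' The azimuth of residue i is the angle (degrees, in [0, 360)) of its
#' Calpha-to-Cbeta direction projected onto the plane perpendicular to the
#' helix axis, measured from residue 1's direction. Consecutive azimuths
#' differ by the helix twist per residue (mod 360).
#'
#' @param model a \code{helix_model}.
#' @return Data frame with columns \code{residue} and \code{azimuth_deg}.
#' @export
residue_azimuths <- function(model) {
  stopifnot(inherits(model, "helix_model"))
  data.frame(residue = seq_along(model$residue_azimuth),
             azimuth_deg = model$residue_azimuth)
}

#' Helical wheel projection
#'
#' Projects a sequence onto a helical wheel: residue i sits at angle
#' (i - 1) * 360 / residues_per_turn (mod 360). Residues are classified as
#' cationic (K, R), polar (H, Q, N, S, T, Y, C, D, E, G) or apolar
#' (L, V, I, F, M, A, W, P). Tryptophan is grouped with the apolar face
#' (interfacial aromatic) and tyrosine with the polar face (hydroxyl);
#' glycine is grouped as polar by lack of a side chain.
#'
#' @param sequence one-letter amino-acid string.
#' @param residues_per_turn helical periodicity (> 2), default 3.6.
#' @return Data frame with \code{residue}, \code{residue_type},
#'   \code{angle_deg}, \code{polarity} (cationic/polar/apolar).
#' @export
helical_wheel <- function(sequence, residues_per_turn = 3.6) {
  stopifnot(residues_per_turn > 2)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, AA1)
  if (length(bad) > 0)
    stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
  ang <- ((seq_along(res) - 1) * 360 / residues_per_turn) %% 360
  cls <- ifelse(res %in% c("K", "R"), "cationic",
         ifelse(res %in% c("H", "Q", "N", "S", "T", "Y", "C", "D", "E", "G"),
                "polar", "apolar"))
  data.frame(residue = seq_along(res), residue_type = res,
             angle_deg = ang, polarity = cls)
}

#' Minimal arc containing a set of wheel angles
#'
#' Width (degrees) of the smallest circular arc containing all given
#' angles; used to quantify the segregation of the cationic face on a
#' helical wheel.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return Arc width in degrees (0 for a single angle).
#' @export
min_arc_width <- function(angles_deg) {
  a <- sort(angles_deg %% 360)
  if (length(a) < 2) return(0)
  gaps <- diff(c(a, a[1] + 360))
  360 - max(gaps)
}

#' Amide frame of a residue
#'
#' Right-handed orthonormal triad attached to a residue's amide group:
#' \code{nh_unit} along N to H, \code{in_plane_perp} in the peptide plane
#' perpendicular to N-H and pointing towards the preceding carbonyl
#' carbon (so rotating from N-H towards it by a positive angle moves
#' towards the N-C' bond), and \code{plane_normal} = nh x in_plane_perp
#' normal to the peptide plane. This is the frame in which the amide
#' \eqn{^{15}}N CSA tensor is expressed.
#'
#' @param model a \code{helix_model}.
#' @param residue 1-based residue index (>= 2; residue 1 has no amide H).
#' @return List with \code{residue}, \code{origin} (N position, Angstrom),
#'   \code{nh_unit}, \code{plane_normal}, \code{in_plane_perp}.
#' @export
amide_frame <- function(model, residue) {
  stopifnot(inherits(model, "helix_model"))
  if (residue < 2) stop("residue 1 has no amide proton")
  n <- helix_atom(model, residue, "N")
  h <- helix_atom(model, residue, "H")
  cprev <- helix_atom(model, residue - 1, "C")
  nh <- unitv(h - n)
  # in-plane perpendicular chosen to point towards the preceding
  # carbonyl carbon, so a positive rotation from N-H by beta moves
  # towards the N-C' bond (the standard amide 15N sigma33 orientation)
  nc <- cprev - n
  ip <- unitv(nc - sum(nc * nh) * nh)
  pn <- pracma::cross(nh, ip)
  structure(list(residue = residue, origin = n, nh_unit = nh,
                 plane_normal = pn, in_plane_perp = ip),
            class = "amide_frame")
}

#' Write a helix model as a minimal PDB file
#'
#' Backbone-only ATOM records (N, CA, C, O, H, CB) in the model's frame
#' (z = helix axis), for visual inspection in a molecular viewer.
#'
#' @param model a \code{helix_model}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_helix_pdb <- function(model, path) {
  stopifnot(inherits(model, "helix_model"))
  co <- model$coords
  aa3 <- setNames(
    c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
      "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"),
    AA1)
  lines <- vapply(seq_len(nrow(co)), function(k) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            k, substr(co$atom[k], 1, 4), aa3[[co$residue_type[k]]],
            co$residue[k], co$x[k], co$y[k], co$z[k],
            substr(co$atom[k], 1, 1))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
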