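#' Default analysis configuration
#'
#' Returns the fully resolved configuration used across the pipeline:
#' the amide \eqn{^{15}}N CSA tensor, the motional model, the ideal-helix
#' backbone geometry, and the per-analysis thresholds. Every run summary
#' echoes this structure so results carry their full parameter provenance.
#'
#' @details
#' Blocks and defaults:
#' \describe{
#'   \item{tensor}{\code{sigma11, sigma22, sigma33} = 57, 81, 227 ppm and
#'     \code{beta_nh} = 17 degrees (angle between the sigma33 axis and the
#'     N--H bond, sigma33 in the peptide plane, sigma22 perpendicular to
#'     it) — standard amide \eqn{^{15}}N literature values.}
#'   \item{motion}{\code{wobble_sd} = 10 degrees (Gaussian SD of the tilt
#'     fluctuation), \code{azimuth_sd} = 18 degrees (Gaussian SD of
#'     rotation about the helix long axis), \code{n_points} = 21
#'     Gauss--Hermite nodes per dimension.}
#'   \item{helix}{\code{phi} = -65, \code{psi} = -45, \code{omega} = 180
#'     degrees plus fixed backbone bond lengths/angles (see
#'     \code{\link{build_ideal_helix}}).}
#'   \item{topology}{\code{grid_step} = 1 degree, \code{min_area} = 3
#'     cells, tilt bounds for classification: in-plane [75, 105],
#'     transmembrane [0, 30] or [150, 180] degrees.}
#'   \item{csd}{helix-call thresholds 0.1 ppm (Halpha) and 0.7 ppm
#'     (Calpha), minimum run length 4 residues.}
#'   \item{scd}{static quadrupole coupling constant \code{qcc} = 167 kHz.}
#' }
#'
#' @param overrides optional named list of blocks to merge over the
#'   defaults (unknown block or key names are an error).
#' @return Nested list of configuration blocks.
#' @export
memtopo_config <- function(overrides = NULL) {
  cfg <- list(
    tensor = list(sigma11 = 57, sigma22 = 81, sigma33 = 227, beta_nh = 17),
    motion = list(wobble_sd = 10, azimuth_sd = 18, n_points = 21),
    helix = list(
      phi = -65, psi = -45, omega = 180,
      # backbone internal coordinates (Angstrom, degrees)
      b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
      b_c_o = 1.231, b_n_h = 1.02, b_ca_cb = 1.53,
      a_n_ca_c = 111.0, a_ca_c_n = 117.2, a_c_n_ca = 121.7,
      a_ca_c_o = 120.5, a_c_n_h = 119.0,
      a_c_ca_cb = 110.1, d_n_c_ca_cb = 122.6
    ),
    topology = list(
      grid_step = 1, min_area = 3,
      in_plane_tilt = c(75, 105), transmembrane_tilt = 30
    ),
    csd = list(h_threshold = 0.1, c_threshold = 0.7, min_run = 4),
    scd = list(qcc = 167)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (blk in names(overrides)) {
      if (!blk %in% names(cfg))
        stop("unknown config block: ", blk)
      for (key in names(overrides[[blk]])) {
        if (!key %in% names(cfg[[blk]]))
          stop("unknown config key: ", blk, "$", key)
        cfg[[blk]][[key]] <- overrides[[blk]][[key]]
      }
    }
  }
  cfg
}

#' Read a configuration file
#'
#' Reads a YAML configuration file and merges it over the package defaults.
#' Unknown blocks or keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param path path to a YAML file whose top-level keys are config blocks.
#' @return Nested list as from \code{\link{memtopo_config}}.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  memtopo_config(yaml::read_yaml(path))
}
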