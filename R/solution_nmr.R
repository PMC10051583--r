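#' Random-coil reference chemical shifts
#'
#' Static per-residue random-coil reference shifts for Halpha and Calpha
#' (ppm), Wishart-style consensus values for short unstructured peptides
#' in water near neutral pH. Embedded as a fixed table so chemical-shift
#' deviations are reproducible without any external predictor; absolute
#' deviations for a particular sample (pH, temperature, neighbors) may
#' differ by a few hundredths of a ppm from condition-corrected
#' predictions.
#'
#' @return Data frame with columns \code{residue_type}, \code{HA},
#'   \code{CA} covering the 20 standard residues.
#' @export
random_coil_table <- function() {
  data.frame(
    residue_type = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                     "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
    HA = c(4.32, 4.34, 4.74, 4.64, 4.55, 4.34, 4.35, 3.96, 4.73, 4.17,
           4.34, 4.32, 4.48, 4.62, 4.42, 4.47, 4.35, 4.66, 4.55, 4.12),
    CA = c(52.5, 56.0, 52.8, 54.2, 58.2, 56.6, 56.6, 45.1, 55.0, 61.1,
           55.1, 56.2, 55.4, 58.0, 63.3, 58.3, 61.9, 57.5, 58.1, 62.2))
}

check_shift_table <- function(shifts) {
  need <- c("residue", "residue_type", "atom", "shift_ppm")
  miss <- setdiff(need, names(shifts))
  if (length(miss) > 0)
    stop("shift table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(shifts[, c("residue", "atom")]))
    stop("shift table has duplicate (residue, atom) entries")
  if (!all(is.finite(shifts$shift_ppm)))
    stop("shift table contains non-finite shifts")
  invisible(shifts)
}

#' Chemical shift deviations from random coil
#'
#' Per-residue secondary chemical shifts: observed minus the residue-type
#' random-coil reference, for Halpha and Calpha. Persistent negative
#' Halpha together with positive Calpha deviations are the canonical
#' signature of alpha-helix.
#'
#' @param shifts data frame with columns \code{residue},
#'   \code{residue_type}, \code{atom} (\code{"HA"}, \code{"CA"}, or
#'   \code{"HN"}; HN rows are ignored here), \code{shift_ppm}.
#' @param reference reference table as from \code{\link{random_coil_table}}.
#' @return Data frame with \code{residue}, \code{residue_type},
#'   \code{d_ha} and \code{d_ca} (ppm; NA where the atom is unobserved).
#' @export
chemical_shift_deviation <- function(shifts, reference = random_coil_table()) {
  check_shift_table(shifts)
  sub <- shifts[shifts$atom %in% c("HA", "CA"), ]
  unknown <- setdiff(unique(sub$residue_type), reference$residue_type)
  if (length(unknown) > 0)
    stop("no random-coil reference for residue type(s): ",
         paste(unknown, collapse = ", "))
  residues <- sort(unique(sub$residue))
  out <- data.frame(residue = residues,
                    residue_type = sub$residue_type[
                      match(residues, sub$residue)],
                    d_ha = NA_real_, d_ca = NA_real_)
  for (k in seq_len(nrow(sub))) {
    i <- match(sub$residue[k], residues)
    ref <- reference[match(sub$residue_type[k], reference$residue_type), ]
    col <- if (sub$atom[k] == "HA") "d_ha" else "d_ca"
    refv <- if (sub$atom[k] == "HA") ref$HA else ref$CA
    out[[col]][i] <- sub$shift_ppm[k] - refv
  }
  out
}

#' Call secondary structure from chemical shift deviations
#'
#' A residue supports helix when its Halpha deviation is at or below
#' \code{-h_threshold} or its Calpha deviation at or above
#' \code{+c_threshold}; when both atoms are observed the two criteria
#' must agree in direction (neither may point the opposite way beyond its
#' threshold). Helix segments are maximal runs of at least \code{min_run}
#' consecutive supporting residues.
#'
#' @param deviations output of \code{\link{chemical_shift_deviation}}.
#' @param h_threshold Halpha threshold in ppm (default 0.1).
#' @param c_threshold Calpha threshold in ppm (default 0.7).
#' @param min_run minimum helix segment length in residues (default 4).
#' @return List with \code{state} (data frame: residue, supporting,
#'   state helix/coil) and \code{segments} (data frame: start, end,
#'   length).
#' @export
call_secondary_structure <- function(deviations, h_threshold = 0.1,
                                     c_threshold = 0.7, min_run = 4) {
  stopifnot(h_threshold > 0, c_threshold > 0, min_run >= 1)
  deviations <- deviations[order(deviations$residue), ]
  ha_helix <- !is.na(deviations$d_ha) & deviations$d_ha <= -h_threshold
  ca_helix <- !is.na(deviations$d_ca) & deviations$d_ca >= c_threshold
  ha_anti <- !is.na(deviations$d_ha) & deviations$d_ha >= h_threshold
  ca_anti <- !is.na(deviations$d_ca) & deviations$d_ca <= -c_threshold
  supporting <- (ha_helix | ca_helix) & !ha_anti & !ca_anti
  r <- rle(supporting)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  segments <- data.frame(
    start = deviations$residue[starts[keep]],
    end = deviations$residue[ends[keep]])
  segments$length <- segments$end - segments$start + 1
  in_seg <- rep(FALSE, nrow(deviations))
  for (k in seq_len(nrow(segments)))
    in_seg[deviations$residue >= segments$start[k] &
           deviations$residue <= segments$end[k]] <- TRUE
  list(state = data.frame(residue = deviations$residue,
                          supporting = supporting,
                          state = ifelse(in_seg, "helix", "coil")),
       segments = segments)
}

#' Amide proton dispersion
#'
#' The spread (max minus min, ppm) of the amide HN chemical shifts — a
#' coarse indicator of structure: random coils give narrow dispersion,
#' well-formed helices a wider one.
#'
#' @param shifts shift table as in \code{\link{chemical_shift_deviation}}.
#' @param atom atom name to use (default \code{"HN"}).
#' @return Dispersion in ppm.
#' @export
amide_dispersion <- function(shifts, atom = "HN") {
  check_shift_table(shifts)
  v <- shifts$shift_ppm[shifts$atom == atom]
  if (length(v) < 2)
    stop("need at least 2 ", atom, " shifts to compute a dispersion")
  max(v) - min(v)
}

#' Paramagnetic percentage loss with linear error propagation
#'
#' For each residue, the percentage loss of cross-peak intensity upon
#' addition of the paramagnetic agent: with B the intensity without and C
#' the intensity with the agent, the retained fraction is A = C/B, the
#' loss is 100 (1 - A), and the error on the loss follows the linear
#' propagation dA = A (dB/B + dC/C) applied to the spectral-noise
#' estimates. Negative losses (C > B) are reported as-is and flagged.
#'
#' @param pre data frame with columns \code{residue},
#'   \code{intensity_ref} (B > 0), \code{intensity_para} (C >= 0),
#'   \code{noise_ref} (dB >= 0), \code{noise_para} (dC >= 0).
#' @return Data frame with \code{residue}, \code{loss_pct},
#'   \code{loss_err_pct}, \code{flag_negative}.
#' @export
pre_attenuation <- function(pre) {
  need <- c("residue", "intensity_ref", "intensity_para",
            "noise_ref", "noise_para")
  miss <- setdiff(need, names(pre))
  if (length(miss) > 0)
    stop("PRE table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(pre$intensity_ref <= 0))
    stop("reference intensities must be > 0")
  if (any(pre$intensity_para < 0) || any(pre$noise_ref < 0) ||
      any(pre$noise_para < 0))
    stop("paramagnetic intensities and noise estimates must be >= 0")
  A <- pre$intensity_para / pre$intensity_ref
  loss <- 100 * (1 - A)
  err <- 100 * A * (pre$noise_ref / pre$intensity_ref +
                    ifelse(pre$intensity_para > 0,
                           pre$noise_para / pre$intensity_para, 0))
  data.frame(residue = pre$residue, loss_pct = loss, loss_err_pct = err,
             flag_negative = loss < 0)
}

#' Fit the helical periodicity of a per-residue profile
#'
#' Fits loss_i = offset + amplitude * cos(2 pi (i - i0) / period) by
#' nonlinear least squares. The period is seeded from a grid over
#' [3.0, 4.5] residues in 0.05 steps (at each candidate period the
#' remaining parameters are solved linearly) and the best seed is refined
#' by quasi-Newton optimisation. When the fitted amplitude is not
#' distinguishable from zero (amplitude < 2 x residual SD) the profile is
#' flagged aperiodic and the period is NA.
#'
#' @param profile data frame with columns \code{residue} and
#'   \code{loss_pct} (at least 8 finite values), or a numeric vector
#'   indexed by residue.
#' @param period_range,period_step seeding grid for the period, in
#'   residues.
#' @return List with \code{period} (residues per turn), \code{phase_deg},
#'   \code{amplitude}, \code{offset}, \code{rss}, \code{residual_sd},
#'   \code{periodic} (logical flag).
#' @export
fit_periodicity <- function(profile, period_range = c(3.0, 4.5),
                            period_step = 0.05) {
  if (is.numeric(profile))
    profile <- data.frame(residue = seq_along(profile), loss_pct = profile)
  ok <- is.finite(profile$loss_pct)
  i <- profile$residue[ok]; y <- profile$loss_pct[ok]
  if (length(y) < 8)
    stop("need at least 8 residues with finite values to fit a period")

  sse_linfit <- function(P) {
    X <- cbind(1, cos(2 * pi * i / P), sin(2 * pi * i / P))
    fit <- stats::lm.fit(X, y)
    list(sse = sum(fit$residuals^2), coef = fit$coefficients)
  }
  grid <- seq(period_range[1], period_range[2], by = period_step)
  sses <- vapply(grid, function(P) sse_linfit(P)$sse, 0)
  P0 <- grid[which.min(sses)]
  cf <- sse_linfit(P0)$coef
  # refine (offset, cos-coef, sin-coef, period) jointly
  obj <- function(par) {
    P <- par[4]
    if (P < 2 || P > 10) return(1e12)
    sum((y - (par[1] + par[2] * cos(2 * pi * i / P) +
              par[3] * sin(2 * pi * i / P)))^2)
  }
  opt <- stats::optim(as.numeric(c(cf, P0)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  a <- opt$par[1]; b <- opt$par[2]; cc <- opt$par[3]; P <- opt$par[4]
  amp <- sqrt(b^2 + cc^2)
  dof <- max(length(y) - 4, 1)
  rsd <- sqrt(opt$value / dof)
  # amplitude must beat the residual noise and be non-negligible on the
  # scale of the data (guards the exactly-constant profile, rsd = 0)
  periodic <- amp >= 2 * rsd && amp > 1e-6 * (1 + abs(a) + sd(y))
  # phase: residue index of a cosine maximum, expressed in degrees
  phase <- (rad2deg(atan2(cc, b))) %% 360
  list(period = if (periodic) P else NA_real_,
       phase_deg = if (periodic) phase else NA_real_,
       amplitude = amp, offset = a, rss = opt$value,
       residual_sd = rsd, periodic = periodic)
}

#' Cationic residue positions of a sequence
#'
#' @param sequence one-letter amino-acid string.
#' @return Integer vector of 1-based positions of K and R.
#' @export
cationic_positions <- function(sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  which(res %in% c("K", "R"))
}

#' Compare paramagnetic attenuation between helix faces
#'
#' Splits the per-residue loss profile into cationic (K/R) and other
#' residues and tests whether the cationic face is less attenuated (the
#' signature of an amphipathic helix lying on the membrane surface with
#' its apolar face buried): group means, their difference, and a
#' one-sided rank-sum (Wilcoxon) p-value for cationic < other.
#'
#' @param profile data frame with columns \code{residue} and
#'   \code{loss_pct}.
#' @param sequence one-letter amino-acid string defining the cationic set.
#' @return List with \code{mean_cationic}, \code{mean_other},
#'   \code{difference} (cationic minus other), \code{p_value},
#'   \code{n_cationic}, \code{n_other}.
#' @export
classify_faces <- function(profile, sequence) {
  cat_pos <- cationic_positions(sequence)
  is_cat <- profile$residue %in% cat_pos
  x <- profile$loss_pct[is_cat]
  y <- profile$loss_pct[!is_cat]
  if (length(x) == 0 || length(y) == 0)
    stop("both the cationic and the other group must be non-empty")
  if (all(x == x[1]) && all(y == x[1])) {
    p <- 1
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, alternative = "less", exact = NULL)$p.value)
  }
  list(mean_cationic = mean(x), mean_other = mean(y),
       difference = mean(x) - mean(y), p_value = p,
       n_cationic = length(x), n_other = length(y))
}
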