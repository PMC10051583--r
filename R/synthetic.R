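# evaluate expr with a locally set RNG seed, restoring the global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic chemical-shift table
#'
#' Emulates an assigned solution-NMR shift table for a peptide:
#' \describe{
#'   \item{coil}{random-coil reference values plus Gaussian noise
#'     (SD 0.02 ppm for Halpha, 0.1 ppm for Calpha).}
#'   \item{helix}{adds the canonical helical deviations (Halpha -0.25
#'     ppm, Calpha +2.0 ppm) over the helix span.}
#'   \item{helix_with_pro_break}{as \code{helix}, with the deviation
#'     zeroed at one break residue (a proline-like helix breaker).}
#' }
#' Amide HN shifts are also emitted: around 8.3 ppm with small noise for
#' coil residues, plus a helical-periodicity modulation (amplitude 0.45
#' ppm) over the helix span, so helical tables show the larger amide
#' dispersion seen for structured peptides.
#'
#' @param scenario one of \code{"coil"}, \code{"helix"},
#'   \code{"helix_with_pro_break"}.
#' @param seed integer RNG seed; fixes the output bit-exactly.
#' @param sequence one-letter amino-acid string (default SAAP-148).
#' @param helix_span length-2 residue range of the true helix.
#' @param break_residue residue whose deviation is zeroed in the
#'   \code{helix_with_pro_break} scenario.
#' @param noise_ha,noise_ca,noise_hn Gaussian noise SDs in ppm.
#' @return List with \code{data} (shift table: residue, residue_type,
#'   atom, shift_ppm) and \code{ground_truth} (scenario, helix span,
#'   break residue).
#' @export
gen_shift_table <- function(scenario = c("helix_with_pro_break", "helix",
                                         "coil"),
                            seed = 1, sequence = SAAP148,
                            helix_span = c(1, 21), break_residue = 22,
                            noise_ha = 0.02, noise_ca = 0.1,
                            noise_hn = 0.05) {
  scenario <- match.arg(scenario)
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  ref <- random_coil_table()
  ri <- match(res, ref$residue_type)
  if (anyNA(ri)) stop("sequence contains unknown residue codes")
  with_seed(seed, {
    in_helix <- rep(FALSE, n)
    if (scenario != "coil")
      in_helix[helix_span[1]:helix_span[2]] <- TRUE
    if (scenario == "helix_with_pro_break")
      in_helix[break_residue] <- FALSE
    d_ha <- ifelse(in_helix, -0.25, 0)
    d_ca <- ifelse(in_helix, 2.0, 0)
    ha <- ref$HA[ri] + d_ha + rnorm(n, 0, noise_ha)
    ca <- ref$CA[ri] + d_ca + rnorm(n, 0, noise_ca)
    hn <- 8.3 + ifelse(in_helix,
                       0.45 * cos(2 * pi * seq_len(n) / 3.6), 0) +
      rnorm(n, 0, noise_hn)
    data <- rbind(
      data.frame(residue = seq_len(n), residue_type = res, atom = "HA",
                 shift_ppm = ha),
      data.frame(residue = seq_len(n), residue_type = res, atom = "CA",
                 shift_ppm = ca),
      data.frame(residue = seq_len(n)[res != "P"],
                 residue_type = res[res != "P"], atom = "HN",
                 shift_ppm = hn[res != "P"]))
    list(data = data,
         ground_truth = list(scenario = scenario,
                             helix_span = if (scenario == "coil") NULL
                                          else helix_span,
                             break_residue = if (scenario ==
                                                 "helix_with_pro_break")
                               break_residue else NULL))
  })
}

#' Generate a synthetic paramagnetic attenuation table
#'
#' Emulates the per-residue percentage intensity loss measured upon
#' addition of a micelle-core paramagnetic agent for a surface-lying
#' amphipathic helix: loss_i = offset + amp cos(2 pi (i - i0) / period),
#' with the loss of cationic (K/R) residues multiplied by
#' \code{cationic_factor} < 1 (the charged face points away from the
#' micelle core) and Gaussian noise added. Intensities are back-computed
#' with the reference intensity fixed at \code{b_ref} and
#' C = B (1 - loss/100); the noise columns carry the spectral-noise
#' equivalent of the loss noise.
#'
#' @param seed integer RNG seed.
#' @param sequence one-letter amino-acid string (default SAAP-148).
#' @param period true helical periodicity in residues (default 3.6).
#' @param amp,offset cosine amplitude and mean loss, percent.
#' @param i0 residue index of a loss maximum (apolar-face reference).
#' @param cationic_factor multiplicative reduction of the loss on K/R
#'   residues (1 = none).
#' @param noise_sd Gaussian noise SD on the loss, percent (default 3,
#'   i.e. 10 percent of the default amplitude).
#' @param b_ref reference cross-peak intensity.
#' @return List with \code{data} (PRE table: residue, intensity_ref,
#'   intensity_para, noise_ref, noise_para) and \code{ground_truth}
#'   (period, phase residue, amplitude, offset, cationic factor).
#' @export
gen_pre_profile <- function(seed = 1, sequence = SAAP148, period = 3.6,
                            amp = 30, offset = 50, i0 = 1,
                            cationic_factor = 0.7, noise_sd = 3,
                            b_ref = 100) {
  res <- strsplit(toupper(sequence), "")[[1]]
  n <- length(res)
  cat_pos <- cationic_positions(sequence)
  with_seed(seed, {
    loss <- offset + amp * cos(2 * pi * (seq_len(n) - i0) / period)
    loss[cat_pos] <- loss[cat_pos] * cationic_factor
    loss <- loss + rnorm(n, 0, noise_sd)
    loss <- pmin(loss, 99.5)  # keep paramagnetic intensities positive
    C <- b_ref * (1 - loss / 100)
    noise_i <- b_ref * noise_sd / 100
    data <- data.frame(residue = seq_len(n), intensity_ref = b_ref,
                       intensity_para = C, noise_ref = noise_i,
                       noise_para = noise_i)
    list(data = data,
         ground_truth = list(period = period, i0 = i0, amplitude = amp,
                             offset = offset,
                             cationic_factor = cationic_factor,
                             cationic_positions = cat_pos))
  })
}

#' Generate synthetic 15N orientational restraints
#'
#' Forward-computes the motionally averaged oriented-sample \eqn{^{15}}N
#' shift of the requested residues at a known (tilt, pitch) ground truth
#' and perturbs each by Gaussian noise with SD equal to half its
#' acceptance half-width, emulating measured restraints whose true
#' orientation should be recovered by the restriction analysis.
#'
#' @param seed integer RNG seed.
#' @param model a \code{\link{build_ideal_helix}} model.
#' @param tilt,pitch true orientation in degrees (defaults 90, 130 — an
#'   in-plane helix).
#' @param residues labeled residue indices (default 11 and 12).
#' @param errors acceptance half-widths in ppm, one per residue
#'   (default 2.5 and 4.0).
#' @param tensor a \code{\link{csa_tensor}}.
#' @param motion a \code{\link{motion_model}}.
#' @return List with \code{restraints} (list of
#'   \code{\link{shift_restraint}}) and \code{ground_truth}
#'   (the true \code{\link{orientation}} and noiseless shifts).
#' @export
gen_15n_restraints <- function(seed = 1, model = NULL, tilt = 90,
                               pitch = 130, residues = c(11, 12),
                               errors = c(2.5, 4.0),
                               tensor = csa_tensor(),
                               motion = motion_model()) {
  stopifnot(length(residues) >= 1, length(errors) == length(residues))
  if (is.null(model)) model <- build_ideal_helix(SAAP148, -65, -45)
  truth <- orientation(tilt, pitch)
  clean <- vapply(residues, function(r)
    averaged_shift(amide_frame(model, r), tensor, truth, motion), 0)
  with_seed(seed, {
    obs <- clean + rnorm(length(residues), 0, errors / 2)
    restraints <- mapply(shift_restraint, residues, obs, errors,
                         SIMPLIFY = FALSE)
    list(restraints = restraints,
         ground_truth = list(orientation = truth, clean_shifts = clean,
                             residues = residues))
  })
}

#' Generate synthetic acyl-chain splitting tables
#'
#' Emulates deuterium quadrupolar splittings of a perdeuterated palmitoyl
#' chain (carbons 2-16) with and without a bound peptide: the unperturbed
#' profile is an order-parameter plateau (S_CD = \code{plateau}) over
#' carbons 2 to \code{plateau_end}, decaying linearly to \code{tail} at
#' the terminal carbon; the with-peptide profile is multiplied by a
#' linear reduction ramp rising from no reduction at carbon 2 to
#' \code{max_reduction} at the terminal carbon (peptide insertion
#' perturbs the chain ends most). Splittings are obtained via
#' \code{\link{splitting_from_scd}}; optional Gaussian noise (kHz) is
#' added to the splittings.
#'
#' @param seed integer RNG seed (only used when \code{noise_sd > 0}).
#' @param carbons carbon indices (default 2:16, palmitoyl-d31).
#' @param plateau,tail order-parameter plateau and terminal values.
#' @param plateau_end last carbon of the plateau (default 8).
#' @param max_reduction maximal fractional reduction at the terminal
#'   carbon (default 0.30).
#' @param noise_sd Gaussian noise SD on the splittings, kHz (default 0).
#' @param qcc static quadrupole coupling constant in kHz.
#' @return List with \code{data} (splitting table, both conditions) and
#'   \code{ground_truth} (profiles and the reduction ramp).
#' @export
gen_scd_tables <- function(seed = 1, carbons = 2:16, plateau = 0.20,
                           tail = 0.05, plateau_end = 8,
                           max_reduction = 0.30, noise_sd = 0, qcc = 167) {
  stopifnot(max_reduction >= 0, max_reduction < 1)
  nc <- length(carbons)
  last <- max(carbons)
  scd_wo <- ifelse(carbons <= plateau_end, plateau,
                   plateau + (tail - plateau) *
                     (carbons - plateau_end) / (last - plateau_end))
  ramp <- (carbons - min(carbons)) / (last - min(carbons))
  scd_w <- scd_wo * (1 - max_reduction * ramp)
  tab_wo <- simulate_splittings(scd_wo, carbons, "without_peptide", qcc)
  tab_w <- simulate_splittings(scd_w, carbons, "with_peptide", qcc)
  data <- rbind(tab_wo, tab_w)
  if (noise_sd > 0) {
    data$splitting_khz <- with_seed(seed,
      pmax(0, data$splitting_khz + rnorm(nrow(data), 0, noise_sd)))
  }
  list(data = data,
       ground_truth = list(scd_without = scd_wo, scd_with = scd_w,
                           carbons = carbons,
                           max_reduction = max_reduction,
                           reduction_ramp = ramp))
}
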