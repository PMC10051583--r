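#' Order parameter from a quadrupolar splitting
#'
#' Converts a deuterium quadrupolar splitting of a lipid C-D bond into
#' the segmental order parameter S_CD = (4/3) * splitting / QCC, where
#' QCC is the static quadrupole coupling constant of deuterons in C-D
#' bonds (167 kHz by default). S_CD is 0 for isotropic motion and 1 for
#' a bond fully ordered along the reference axis.
#'
#' @param splitting quadrupolar splitting(s) in kHz (>= 0).
#' @param qcc static quadrupole coupling constant in kHz (> 0).
#' @return S_CD value(s), dimensionless in [0, 1].
#' @examples
#' scd_from_splitting(50)          # ~0.399
#' @export
scd_from_splitting <- function(splitting, qcc = 167) {
  stopifnot(qcc > 0)
  if (any(splitting < 0)) stop("splittings must be >= 0")
  s <- (4 / 3) * splitting / qcc
  if (any(s > 1))
    stop("out-of-range error: splitting implies S_CD > 1 ",
         "(unphysical for a C-D bond)")
  s
}

#' Splitting from an order parameter
#'
#' Inverse of \code{\link{scd_from_splitting}}:
#' splitting = (3/4) * QCC * S_CD. Round-trips to machine precision.
#'
#' @param scd order parameter(s) in [0, 1].
#' @param qcc static quadrupole coupling constant in kHz (> 0).
#' @return Splitting(s) in kHz.
#' @export
splitting_from_scd <- function(scd, qcc = 167) {
  stopifnot(qcc > 0)
  if (any(scd < 0 | scd > 1)) stop("S_CD values must lie in [0, 1]")
  (3 / 4) * qcc * scd
}

check_splitting_table <- function(table) {
  need <- c("carbon", "group", "splitting_khz", "condition")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    stop("splitting table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(table) > 0) {
    if (any(table$splitting_khz < 0)) stop("splittings must be >= 0")
    if (!all(table$condition %in% c("with_peptide", "without_peptide")))
      stop("condition must be 'with_peptide' or 'without_peptide'")
    if (anyDuplicated(table[, c("carbon", "condition")]))
      stop("duplicate (carbon, condition) entries in splitting table")
  }
  invisible(table)
}

#' Acyl-chain order-parameter profile
#'
#' Converts a per-carbon quadrupolar-splitting table (for a
#' perdeuterated acyl chain, e.g. palmitoyl-d31, carbons 2-16) into
#' S_CD profiles per condition (with/without peptide). CD3 terminal
#' groups are converted with the same relation as CD2 groups (no 3-fold
#' correction is applied).
#'
#' @param table data frame with columns \code{carbon}, \code{group}
#'   (\code{"CD2"}/\code{"CD3"}), \code{splitting_khz}, \code{condition}
#'   (\code{"with_peptide"}/\code{"without_peptide"}); an optional
#'   \code{lipid} column is carried through.
#' @param qcc static quadrupole coupling constant in kHz.
#' @return Object of class \code{scd_profile}: data frame with
#'   \code{carbon}, \code{group}, \code{condition}, \code{scd}, sorted by
#'   condition then carbon.
#' @export
build_profile <- function(table, qcc = 167) {
  check_splitting_table(table)
  if (nrow(table) == 0) {
    out <- data.frame(carbon = integer(), group = character(),
                      condition = character(), scd = numeric())
    return(structure(out, class = c("scd_profile", "data.frame")))
  }
  out <- data.frame(carbon = table$carbon, group = table$group,
                    condition = table$condition,
                    scd = scd_from_splitting(table$splitting_khz, qcc))
  out <- out[order(out$condition, out$carbon), ]
  rownames(out) <- NULL
  structure(out, class = c("scd_profile", "data.frame"))
}

#' With/without-peptide order-parameter ratios
#'
#' For every carbon present in both conditions, the ratio
#' S_CD(with peptide) / S_CD(without peptide) and the corresponding
#' percentage reduction 100 (1 - ratio); summarises the maximum
#' reduction and the carbon where it occurs. Carbons with
#' S_CD(without) = 0 are flagged and excluded from the summary.
#'
#' @param profile an \code{scd_profile} containing both conditions for at
#'   least one carbon.
#' @return List with \code{ratios} (data frame: carbon, scd_with,
#'   scd_without, ratio, reduction_pct, flag_undefined) and
#'   \code{max_reduction_pct}, \code{max_reduction_carbon}.
#' @export
profile_ratio <- function(profile) {
  w <- profile[profile$condition == "with_peptide", ]
  wo <- profile[profile$condition == "without_peptide", ]
  common <- intersect(w$carbon, wo$carbon)
  if (length(common) == 0)
    stop("need both conditions for at least one carbon")
  common <- sort(common)
  sw <- w$scd[match(common, w$carbon)]
  swo <- wo$scd[match(common, wo$carbon)]
  undef <- swo == 0
  ratio <- ifelse(undef, NA_real_, sw / swo)
  red <- 100 * (1 - ratio)
  ratios <- data.frame(carbon = common, scd_with = sw, scd_without = swo,
                       ratio = ratio, reduction_pct = red,
                       flag_undefined = undef)
  if (all(undef)) {
    max_red <- NA_real_; max_carbon <- NA_integer_
  } else {
    k <- which.max(red)
    max_red <- red[k]; max_carbon <- common[k]
  }
  list(ratios = ratios, max_reduction_pct = max_red,
       max_reduction_carbon = max_carbon)
}

#' Simulate a splitting table from an order-parameter profile
#'
#' Builds the quadrupolar-splitting table a spectrometer would yield for
#' a given per-carbon S_CD profile (inverse of \code{\link{build_profile}});
#' used by the synthetic-data generators.
#'
#' @param scd numeric vector of order parameters in [0, 1], one per
#'   carbon.
#' @param carbons carbon indices (default 2..(length + 1), palmitoyl
#'   numbering; the terminal carbon is labeled CD3).
#' @param condition condition label for all rows.
#' @param qcc static quadrupole coupling constant in kHz.
#' @return Splitting table as accepted by \code{\link{build_profile}}.
#' @export
simulate_splittings <- function(scd, carbons = seq_along(scd) + 1,
                                condition = "without_peptide", qcc = 167) {
  stopifnot(length(scd) == length(carbons))
  data.frame(carbon = carbons,
             group = ifelse(carbons == max(carbons), "CD3", "CD2"),
             splitting_khz = splitting_from_scd(scd, qcc),
             condition = condition)
}
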