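# Biochemical unit conversions. TBARS reports lipid peroxidation as
# malondialdehyde (MDA) equivalents from background-corrected absorbance;
# LDH release is expressed as percent of the maximal signal after complete
# lysis with Triton X-100.

#' Construct a TBARS measurement
#'
#' Background-corrected absorbance (532 nm minus 600 nm) together with the
#' assay geometry needed for the Beer-Lambert conversion to MDA
#' equivalents.
#'
#' @param a532 Absorbance at 532 nm.
#' @param a600 Background absorbance at 600 nm.
#' @param path_length Optical path length in cm, `> 0`.
#' @param dilution_factor Homogenate dilution in the reaction, `>= 1`.
#'   Defaults to 10, the ratio implied by 100 uL homogenate in a 1000 uL
#'   reaction.
#' @param protein_g Total protein in the assayed volume (g), optional.
#' @param epsilon Molar absorptivity of the MDA-TBA adduct in
#'   mM^-1 cm^-1; default 156.
#' @return A list of class `"tbars_measurement"`.
#' @export
tbars_measurement <- function(a532, a600 = 0, path_length = 1,
                              dilution_factor = 10, protein_g = NULL,
                              epsilon = 156) {
  if (!is.numeric(path_length) || path_length <= 0)
    stop("'path_length' must be positive", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be positive", call. = FALSE)
  if (!is.numeric(dilution_factor) || any(dilution_factor < 1))
    stop("'dilution_factor' must be >= 1", call. = FALSE)
  structure(list(a532 = a532, a600 = a600, path_length = path_length,
                 dilution_factor = dilution_factor, protein_g = protein_g,
                 epsilon = epsilon),
            class = "tbars_measurement")
}

#' Convert TBARS absorbance to MDA concentration
#'
#' Beer-Lambert: `(a532 - a600) / (epsilon * path_length)` gives mM, the
#' factor 1000 converts to uM, and the dilution factor restores the
#' homogenate concentration. A negative delta-absorbance passes through
#' and yields a negative concentration; control-centered MDA values are
#' legitimately negative.
#'
#' @param m A [tbars_measurement()].
#' @return MDA concentration in uM (malondialdehyde equivalents);
#'   vectorized over the absorbances.
#' @examples
#' mda_concentration(tbars_measurement(0.156, 0, dilution_factor = 1)) # 1 uM
#' @export
mda_concentration <- function(m) {
  stopifnot(inherits(m, "tbars_measurement"))
  (m$a532 - m$a600) / (m$epsilon * m$path_length) * 1000 * m$dilution_factor
}

#' Normalize a concentration to total protein
#'
#' @param conc_um Concentration in uM.
#' @param protein_g Total protein in g, `> 0`.
#' @return Concentration in uM per g protein.
#' @export
normalize_to_protein <- function(conc_um, protein_g) {
  if (!is.numeric(protein_g) || any(protein_g <= 0))
    stop("'protein_g' must be positive", call. = FALSE)
  conc_um / protein_g
}

#' Center values on a batch control mean
#'
#' The documented normalization option that yields negative MDA values for
#' samples below the control mean: subtract the mean of the batch controls.
#'
#' @param values Numeric vector.
#' @param control_values Numeric vector of control measurements.
#' @return `values - mean(control_values)`.
#' @export
center_on_control <- function(values, control_values) {
  if (length(control_values) == 0L)
    stop("'control_values' must be non-empty", call. = FALSE)
  values - mean(control_values)
}

#' LDH release as percent of maximal lysis signal
#'
#' @param sample_rfu Sample fluorescence (RFU).
#' @param triton_max_rfu Maximal signal after complete Triton X-100 lysis,
#'   `> 0`.
#' @return `100 * sample_rfu / triton_max_rfu` (percent).
#' @examples
#' ldh_percent_of_max(4430, 11467)
#' @export
ldh_percent_of_max <- function(sample_rfu, triton_max_rfu) {
  if (!is.numeric(triton_max_rfu) || any(triton_max_rfu <= 0))
    stop("'triton_max_rfu' must be positive", call. = FALSE)
  100 * sample_rfu / triton_max_rfu
}
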