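# Canonical labels used throughout the package. Conditions: medium-only
# control, 200 uM heme-albumin, heme-hemopexin complex, cell-free
# hemoglobin, hemoglobin-haptoglobin complex. Readouts: tissue 58Fe burden
# (ICP-MS, ppb), normalized MDA (TBARS, uM per g protein), two
# transcriptional scores (arbitrary VST units), and the pseudocytometric
# neuronal cell-death fraction.

.conditions <- c("Ctrl", "HemeAlb", "HemeHpx", "Hb", "HbHp")
.readouts   <- c("fe58", "mda", "heme_stress", "heme_metab", "cell_death")

# Valid range per readout; truncated-normal sampling never leaves it.
.readout_ranges <- list(
  fe58        = c(0, Inf),
  mda         = c(-Inf, Inf),
  heme_stress = c(-Inf, Inf),
  heme_metab  = c(-Inf, Inf),
  cell_death  = c(0, 1)
)

#' Canonical condition and readout labels
#'
#' @return Character vector of the five treatment conditions or the five
#'   readout names, in their canonical order.
#' @export
hemoscape_conditions <- function() .conditions

#' @rdname hemoscape_conditions
#' @export
hemoscape_readouts <- function() .readouts

#' Construct a per-condition readout summary
#'
#' One row of the preset table: mean, standard deviation and sample size of
#' one readout under one treatment condition. Units follow the readout:
#' ppb for `fe58`, uM per g protein for `mda`, a fraction in \[0, 1\] for
#' `cell_death`, and arbitrary variance-stabilized units for the two
#' transcriptional scores.
#'
#' @param condition One of `hemoscape_conditions()`.
#' @param readout One of `hemoscape_readouts()`.
#' @param mean Readout mean, in readout units.
#' @param sd Standard deviation, `>= 0`.
#' @param n Number of slices the summary is based on, `>= 2`.
#' @param assumed Logical; `TRUE` when the value is an implementer-chosen
#'   stand-in rather than a published measurement.
#' @return A one-row `data.frame` with columns
#'   `condition, readout, mean, sd, n, assumed`.
#' @export
condition_summary <- function(condition, readout, mean, sd, n,
                              assumed = FALSE) {
  condition <- match.arg(condition, .conditions)
  readout <- match.arg(readout, .readouts)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("'sd' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  if (readout == "cell_death" && (mean < 0 || mean > 1))
    stop("'cell_death' mean must lie in [0, 1]", call. = FALSE)
  data.frame(condition = condition, readout = readout,
             mean = mean, sd = sd, n = as.integer(n),
             assumed = isTRUE(assumed), stringsAsFactors = FALSE)
}

#' Default per-condition readout presets
#'
#' The 25-row table (5 conditions x 5 readouts) of per-condition mean, SD
#' and n that parameterizes the synthetic readout-pool generator. Published
#' group summaries are transcribed exactly: tissue 58Fe after 200 uM
#' exposure (e.g. free Hb 0.202 +/- 0.011 ppb, n = 6), control-centered MDA
#' (e.g. free Hb 1.164 +/- 0.685 uM/g), and the apoptotic neuron fraction
#' (e.g. heme-albumin 0.543 +/- 0.25), with cell-death percentages stored
#' as fractions.
#'
#' Rows with `assumed = TRUE` carry implementer-chosen stand-ins: the
#' control 58Fe value (no control iron value is published; the
#' heme-hemopexin level, described as near-baseline, serves as proxy) and
#' all ten transcriptional score rows, whose absolute units are arbitrary
#' and which encode only the published ordinal ranking — heme stress:
#' HemeHpx < Ctrl < HemeAlb < Hb < HbHp; heme metabolism elevated only for
#' HbHp.
#'
#' @return A 25-row `data.frame` with columns
#'   `condition, readout, mean, sd, n, assumed`.
#' @seealso [generate_readout_pool()], [pools_from_presets()]
#' @export
default_presets <- function() {
  rows <- list(
    # 58Fe tissue burden (ppb), n = 6 per exposed group
    condition_summary("Ctrl",    "fe58", 0.056, 0.004, 6, assumed = TRUE),
    condition_summary("HemeAlb", "fe58", 0.182, 0.009, 6),
    condition_summary("HemeHpx", "fe58", 0.056, 0.004, 6),
    condition_summary("Hb",      "fe58", 0.202, 0.011, 6),
    condition_summary("HbHp",    "fe58", 0.136, 0.023, 6),
    # normalized MDA (uM per g protein); control-centered, negatives legal
    condition_summary("Ctrl",    "mda", -0.830, 0.286, 21),
    condition_summary("HemeAlb", "mda",  0.861, 0.940, 21),
    condition_summary("HemeHpx", "mda", -0.924, 0.359, 13),
    condition_summary("Hb",      "mda",  1.164, 0.685, 21),
    condition_summary("HbHp",    "mda", -0.234, 0.656, 21),
    # heme-stress transcript score (arbitrary VST units)
    condition_summary("Ctrl",    "heme_stress",  0.00, 0.30, 12, assumed = TRUE),
    condition_summary("HemeAlb", "heme_stress",  1.00, 0.35, 12, assumed = TRUE),
    condition_summary("HemeHpx", "heme_stress", -0.20, 0.30, 12, assumed = TRUE),
    condition_summary("Hb",      "heme_stress",  1.20, 0.40, 12, assumed = TRUE),
    condition_summary("HbHp",    "heme_stress",  1.50, 0.40, 12, assumed = TRUE),
    # heme-metabolism transcript score (arbitrary VST units)
    condition_summary("Ctrl",    "heme_metab", 0.00, 0.25, 12, assumed = TRUE),
    condition_summary("HemeAlb", "heme_metab", 0.10, 0.25, 12, assumed = TRUE),
    condition_summary("HemeHpx", "heme_metab", 0.00, 0.25, 12, assumed = TRUE),
    condition_summary("Hb",      "heme_metab", 0.20, 0.25, 12, assumed = TRUE),
    condition_summary("HbHp",    "heme_metab", 1.20, 0.35, 12, assumed = TRUE),
    # apoptotic neuron fraction (pseudocytometry), percent / 100
    condition_summary("Ctrl",    "cell_death", 0.229, 0.12, 16),
    condition_summary("HemeAlb", "cell_death", 0.543, 0.25, 15),
    condition_summary("HemeHpx", "cell_death", 0.314, 0.16, 13),
    condition_summary("Hb",      "cell_death", 0.480, 0.22, 18),
    condition_summary("HbHp",    "cell_death", 0.197, 0.17, 17)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
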