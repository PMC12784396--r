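#' Specify a synthetic two-population fluorescence image
#'
#' Describes a field of disk-shaped cells in two populations —
#' apoptotic (Casp3-high / NeuN-low) and viable (Casp3-low / NeuN-high) —
#' rendered into three 16-bit channels (nuclei, NeuN, cleaved Caspase-3)
#' with additive Gaussian noise. The apoptotic population must have the
#' higher Casp3 mean and the lower NeuN mean.
#'
#' @param n_cells Number of cells, `>= 1`.
#' @param apoptotic_fraction Fraction of cells in the apoptotic population,
#'   in \[0, 1\]. The apoptotic count is `round half up` of
#'   `apoptotic_fraction * n_cells`.
#' @param image_shape Integer `(height, width)` in pixels.
#' @param channel_means 2x2 numeric matrix of per-population mean
#'   intensities; rows `viable`/`apoptotic`, columns `neun`/`casp3`.
#' @param channel_cv Coefficient of variation of per-cell intensity for
#'   both channels.
#' @param background_level Background intensity.
#' @param cell_radius Cell (disk) radius in pixels.
#' @param nuclei_level Nuclei-channel intensity of every cell.
#' @param seed Integer seed used by [generate_image()].
#' @return A list of class `"synthetic_image_spec"`.
#' @export
synthetic_image_spec <- function(n_cells = 100,
                                 apoptotic_fraction = 0.5,
                                 image_shape = c(512L, 512L),
                                 channel_means = rbind(
                                   viable    = c(neun = 12000, casp3 = 800),
                                   apoptotic = c(neun = 800, casp3 = 12000)),
                                 channel_cv = 0.15,
                                 background_level = 500,
                                 cell_radius = 6,
                                 nuclei_level = 20000,
                                 seed = 1L) {
  stopifnot(n_cells >= 1, length(image_shape) == 2L,
            all(image_shape >= 4 * cell_radius),
            channel_cv >= 0, cell_radius >= 1, background_level >= 0)
  if (apoptotic_fraction < 0 || apoptotic_fraction > 1)
    stop("'apoptotic_fraction' must lie in [0, 1]", call. = FALSE)
  channel_means <- as.matrix(channel_means)
  if (!all(c("viable", "apoptotic") %in% rownames(channel_means)) ||
      !all(c("neun", "casp3") %in% colnames(channel_means)))
    stop("'channel_means' needs rows viable/apoptotic, columns neun/casp3",
         call. = FALSE)
  if (!(channel_means["apoptotic", "casp3"] > channel_means["viable", "casp3"] &&
        channel_means["apoptotic", "neun"] < channel_means["viable", "neun"]))
    stop("apoptotic population must be Casp3-high and NeuN-low ",
         "relative to the viable population", call. = FALSE)
  hi <- max(channel_means, nuclei_level, background_level)
  if (hi * (1 + 5 * channel_cv) > 65535)
    stop("intensities do not fit the 16-bit range", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells),
                 apoptotic_fraction = apoptotic_fraction,
                 image_shape = as.integer(image_shape),
                 channel_means = channel_means,
                 channel_cv = channel_cv,
                 background_level = background_level,
                 cell_radius = cell_radius,
                 nuclei_level = nuclei_level,
                 seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Non-overlapping disk centers by rejection sampling; errors out rather
# than silently dropping cells when the packing is infeasible.
.place_centers <- function(n, shape, radius, max_tries = 300L * n) {
  margin <- radius + 1
  min_d2 <- (2 * radius + 2)^2
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L; tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: could not place ", n,
           " non-overlapping cells of radius ", radius,
           " in a ", shape[1], "x", shape[2], " image", call. = FALSE)
    r <- stats::runif(1, margin, shape[1] - margin)
    c <- stats::runif(1, margin, shape[2] - margin)
    if (placed == 0L ||
        min((rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2) >=
        min_d2) {
      placed <- placed + 1L
      rows[placed] <- r; cols[placed] <- c
    }
  }
  cbind(row = rows, col = cols)
}

#' Render a synthetic two-channel + nuclei fluorescence image
#'
#' Places `n_cells` non-overlapping disks, assigns
#' `round(apoptotic_fraction * n_cells)` of them (round half up) to the
#' apoptotic population, and renders three 16-bit channels. Per-cell
#' intensity is drawn as Normal(mean, cv * mean) per channel; pixels add
#' Gaussian noise at 30% of the cell-level SD; the background carries mild
#' Gaussian noise. All pixels are clamped to \[0, 65535\].
#'
#' @param spec A [synthetic_image_spec()].
#' @return A list with integer matrices `nuclei`, `neun`, `casp3` and a
#'   `truth` data.frame (`cell_id`, 0-based center `row`/`col`,
#'   `population`, per-cell true `neun`/`casp3` intensity) carrying the
#'   realized `apoptotic_fraction` as an attribute.
#' @examples
#' img <- generate_image(synthetic_image_spec(n_cells = 20, seed = 3))
#' table(img$truth$population)
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    shape <- spec$image_shape
    centers <- .place_centers(n, shape, spec$cell_radius)
    n_apo <- floor(spec$apoptotic_fraction * n + 0.5)  # round half up
    population <- rep("viable", n)
    if (n_apo > 0) population[seq_len(n_apo)] <- "apoptotic"
    cv <- spec$channel_cv
    mu <- spec$channel_means
    cell_neun <- pmax(0, stats::rnorm(n, mu[population, "neun"],
                                      cv * mu[population, "neun"]))
    cell_casp3 <- pmax(0, stats::rnorm(n, mu[population, "casp3"],
                                       cv * mu[population, "casp3"]))

    npix <- prod(shape)
    bg_sd <- 0.05 * max(spec$background_level, 1)
    nuclei <- matrix(stats::rnorm(npix, spec$background_level, bg_sd),
                     shape[1], shape[2])
    neun <- matrix(stats::rnorm(npix, spec$background_level, bg_sd),
                   shape[1], shape[2])
    casp3 <- matrix(stats::rnorm(npix, spec$background_level, bg_sd),
                    shape[1], shape[2])

    r <- spec$cell_radius
    off <- expand.grid(dr = -r:r, dc = -r:r)
    off <- off[off$dr^2 + off$dc^2 <= r^2, ]
    for (i in seq_len(n)) {
      pr <- round(centers[i, "row"]) + off$dr
      pc <- round(centers[i, "col"]) + off$dc
      idx <- cbind(pr, pc)
      k <- nrow(idx)
      nuclei[idx] <- spec$nuclei_level +
        stats::rnorm(k, 0, 0.3 * cv * spec$nuclei_level)
      neun[idx] <- cell_neun[i] +
        stats::rnorm(k, 0, 0.3 * cv * max(cell_neun[i], 1))
      casp3[idx] <- cell_casp3[i] +
        stats::rnorm(k, 0, 0.3 * cv * max(cell_casp3[i], 1))
    }
    clamp16 <- function(m) {
      m[m < 0] <- 0; m[m > 65535] <- 65535
      round(m)
    }
    truth <- data.frame(cell_id = seq_len(n),
                        row = centers[, "row"] - 1,  # 0-based
                        col = centers[, "col"] - 1,
                        population = population,
                        neun = cell_neun,
                        casp3 = cell_casp3,
                        stringsAsFactors = FALSE)
    attr(truth, "apoptotic_fraction") <- n_apo / n
    list(nuclei = clamp16(nuclei), neun = clamp16(neun),
         casp3 = clamp16(casp3), truth = truth)
  })
}

#' Write or read a 16-bit grayscale TIFF channel
#'
#' Intensities are stored as 16-bit grayscale; matrices hold raw counts in
#' \[0, 65535\].
#'
#' @param image Numeric matrix of intensities in \[0, 65535\].
#' @param path File path.
#' @return `read_channel_tiff()` returns the intensity matrix;
#'   `write_channel_tiff()` returns `path` invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 65535))
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @export
read_channel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 65535)
}
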