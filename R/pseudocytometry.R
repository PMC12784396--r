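# Pseudocytometry: flow-cytometry-style per-cell analysis of segmented
# fluorescence images. Nuclei are segmented by Otsu thresholding and
# connected-component labelling (EBImage); per-cell NeuN and cleaved
# Caspase-3 mean intensities are clustered by k-means (k = 2) on
# log-transformed features to separate Casp3-high/NeuN-low apoptotic from
# Casp3-low/NeuN-high viable neurons.

#' Segment cells from a nuclei channel and quantify marker intensities
#'
#' Otsu threshold on the nuclei channel, connected components, minimum
#' size filter, then per-component mean intensity in the NeuN and Casp3
#' channels. Deterministic for fixed input. A nuclei image that is empty
#' after thresholding yields an empty table, not an error.
#'
#' @param nuclei,neun,casp3 Intensity matrices of identical shape (16-bit
#'   counts or any non-negative grayscale).
#' @param min_area Minimum component area in pixels.
#' @return A `data.frame` with one row per cell: `cell_id`, 0-based
#'   centroid `row`/`col`, `area`, `neun_mean`, `casp3_mean`,
#'   `log_neun`/`log_casp3` (`log10(x + 1)`), and `label`
#'   (`"unassigned"` until classified).
#' @seealso [classify_cells()]
#' @export
segment_cells <- function(nuclei, neun, casp3, min_area = 20) {
  if (!is.matrix(nuclei) || !is.matrix(neun) || !is.matrix(casp3))
    stop("channel images must be matrices", call. = FALSE)
  if (!identical(dim(nuclei), dim(neun)) ||
      !identical(dim(nuclei), dim(casp3)))
    stop("channel images must share the same shape", call. = FALSE)

  empty <- data.frame(cell_id = integer(0), row = numeric(0),
                      col = numeric(0), area = integer(0),
                      neun_mean = numeric(0), casp3_mean = numeric(0),
                      log_neun = numeric(0), log_casp3 = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  rng <- range(nuclei)
  if (rng[1] == rng[2]) return(empty)

  scaled <- (nuclei - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  if (!any(mask)) return(empty)

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  labv <- as.vector(lab)
  keep <- labv > 0
  if (!any(keep)) return(empty)

  labv <- labv[keep]
  areas <- tabulate(labv)
  ok <- which(areas >= min_area)
  if (length(ok) == 0L) return(empty)

  ridx <- (row(nuclei) - 1)[keep]   # 0-based pixel coordinates
  cidx <- (col(nuclei) - 1)[keep]
  sum_by <- function(x) rowsum(x, labv)[, 1]
  n_by <- areas[seq_len(max(labv))]
  cen_r <- sum_by(ridx) / n_by
  cen_c <- sum_by(cidx) / n_by
  neun_mean <- sum_by(as.vector(neun)[keep]) / n_by
  casp3_mean <- sum_by(as.vector(casp3)[keep]) / n_by

  out <- data.frame(cell_id = seq_along(ok),
                    row = cen_r[ok], col = cen_c[ok],
                    area = as.integer(areas[ok]),
                    neun_mean = neun_mean[ok], casp3_mean = casp3_mean[ok],
                    stringsAsFactors = FALSE)
  out$log_neun <- log10(out$neun_mean + 1)
  out$log_casp3 <- log10(out$casp3_mean + 1)
  out$label <- "unassigned"
  rownames(out) <- NULL
  out
}

#' Classify segmented cells into apoptotic and viable populations
#'
#' k-means with k = 2 on `(log_neun, log_casp3)`, 10 random restarts under
#' a fixed seed. The cluster whose center has the higher `log_casp3` is
#' labelled apoptotic (tie broken by lower `log_neun`), matching the
#' Casp3-high/NeuN-low phenotype definition; every cell receives a label.
#'
#' @param cells Cell table from [segment_cells()].
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Number of k-means restarts (`>= 10` recommended).
#' @return An object of class `"cell_classification"`: list with `cells`
#'   (labelled table), `k = 2`, `centers` (2x2 matrix, rows
#'   `apoptotic`/`viable`), `apoptotic_fraction` and `n_cells`.
#' @examples
#' img <- generate_image(synthetic_image_spec(n_cells = 40, seed = 2))
#' cells <- segment_cells(img$nuclei, img$neun, img$casp3)
#' res <- classify_cells(cells, seed = 2)
#' res$apoptotic_fraction
#' @export
classify_cells <- function(cells, seed = 1L, nstart = 10L) {
  if (!is.data.frame(cells) || nrow(cells) < 2L)
    stop("classification needs at least 2 segmented cells", call. = FALSE)
  feats <- as.matrix(cells[, c("log_neun", "log_casp3")])
  if (nrow(unique(feats)) < 2L)
    stop("all cells have identical (log_neun, log_casp3) features; ",
         "two clusters are undefined", call. = FALSE)
  if (nrow(feats) == 2L) {
    # two distinct cells: the optimal 2-partition is one cell per cluster
    km <- list(cluster = 1:2, centers = feats)
  } else {
    km <- with_seed(seed,
                    stats::kmeans(feats, centers = 2L, nstart = nstart,
                                  iter.max = 100L))
  }
  cen <- km$centers
  colnames(cen) <- c("log_neun", "log_casp3")
  if (cen[1, "log_casp3"] != cen[2, "log_casp3"]) {
    apo <- which.max(cen[, "log_casp3"])
  } else {
    apo <- which.min(cen[, "log_neun"])
  }
  lab <- ifelse(km$cluster == apo, "apoptotic", "viable")
  cells$label <- lab
  centers <- cen[c(apo, 3L - apo), , drop = FALSE]
  rownames(centers) <- c("apoptotic", "viable")
  structure(list(cells = cells, k = 2L, centers = centers,
                 apoptotic_fraction = sum(lab == "apoptotic") / nrow(cells),
                 n_cells = nrow(cells)),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  cat("Pseudocytometric classification (k-means, k = 2)\n")
  cat(sprintf("  %d cells: %d apoptotic / %d viable (fraction %.3f)\n",
              x$n_cells, sum(x$cells$label == "apoptotic"),
              sum(x$cells$label == "viable"), x$apoptotic_fraction))
  cat("  cluster centers (log10 intensity + 1):\n")
  print(round(x$centers, 3))
  invisible(x)
}

#' Per-image apoptotic fractions and pooled summary
#'
#' @param results List of `"cell_classification"` objects, optionally
#'   named by image.
#' @return A `data.frame` (`image`, `fraction`, `n_cells`) with a
#'   `"pooled"` attribute holding mean, SD and image count across images.
#' @export
apoptotic_fraction_by_image <- function(results) {
  if (length(results) == 0L)
    stop("'results' must contain at least one classification", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "cell_classification")))
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("image", seq_along(results))
  out <- data.frame(
    image = nm,
    fraction = vapply(results, function(r) r$apoptotic_fraction, numeric(1)),
    n_cells = vapply(results, function(r) r$n_cells, integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pooled") <- c(mean = mean(out$fraction),
                           sd = stats::sd(out$fraction),
                           n_images = nrow(out))
  out
}
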