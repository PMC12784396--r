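#' Fit the bootstrap pseudoslice PCA
#'
#' The package's central model fit: assembles `B` bootstrap pseudoslices
#' per condition from the readout pools, z-scales the stacked matrix
#' globally, decomposes it into principal components, orients PC1 on the
#' iron-deposition readout and PC2 on the heme-metabolism score, and
#' summarizes each condition by its centroid, percentile interval and
#' attractor state on the PC1 (oxidative toxicity) / PC2 (metabolic
#' adaptation) map.
#'
#' @param pools A [readout_pools()] object, or a long `data.frame`
#'   accepted by `readout_pools()`.
#' @param B Bootstrap replicates per condition (default 250).
#' @param seed Integer seed for the bootstrap resampling.
#' @param control Control condition label for attractor classification;
#'   `NULL` skips classification.
#' @param anchors Sign-orientation anchors, see [orient_components()].
#' @return Object of class `"boot_pca"`: list with `pca` (oriented
#'   [run_pca()] result), `pseudoslices`, `centroids`, `states`, `B`,
#'   `seed`, `control` and `call`.
#' @examples
#' fit <- boot_pca(pools_from_presets(seed = 1), B = 50, seed = 1)
#' fit
#' coef(fit)[, 1:2]
#' @seealso [make_pseudoslices()], [zscale()], [run_pca()],
#'   [orient_components()], [condition_centroids()],
#'   [classify_attractors()]
#' @export
boot_pca <- function(pools, B = 250, seed = 1L, control = "Ctrl",
                     anchors = c(PC1 = "fe58", PC2 = "heme_metab")) {
  cl <- match.call()
  if (is.data.frame(pools)) pools <- readout_pools(pools)
  stopifnot(inherits(pools, "readout_pools"))
  ps <- make_pseudoslices(pools, B = B, seed = seed)
  scaled <- zscale(ps)
  p <- orient_components(run_pca(scaled), anchors = anchors)
  centroids <- condition_centroids(p)
  states <- if (!is.null(control) && control %in% centroids$condition)
    classify_attractors(centroids, control) else NULL
  structure(list(pca = p, pseudoslices = scaled, centroids = centroids,
                 states = states, B = as.integer(B), seed = seed,
                 control = control, call = cl),
            class = "boot_pca")
}

#' @export
print.boot_pca <- function(x, ...) {
  ev <- x$pca$explained_fraction
  cat("Bootstrap pseudoslice PCA\n")
  cat(sprintf("  %d pseudoslices (%d conditions x B = %d), %d readouts\n",
              nrow(x$pca$scores), length(unique(x$pca$condition_labels)),
              x$B, nrow(x$pca$loadings)))
  cat(sprintf("  PC1 %.1f%% (oxidative toxicity), PC2 %.1f%% (metabolic adaptation)\n",
              100 * ev[1], 100 * ev[2]))
  if (!is.null(x$states)) {
    st <- merge(x$centroids[, c("condition", "pc1_mean", "pc2_mean")],
                x$states, by = "condition", sort = FALSE)
    print(within(st, {pc1_mean <- round(pc1_mean, 2)
                      pc2_mean <- round(pc2_mean, 2)}),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.boot_pca <- function(object, ...) {
  structure(list(explained = object$pca$explained_fraction,
                 loadings = object$pca$loadings,
                 centroids = object$centroids,
                 states = object$states,
                 orientation = object$pca$orientation,
                 B = object$B),
            class = "summary.boot_pca")
}

#' @export
print.summary.boot_pca <- function(x, ...) {
  cat("Explained variance fraction per component:\n")
  ev <- x$explained
  names(ev) <- colnames(x$loadings)
  print(round(ev, 4))
  cat("\nLoadings (readouts x components):\n")
  print(round(x$loadings, 3))
  cat("\nCondition centroids (95% percentile intervals):\n")
  print(cbind(x$centroids[1],
              round(x$centroids[, -1, drop = FALSE], 3)),
        row.names = FALSE)
  if (!is.null(x$states)) {
    cat("\nAttractor states:\n")
    print(x$states, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn boot_pca Loadings matrix (readouts x components).
#' @param object,x A `"boot_pca"` fit.
#' @param ... Unused.
#' @export
coef.boot_pca <- function(object, ...) object$pca$loadings

#' @describeIn boot_pca Project new readout observations onto the fitted
#'   components using the stored scaling constants.
#' @param newdata Matrix or data.frame with the fitted readout columns;
#'   `NULL` returns the fitted pseudoslice scores.
#' @export
predict.boot_pca <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$pca$scores)
  nd <- as.matrix(newdata[, rownames(object$pca$loadings), drop = FALSE])
  z <- sweep(sweep(nd, 2, object$pca$column_means), 2,
             object$pca$column_sds, "/")
  z %*% object$pca$loadings
}

#' @describeIn boot_pca Biplot-style map: pseudoslice scores on PC1/PC2
#'   colored by condition, centroids, and loading arrows.
#' @export
plot.boot_pca <- function(x, ...) {
  s <- x$pca$scores
  conds <- unique(x$pca$condition_labels)
  cols <- grDevices::hcl.colors(length(conds), "Dark 2")
  names(cols) <- conds
  ev <- x$pca$explained_fraction
  graphics::plot(s[, 1], s[, 2],
                 col = grDevices::adjustcolor(cols[x$pca$condition_labels], 0.35),
                 pch = 16, cex = 0.5,
                 xlab = sprintf("PC1, oxidative toxicity (%.1f%%)", 100 * ev[1]),
                 ylab = sprintf("PC2, metabolic adaptation (%.1f%%)", 100 * ev[2]),
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 2)
  cen <- x$centroids
  graphics::points(cen$pc1_mean, cen$pc2_mean, pch = 21, cex = 1.6,
                   bg = cols[cen$condition])
  graphics::text(cen$pc1_mean, cen$pc2_mean, cen$condition, pos = 3)
  L <- x$pca$loadings
  sc <- 0.8 * max(abs(s[, 1:2])) / max(abs(L[, 1:2]))
  graphics::arrows(0, 0, sc * L[, 1], sc * L[, 2], length = 0.08,
                   col = "grey30")
  graphics::text(1.05 * sc * L[, 1], 1.05 * sc * L[, 2], rownames(L),
                 col = "grey30", cex = 0.8)
  invisible(x)
}
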