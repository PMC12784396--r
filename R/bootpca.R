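# Bootstrap pseudoslice PCA. Each destructive assay consumes the slice it
# measures, so no single slice carries all five readouts. Pseudoslices
# resolve this: for each condition, B multivariate observations are
# assembled by drawing, with replacement and independently, one value per
# readout from that condition's empirical pool. The stacked matrix is
# z-scaled globally and decomposed into principal components; PC1 captures
# the oxidative-toxicity cascade (iron deposition, lipid peroxidation,
# cell death, heme-stress transcription) and PC2 the Nrf2/heme-metabolism
# adaptation program.

#' Construct per-condition readout pools
#'
#' @param values Long `data.frame` with columns `condition`, `readout`,
#'   `value` — one row per measured slice value.
#' @param conditions,readouts Label order; defaults to order of first
#'   appearance. Every (condition, readout) cell must be non-empty.
#' @return Object of class `"readout_pools"`: nested list
#'   `pools[[condition]][[readout]]` plus the ordered label vectors.
#' @export
readout_pools <- function(values,
                          conditions = unique(values$condition),
                          readouts = unique(values$readout)) {
  stopifnot(is.data.frame(values),
            all(c("condition", "readout", "value") %in% names(values)))
  pools <- lapply(conditions, function(cond) {
    row <- lapply(readouts, function(r) {
      v <- values$value[values$condition == cond & values$readout == r]
      if (length(v) == 0L)
        stop("empty pool for (", cond, ", ", r, ")", call. = FALSE)
      v
    })
    names(row) <- readouts
    row
  })
  names(pools) <- conditions
  structure(list(pools = pools, conditions = conditions,
                 readouts = readouts),
            class = "readout_pools")
}

#' @export
print.readout_pools <- function(x, ...) {
  sizes <- sapply(x$pools, function(p) sapply(p, length))
  cat(sprintf("Readout pools: %d conditions x %d readouts\n",
              length(x$conditions), length(x$readouts)))
  print(sizes)
  invisible(x)
}

#' Assemble bootstrap pseudoslices from readout pools
#'
#' For each condition, `B` pseudoslices are built by sampling with
#' replacement one value per readout, independently across readouts. With
#' the five standard conditions and the default `B = 250` the result is
#' the 1250 x 5 matrix the downstream PCA operates on. The RNG is consumed
#' in a fixed condition-major order so a seed pins the whole matrix.
#'
#' @param pools A [readout_pools()] object.
#' @param B Bootstrap replicates per condition, `>= 1` (default 250).
#' @param seed Integer seed.
#' @return Object of class `"pseudoslice_matrix"`: list with `values`
#'   ((conditions x B) x readouts matrix), `condition_labels`, `B`,
#'   `scaled = FALSE`, and empty scaling records.
#' @export
make_pseudoslices <- function(pools, B = 250, seed = NULL) {
  stopifnot(inherits(pools, "readout_pools"))
  if (!is.numeric(B) || length(B) != 1L || B < 1 || B != round(B))
    stop("'B' must be a positive integer", call. = FALSE)
  B <- as.integer(B)
  nr <- length(pools$readouts)
  with_seed(seed, {
    blocks <- lapply(pools$conditions, function(cond) {
      cell <- pools$pools[[cond]]
      # one runif block per condition, laid out replicate-major
      u <- matrix(stats::runif(B * nr), B, nr, byrow = TRUE)
      m <- matrix(0, B, nr, dimnames = list(NULL, pools$readouts))
      for (j in seq_len(nr)) {
        pool <- cell[[j]]
        m[, j] <- pool[ceiling(u[, j] * length(pool))]
      }
      m
    })
    values <- do.call(rbind, blocks)
    structure(list(values = values,
                   condition_labels = rep(pools$conditions, each = B),
                   B = B, scaled = FALSE,
                   column_means = NULL, column_sds = NULL),
              class = "pseudoslice_matrix")
  })
}

#' @export
print.pseudoslice_matrix <- function(x, ...) {
  cat(sprintf("Pseudoslice matrix: %d rows (%d conditions x B = %d) x %d readouts%s\n",
              nrow(x$values), length(unique(x$condition_labels)), x$B,
              ncol(x$values), if (x$scaled) ", z-scaled" else ""))
  invisible(x)
}

#' Z-scale a pseudoslice matrix
#'
#' Each readout column is centered by its global mean and divided by its
#' global SD (denominator n - 1), computed over all rows of the stacked
#' matrix — one matrix-level operation, not per condition. The scaling
#' constants are recorded so new observations can be projected later.
#'
#' @param m A [make_pseudoslices()] result, not yet scaled.
#' @return The scaled `"pseudoslice_matrix"` with `column_means` and
#'   `column_sds` filled in.
#' @export
zscale <- function(m) {
  stopifnot(inherits(m, "pseudoslice_matrix"))
  if (isTRUE(m$scaled))
    stop("matrix is already z-scaled", call. = FALSE)
  mu <- colMeans(m$values)
  sds <- apply(m$values, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    stop("zero-variance readout column(s): ",
         paste(colnames(m$values)[zero], collapse = ", "), call. = FALSE)
  m$values <- sweep(sweep(m$values, 2, mu), 2, sds, "/")
  m$scaled <- TRUE
  m$column_means <- mu
  m$column_sds <- sds
  m
}

#' Principal components of a scaled pseudoslice matrix
#'
#' Eigendecomposition of the sample covariance matrix (divisor n - 1) of
#' the z-scaled data; components are sorted by descending eigenvalue,
#' explained fractions are eigenvalue / trace, and scores are the scaled
#' rows projected on the loadings.
#'
#' @param m A z-scaled `"pseudoslice_matrix"` with more rows than columns.
#' @return Object of class `"pca_result"`: `loadings` (readouts x
#'   components, orthonormal columns), `explained_fraction`, `sdev`,
#'   `scores`, `condition_labels`, `orientation` (sign-flip record, empty
#'   until [orient_components()]), and the scaling constants.
#' @export
run_pca <- function(m) {
  stopifnot(inherits(m, "pseudoslice_matrix"))
  if (!isTRUE(m$scaled))
    stop("z-scale the pseudoslice matrix before PCA", call. = FALSE)
  v <- m$values
  if (nrow(v) <= ncol(v))
    stop("PCA needs more pseudoslices than readouts", call. = FALSE)
  C <- stats::cov(v)
  e <- eigen(C, symmetric = TRUE)
  val <- pmax(e$values, 0)
  k <- ncol(v)
  loadings <- e$vectors
  dimnames(loadings) <- list(colnames(v), paste0("PC", seq_len(k)))
  structure(list(loadings = loadings,
                 explained_fraction = val / sum(val),
                 sdev = sqrt(val),
                 scores = v %*% loadings,
                 condition_labels = m$condition_labels,
                 orientation = data.frame(component = character(0),
                                          anchor = character(0),
                                          flipped = logical(0),
                                          stringsAsFactors = FALSE),
                 column_means = m$column_means,
                 column_sds = m$column_sds),
            class = "pca_result")
}

#' Fix component signs with readout anchors
#'
#' PCA signs are arbitrary; the biplot convention used here orients PC1 so
#' the `fe58` loading is non-negative (toxicity increases rightward) and
#' PC2 so the `heme_metab` loading is non-negative (adaptation increases
#' upward). Scores flip with their loadings; applied flips are recorded. A
#' zero loading on an anchor leaves that component untouched (recorded as
#' not flipped). Idempotent, and an involution with respect to a sign
#' flip.
#'
#' @param p A [run_pca()] result.
#' @param anchors Named character vector mapping component name to anchor
#'   readout.
#' @return The oriented `"pca_result"`.
#' @export
orient_components <- function(p, anchors = c(PC1 = "fe58",
                                             PC2 = "heme_metab")) {
  stopifnot(inherits(p, "pca_result"))
  rec <- list()
  for (comp in names(anchors)) {
    anchor <- anchors[[comp]]
    if (!comp %in% colnames(p$loadings) ||
        !anchor %in% rownames(p$loadings)) next
    flip <- p$loadings[anchor, comp] < 0
    if (flip) {
      p$loadings[, comp] <- -p$loadings[, comp]
      p$scores[, comp] <- -p$scores[, comp]
    }
    rec[[comp]] <- data.frame(component = comp, anchor = anchor,
                              flipped = flip, stringsAsFactors = FALSE)
  }
  p$orientation <- do.call(rbind, c(list(p$orientation[0, ]), rec))
  rownames(p$orientation) <- NULL
  p
}

#' Per-condition centroids with percentile intervals
#'
#' Mean PC1/PC2 score per condition plus the 2.5-97.5 percentile interval
#' of that condition's pseudoslice scores on each axis.
#'
#' @param p A `"pca_result"`.
#' @param labels Condition label per score row; defaults to the labels
#'   carried by `p`.
#' @param level Interval coverage, default 0.95.
#' @return `data.frame` with columns `condition`, `pc1_mean`, `pc1_lo`,
#'   `pc1_hi`, `pc2_mean`, `pc2_lo`, `pc2_hi`, `n`.
#' @export
condition_centroids <- function(p, labels = p$condition_labels,
                                level = 0.95) {
  stopifnot(inherits(p, "pca_result"))
  if (length(labels) != nrow(p$scores))
    stop("'labels' must align with the score rows", call. = FALSE)
  a <- (1 - level) / 2
  conds <- unique(labels)
  rows <- lapply(conds, function(cond) {
    s <- p$scores[labels == cond, c("PC1", "PC2"), drop = FALSE]
    q1 <- stats::quantile(s[, 1], c(a, 1 - a), names = FALSE)
    q2 <- stats::quantile(s[, 2], c(a, 1 - a), names = FALSE)
    data.frame(condition = cond,
               pc1_mean = mean(s[, 1]), pc1_lo = q1[1], pc1_hi = q1[2],
               pc2_mean = mean(s[, 2]), pc2_lo = q2[1], pc2_hi = q2[2],
               n = nrow(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify conditions into attractor states
#'
#' Deterministic rule relative to the control's percentile intervals:
#' the control itself is `Baseline`; a treated condition whose PC1
#' interval lies entirely above the control's is `Toxic`; otherwise, one
#' whose PC2 interval lies entirely above the control's is `Adaptive`;
#' any other treated condition — its intervals overlap the control's
#' despite a toxin being present — is `Sequestered`.
#'
#' @param centroids Table from [condition_centroids()].
#' @param control_label The control condition; must be present.
#' @return `data.frame` with columns `condition`, `state`.
#' @export
classify_attractors <- function(centroids, control_label = "Ctrl") {
  stopifnot(is.data.frame(centroids),
            all(c("condition", "pc1_lo", "pc1_hi", "pc2_lo", "pc2_hi") %in%
                  names(centroids)))
  if (!control_label %in% centroids$condition)
    stop("control condition '", control_label, "' not present",
         call. = FALSE)
  ctrl <- centroids[centroids$condition == control_label, ]
  state <- vapply(seq_len(nrow(centroids)), function(i) {
    row <- centroids[i, ]
    if (row$condition == control_label) return("Baseline")
    if (row$pc1_lo > ctrl$pc1_hi) return("Toxic")
    if (row$pc2_lo > ctrl$pc2_hi) return("Adaptive")
    "Sequestered"
  }, character(1))
  data.frame(condition = centroids$condition, state = state,
             stringsAsFactors = FALSE)
}
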