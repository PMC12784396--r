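test_that("readout_pools validates cells and make_pseudoslices sizes the matrix", {
  df <- toy_pool_df(n_per_cell = 8)
  pools <- readout_pools(df)
  ps <- make_pseudoslices(pools, B = 250, seed = 1)
  expect_equal(dim(ps$values), c(1250, 5))
  expect_equal(table(ps$condition_labels)[hemoscape_conditions()],
               table(rep(hemoscape_conditions(), 250))[hemoscape_conditions()])
  expect_false(ps$scaled)
  # seeded determinism
  expect_identical(make_pseudoslices(pools, B = 250, seed = 1)$values,
                   ps$values)
  # empty cell is named in the error
  bad <- df[!(df$condition == "Hb" & df$readout == "mda"), ]
  expect_error(readout_pools(bad), "\\(Hb, mda\\)")
})

test_that("degenerate single-value pools give constant pseudoslice blocks", {
  df <- expand.grid(condition = hemoscape_conditions(),
                    readout = hemoscape_readouts(),
                    stringsAsFactors = FALSE)
  df$value <- seq_len(nrow(df))  # one distinct value per cell
  ps <- make_pseudoslices(readout_pools(df), B = 20, seed = 2)
  for (cond in hemoscape_conditions()) {
    block <- ps$values[ps$condition_labels == cond, ]
    expect_equal(max(apply(block, 2, function(col) diff(range(col)))), 0)
  }
})

test_that("independent per-readout draws leave within-condition correlation near 0", {
  df <- toy_pool_df(n_per_cell = 40, seed = 13)
  ps <- make_pseudoslices(readout_pools(df), B = 5000, seed = 3)
  for (cond in hemoscape_conditions()) {
    block <- ps$values[ps$condition_labels == cond, ]
    cc <- cor(block)
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
  }
})

test_that("zscale centers and scales globally, once, and names degenerate columns", {
  df <- toy_pool_df(n_per_cell = 15,
                    mean_fun = function(cond, r) match(cond, hemoscape_conditions()))
  ps <- make_pseudoslices(readout_pools(df), B = 100, seed = 4)
  z <- zscale(ps)
  expect_true(all(abs(colMeans(z$values)) < 1e-9))
  expect_true(all(abs(apply(z$values, 2, sd) - 1) < 1e-9))
  expect_true(z$scaled)
  expect_error(zscale(z), "already")
  # scaling an already-centered unit-variance column is the identity
  ps2 <- ps
  ps2$values <- sweep(sweep(ps$values, 2, colMeans(ps$values)), 2,
                      apply(ps$values, 2, sd), "/")
  expect_equal(zscale(ps2)$values, ps2$values, tolerance = 1e-12)
  # constant column errors with the readout name
  ps3 <- ps
  ps3$values[, "mda"] <- 1
  expect_error(zscale(ps3), "mda")
})

test_that("run_pca matches prcomp and spectral properties hold", {
  set.seed(5)
  for (i in 1:20) {
    v <- matrix(rnorm(100), 20, 5,
                dimnames = list(NULL, hemoscape_readouts()))
    m <- structure(list(values = scale(v)[, ], condition_labels = rep("a", 20),
                        B = 20L, scaled = TRUE,
                        column_means = colMeans(v),
                        column_sds = apply(v, 2, sd)),
                   class = "pseudoslice_matrix")
    p <- run_pca(m)
    ref <- prcomp(m$values, center = FALSE, scale. = FALSE)
    expect_equal(p$sdev^2, ref$sdev^2, tolerance = 1e-8)
    for (j in 1:5)
      expect_equal(abs(sum(p$loadings[, j] * ref$rotation[, j])), 1,
                   tolerance = 1e-8)
    # orthonormal loadings, descending fractions summing to 1
    expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_true(all(diff(p$explained_fraction) <= 1e-12))
    expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-9)
  }
})

test_that("two correlated variables follow the (1 +/- rho)/2 closed form", {
  n <- 20000
  for (rho in c(0, 0.5, 0.9)) {
    set.seed(round(100 * rho) + 1)
    a <- rnorm(n)
    b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
    v <- scale(cbind(fe58 = a, mda = b))[, ]
    m <- structure(list(values = v, condition_labels = rep("x", n), B = n,
                        scaled = TRUE, column_means = c(0, 0),
                        column_sds = c(1, 1)),
                   class = "pseudoslice_matrix")
    p <- run_pca(m)
    r <- cor(v)[1, 2]  # realized correlation, exact closed form
    expect_equal(p$explained_fraction, c(1 + abs(r), 1 - abs(r)) / 2,
                 tolerance = 1e-9)
    expect_equal(p$explained_fraction[1], (1 + rho) / 2, tolerance = 0.02)
  }
  # perfectly correlated pair: first component carries 100%
  v <- scale(cbind(fe58 = 1:50, mda = 2 * (1:50) + 3))[, ]
  m <- structure(list(values = v, condition_labels = rep("x", 50), B = 50L,
                      scaled = TRUE, column_means = c(0, 0),
                      column_sds = c(1, 1)),
                 class = "pseudoslice_matrix")
  expect_equal(run_pca(m)$explained_fraction[1], 1, tolerance = 1e-12)
})

test_that("run_pca refuses unscaled or under-determined input", {
  df <- toy_pool_df(n_per_cell = 5)
  ps <- make_pseudoslices(readout_pools(df), B = 2, seed = 1)
  expect_error(run_pca(ps), "z-scale")
  z <- zscale(make_pseudoslices(readout_pools(df), B = 1, seed = 1))
  expect_error(run_pca(z), "more pseudoslices")
})

test_that("orientation anchors signs, is a fixed point and an involution", {
  fit <- boot_pca(pools_from_presets(seed = 2), B = 60, seed = 6)
  p <- fit$pca
  expect_gte(p$loadings["fe58", "PC1"], 0)
  expect_gte(p$loadings["heme_metab", "PC2"], 0)
  # already-oriented input is unchanged (up to the flip bookkeeping)
  p2 <- orient_components(p)
  expect_equal(p2$loadings, p$loadings)
  expect_equal(p2$scores, p$scores)
  expect_false(any(p2$orientation$flipped))
  # negate PC1 then orient: original recovered, flip recorded
  q <- p
  q$loadings[, "PC1"] <- -q$loadings[, "PC1"]
  q$scores[, "PC1"] <- -q$scores[, "PC1"]
  q2 <- orient_components(q)
  expect_equal(q2$loadings, p$loadings)
  expect_equal(q2$scores, p$scores)
  expect_true(q2$orientation$flipped[q2$orientation$component == "PC1"])
})

test_that("centroids sit at the origin in aggregate and separate by construction", {
  # two-condition toy: condition B exceeds A on every toxicity readout
  mean_fun <- function(cond, r)
    if (cond == "Hb" && r %in% c("fe58", "mda", "cell_death")) 5 else 0
  df <- toy_pool_df(conditions = c("Ctrl", "Hb"), n_per_cell = 30,
                    mean_fun = mean_fun, seed = 21)
  fit <- boot_pca(readout_pools(df), B = 200, seed = 7)
  cen <- fit$centroids
  # grand centroid of centered scores is the origin
  expect_lt(abs(mean(fit$pca$scores[, "PC1"])), 1e-9)
  expect_lt(abs(mean(fit$pca$scores[, "PC2"])), 1e-9)
  # the toxin-shifted condition lies at PC1 > 0 after orientation
  expect_gt(cen$pc1_mean[cen$condition == "Hb"], 0)
  expect_gt(cen$pc1_mean[cen$condition == "Hb"],
            cen$pc1_mean[cen$condition == "Ctrl"])
  # degenerate pools: zero-width interval at the centroid
  dfc <- expand.grid(condition = c("Ctrl", "Hb"),
                     readout = hemoscape_readouts(),
                     stringsAsFactors = FALSE)
  dfc$value <- ifelse(dfc$condition == "Hb", 1, 0)
  psc <- zscale(make_pseudoslices(readout_pools(dfc), B = 50, seed = 1))
  cenc <- condition_centroids(orient_components(run_pca(psc)))
  expect_equal(cenc$pc1_lo, cenc$pc1_hi)
  expect_equal(cenc$pc1_lo, cenc$pc1_mean)
  expect_error(condition_centroids(fit$pca, labels = c("a", "b")), "align")
})

test_that("attractor rule: control Baseline, PC1 shift Toxic, PC2 shift Adaptive", {
  shift <- function(readouts, by = 5) function(cond, r)
    if (cond == "Hb" && r %in% readouts) by else 0
  # +5 SD on the toxicity readouts only -> Toxic
  df1 <- toy_pool_df(conditions = c("Ctrl", "Hb"), n_per_cell = 30,
                     mean_fun = shift(c("fe58", "mda", "cell_death")),
                     seed = 31)
  st1 <- boot_pca(readout_pools(df1), B = 200, seed = 8)$states
  expect_equal(st1$state[st1$condition == "Ctrl"], "Baseline")
  expect_equal(st1$state[st1$condition == "Hb"], "Toxic")
  # +5 SD on heme_metab only -> Adaptive; a toxin condition anchors PC1
  mean_fun2 <- function(cond, r) {
    if (cond == "HemeAlb" && r %in% c("fe58", "mda", "cell_death",
                                      "heme_stress")) return(5)
    if (cond == "HbHp" && r == "heme_metab") return(5)
    0
  }
  df2 <- toy_pool_df(conditions = c("Ctrl", "HemeAlb", "HbHp"),
                     n_per_cell = 30, mean_fun = mean_fun2, seed = 32)
  st2 <- boot_pca(readout_pools(df2), B = 200, seed = 9)$states
  expect_equal(st2$state[st2$condition == "HbHp"], "Adaptive")
  expect_equal(st2$state[st2$condition == "HemeAlb"], "Toxic")
  # no shift -> treated condition overlaps control: Sequestered
  df3 <- toy_pool_df(conditions = c("Ctrl", "Hb"), n_per_cell = 30,
                     mean_fun = function(cond, r) 0, seed = 33)
  st3 <- boot_pca(readout_pools(df3), B = 200, seed = 10)$states
  expect_equal(st3$state[st3$condition == "Hb"], "Sequestered")
  expect_error(classify_attractors(
    boot_pca(readout_pools(df3), B = 50, seed = 1, control = NULL)$centroids,
    "Missing"), "not present")
})

test_that("same seed reproduces the fit bit for bit; seeds only jitter centroids", {
  pools <- pools_from_presets(seed = 3)
  f1 <- boot_pca(pools, B = 250, seed = 12)
  f2 <- boot_pca(pools, B = 250, seed = 12)
  expect_identical(f1$centroids, f2$centroids)
  f3 <- boot_pca(pools, B = 250, seed = 13)
  half_width <- (f1$centroids$pc1_hi - f1$centroids$pc1_lo) / 2
  expect_true(all(abs(f1$centroids$pc1_mean - f3$centroids$pc1_mean) <
                    half_width))
})

test_that("between-condition separation grows with effect size", {
  sep_ratio <- function(effect) {
    mean_fun <- function(cond, r)
      if (cond %in% c("Hb", "HemeAlb") && r != "heme_metab") effect else 0
    df <- toy_pool_df(n_per_cell = 20, mean_fun = mean_fun, seed = 41)
    ps <- make_pseudoslices(readout_pools(df), B = 100, seed = 14)
    v <- ps$values[, "fe58"]
    grand <- mean(v)
    groups <- split(v, ps$condition_labels)
    between <- sum(vapply(groups, function(g)
      length(g) * (mean(g) - grand)^2, numeric(1)))
    within <- sum(vapply(groups, function(g)
      sum((g - mean(g))^2), numeric(1)))
    between / within
  }
  ratios <- vapply(c(0, 1, 3, 6), sep_ratio, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("preset fit reproduces the qualitative toxicity/adaptation structure", {
  pools <- pools_from_presets(seed = 4)
  fit <- boot_pca(pools, B = 250, seed = 15)
  L <- coef(fit)
  tox <- c("fe58", "mda", "cell_death", "heme_stress")
  expect_true(all(L[tox, "PC1"] > 0))
  expect_equal(rownames(L)[which.max(abs(L[, "PC2"]))], "heme_metab")
  cen <- fit$centroids
  top2 <- cen$condition[order(-cen$pc1_mean)][1:2]
  expect_setequal(top2, c("Hb", "HemeAlb"))
  expect_equal(cen$condition[which.max(cen$pc2_mean)], "HbHp")
  d_ctrl <- sqrt((cen$pc1_mean - cen$pc1_mean[cen$condition == "Ctrl"])^2 +
                   (cen$pc2_mean - cen$pc2_mean[cen$condition == "Ctrl"])^2)
  treated <- cen$condition != "Ctrl"
  expect_equal(cen$condition[treated][which.min(d_ctrl[treated])], "HemeHpx")
})

test_that("predict projects new observations with the stored scaling", {
  fit <- boot_pca(pools_from_presets(seed = 5), B = 50, seed = 16)
  # projecting the training rows returns the fitted scores
  raw <- sweep(sweep(fit$pseudoslices$values, 2, fit$pca$column_sds, "*"),
               2, fit$pca$column_means, "+")
  expect_equal(predict(fit, raw), fit$pca$scores, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(predict(fit), fit$pca$scores)
})
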