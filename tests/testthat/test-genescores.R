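make_counts <- function(g = 50, n = 6, seed = 1, mu = 100, size = 10) {
  set.seed(seed)
  matrix(rnbinom(g * n, mu = mu, size = size), g, n,
         dimnames = list(sprintf("g%03d", 1:g), sprintf("s%02d", 1:n)))
}

test_that("vst size factors follow the median-of-ratios definition", {
  x <- make_counts(50, 4, seed = 2)
  v <- vst_counts(x)
  sf <- attr(v, "size_factors")
  # hand-computed median-of-ratios on the same matrix
  geo <- exp(rowMeans(log(x)))
  hand <- apply(x, 2, function(cnt) exp(median(log(cnt / geo))))
  expect_equal(unname(sf), unname(hand))
  expect_equal(v, log2(sweep(x, 2, sf, "/") + 1), ignore_attr = TRUE)

  # identical columns: factors all 1, identical transformed columns
  y <- cbind(a = x[, 1], b = x[, 1], c = x[, 1])
  vy <- vst_counts(y)
  expect_equal(unname(attr(vy, "size_factors")), c(1, 1, 1))
  expect_equal(vy[, "a"], vy[, "b"], ignore_attr = TRUE)

  # doubling one sample's counts doubles its size factor relative to the
  # others (the shared geometric-mean reference shifts all factors alike)
  z <- x; z[, 1] <- z[, 1] * 2L
  sfz <- attr(vst_counts(z), "size_factors")
  expect_equal(unname(sfz[1] / sfz[-1]), unname(2 * sf[1] / sf[-1]))

  # all-zero gene row passes through as zeros
  w <- rbind(x, zero = 0L)
  expect_true(all(vst_counts(w)["zero", ] == 0))
  expect_error(vst_counts(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("vst size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  x <- make_counts(200, 8, seed = 3)
  sf <- attr(vst_counts(x), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(x)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("rank_de reproduces stats::t.test gene by gene", {
  x <- vst_counts(make_counts(30, 8, seed = 4))
  grp <- rep(c("Ctrl", "Trt"), each = 4)
  de <- rank_de(x, grp, treatment = "Trt", control = "Ctrl")
  expect_equal(nrow(de), 30)
  expect_true(all(de$adj_p >= de$p_value))
  for (i in c(1, 7, 19, 30)) {
    tt <- t.test(x[i, grp == "Trt"], x[i, grp == "Ctrl"])
    expect_equal(de$p_value[i], tt$p.value)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))))
  }
  expect_equal(de$adj_p, p.adjust(de$p_value, "BH"))
})

test_that("rank_de is invariant to sample order and guards group sizes", {
  x <- vst_counts(make_counts(20, 10, seed = 5))
  grp <- rep(c("A", "B"), each = 5)
  de1 <- rank_de(x, grp)
  perm <- c(sample(1:5), sample(6:10))
  de2 <- rank_de(x[, perm], grp[perm])
  expect_equal(de1, de2)
  expect_error(rank_de(x[, 1:6], c(rep("A", 5), "B")), "at least 2")
  expect_error(rank_de(x, rep("A", 10)), "two groups")
})

test_that("score-set construction takes the top-k up genes deterministically", {
  set.seed(6)
  n <- 200
  de <- data.frame(gene = sprintf("g%03d", 1:n),
                   log2fc = c(runif(120, 0.5, 4), runif(80, -3, 0)),
                   adj_p = c(rep(1e-4, 120), rep(0.5, 80)))
  de$p_value <- de$adj_p
  s <- build_score_set(de, k = 50)
  expect_length(s, 50)
  # the k genes are the 50 largest significant positive fold changes
  up <- de[de$adj_p < 0.05 & de$log2fc > 0, ]
  expect_setequal(s, up$gene[order(-up$log2fc)][1:50])
  # k = 1 is the argmax
  expect_equal(build_score_set(de, k = 1), up$gene[which.max(up$log2fc)])
  # row shuffling changes nothing
  expect_identical(build_score_set(de[sample(n), ], k = 50), s)
})

test_that("fold-change ties at the boundary break lexicographically", {
  de <- data.frame(gene = c("gB", "gA", "gC"),
                   log2fc = c(2, 2, 3), adj_p = c(1e-3, 1e-3, 1e-3))
  expect_equal(build_score_set(de, k = 2), c("gC", "gA"))
})

test_that("an underpowered DE table reports the attainable count", {
  de <- data.frame(gene = c("g1", "g2"), log2fc = c(1, -1),
                   adj_p = c(0.01, 0.01))
  expect_error(build_score_set(de, k = 50), "only 1 significant")
})

test_that("per-sample scores are means over the gene rows", {
  x <- vst_counts(make_counts(10, 4, seed = 7))
  s1 <- score_samples(x, rownames(x)[3])
  expect_equal(unname(s1$score), unname(x[3, ]))
  # constant rows score the constant
  xc <- x; xc[1, ] <- 5; xc[2, ] <- 5
  sc <- score_samples(xc, rownames(x)[1:2])
  expect_true(all(sc$score == 5))
  # duplicating an identically valued gene leaves the mean unchanged
  xd <- rbind(x, dup = x[3, ])
  expect_equal(unname(score_samples(xd, c(rownames(x)[3], "dup"))$score),
               unname(x[3, ]))
  expect_error(score_samples(x, c("g001", "missing")), "missing")
})

test_that("score correlation is symmetric, affine-invariant, near 0 under independence", {
  x <- vst_counts(make_counts(10, 20, seed = 8))
  s1 <- score_samples(x, rownames(x)[1:3], "a")
  s2 <- s1; s2$score <- 2 * s1$score + 1; s2$set_name <- "b"
  expect_equal(score_correlation(s1, s2), 1)
  expect_equal(score_correlation(s1, s2), score_correlation(s2, s1))
  # independent noise: average r^2 over replicates ~ 1/(n-1)
  set.seed(9)
  r2 <- replicate(200, {
    sa <- s1; sa$score <- rnorm(20); names(sa$score) <- names(s1$score)
    score_correlation(s1, sa)
  })
  expect_lt(mean(r2), 0.12)
  s3 <- s1; names(s3$score)[1] <- "other"
  expect_error(score_correlation(s1, s3), "different sample sets")
})

test_that("shared-driver scores correlate above disjoint random sets", {
  x <- generate_counts(synthetic_count_design(
    n_genes = 1000, samples_per_condition = 6, library_size = 1e5,
    program_gene_counts = c(heme_stress = 100, heme_metab = 60), seed = 10))
  v <- vst_counts(x$counts)
  hs <- x$truth$gene[x$truth$program == "heme_stress"]
  stress <- score_samples(v, hs[1:50], "heme_stress")
  nrf2 <- score_samples(v, hs[51:100], "nrf2")
  r2_driven <- score_correlation(stress, nrf2)
  none <- x$truth$gene[x$truth$program == "none"]
  set.seed(11)
  r2_random <- score_correlation(
    score_samples(v, sample(none, 50), "rand1"),
    score_samples(v, sample(setdiff(none, hs), 50), "rand2"))
  expect_gt(r2_driven, 0.9)
  expect_gt(r2_driven, r2_random)
})

test_that("GMT round trip preserves gene sets", {
  sets <- list(heme_stress = c("Nqo1", "Gclm", "Gstm1"),
               iron_transport = c("Slc48a1", "Slc40a1"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back, sets)
})
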