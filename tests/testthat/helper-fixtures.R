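# Shared fixtures, all built in code.

# Long-format pool table with constant values per (condition, readout).
toy_pool_df <- function(conditions = hemoscape_conditions(),
                        readouts = hemoscape_readouts(),
                        n_per_cell = 10, mean_fun = NULL, seed = 42) {
  if (is.null(mean_fun)) mean_fun <- function(cond, r) 0
  set.seed(seed)
  do.call(rbind, lapply(conditions, function(cond)
    do.call(rbind, lapply(readouts, function(r)
      data.frame(condition = cond, readout = r,
                 value = rnorm(n_per_cell, mean_fun(cond, r), 1),
                 stringsAsFactors = FALSE)))))
}

# Two clearly separated synthetic cell populations in log-feature space.
toy_cells <- function(n_apo, n_via, seed = 1,
                      apo = c(neun = 800, casp3 = 12000),
                      via = c(neun = 12000, casp3 = 800), sd_log = 0.05) {
  set.seed(seed)
  n <- n_apo + n_via
  truth <- rep(c("apoptotic", "viable"), c(n_apo, n_via))
  neun <- 10^(log10(ifelse(truth == "apoptotic", apo["neun"], via["neun"])) +
                rnorm(n, 0, sd_log))
  casp3 <- 10^(log10(ifelse(truth == "apoptotic", apo["casp3"], via["casp3"])) +
                 rnorm(n, 0, sd_log))
  data.frame(cell_id = seq_len(n), row = 0, col = 0, area = 50L,
             neun_mean = neun, casp3_mean = casp3,
             log_neun = log10(neun + 1), log_casp3 = log10(casp3 + 1),
             label = "unassigned", truth = truth,
             stringsAsFactors = FALSE)
}

# Exhaustive best 2-partition by within-cluster sum of squares (k-means
# oracle, feasible for <= 12 points).
best_two_partition <- function(x) {
  n <- nrow(x)
  best <- NULL
  best_ss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {  # fix point 1 in cluster 0; skip empty
    assign <- as.integer(intToBits(code))[seq_len(n)]
    if (all(assign == assign[1])) next
    ss <- 0
    for (g in 0:1) {
      xg <- x[assign == g, , drop = FALSE]
      ss <- ss + sum(sweep(xg, 2, colMeans(xg))^2)
    }
    if (ss < best_ss) { best_ss <- ss; best <- assign }
  }
  list(assignment = best, withinss = best_ss)
}
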