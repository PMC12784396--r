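# Transcriptional stress/adaptation scoring: a minimal, documented
# differential-expression ranker (Welch t on variance-stabilized values
# with Benjamini-Hochberg correction — a deliberate lightweight stand-in
# for a full shrinkage-based DE model), top-K up-regulated set
# construction, and per-sample mean-VST gene-set scores.

#' Variance-stabilizing transform of a count matrix
#'
#' Median-of-ratios size-factor normalization (reference = per-gene
#' geometric mean over genes expressed in every sample) followed by
#' `log2(normalized + 1)`. All-zero gene rows pass through as zeros.
#'
#' @param counts Non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @return Numeric matrix of the same shape with a `"size_factors"`
#'   attribute (one factor per sample).
#' @export
vst_counts <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0L || ncol(counts) == 0L)
    stop("'counts' must be a non-empty matrix", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers", call. = FALSE)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("no gene is expressed in every sample; size factors undefined",
         call. = FALSE)
  log_geo <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(cnt)
    exp(stats::median(log(cnt) - log_geo)))
  norm <- sweep(counts, 2, sf, "/")
  out <- log2(norm + 1)
  attr(out, "size_factors") <- sf
  out
}

#' Rank genes by differential expression between two groups
#'
#' Per-gene Welch t-test on variance-stabilized values with
#' Benjamini-Hochberg adjustment; `log2fc` is the treatment-minus-control
#' group-mean difference (VST values are on the log2 scale). This is a
#' minimal DE ranker intended for score-set construction, not a
#' replacement for a count-based DE model.
#'
#' @param x VST matrix from [vst_counts()] (genes x samples).
#' @param groups Character/factor of length `ncol(x)` with exactly two
#'   levels; each group needs `>= 2` samples.
#' @param treatment,control Which group label is which; default: `control`
#'   is the first sorted level, `treatment` the second.
#' @return `data.frame` with one row per gene: `gene`, `log2fc`,
#'   `p_value`, `adj_p` (BH), `mean_expr`.
#' @export
rank_de <- function(x, groups, treatment = NULL, control = NULL) {
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("'groups' must contain exactly two groups", call. = FALSE)
  if (is.null(control)) control <- lev[1]
  if (is.null(treatment)) treatment <- setdiff(lev, control)
  stopifnot(treatment %in% lev, control %in% lev, treatment != control)
  it <- groups == treatment
  ic <- groups == control
  n1 <- sum(it); n2 <- sum(ic)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (treatment has ", n1,
         ", control has ", n2, ")", call. = FALSE)

  xt <- x[, it, drop = FALSE]
  xc <- x[, ic, drop = FALSE]
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  v1 <- rowSums((xt - m1)^2) / (n1 - 1)
  v2 <- rowSums((xc - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  # degenerate rows: zero variance in both groups
  flat <- se2 == 0
  p[flat] <- ifelse(m1[flat] == m2[flat], 1, .Machine$double.xmin)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(gene = rownames(x),
             log2fc = m1 - m2,
             p_value = p,
             adj_p = stats::p.adjust(p, method = "BH"),
             mean_expr = rowMeans(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a top-K regulated gene set from a DE ranking
#'
#' Filters to `adj_p < adj_p_cutoff` with positive (`direction = "up"`) or
#' negative (`"down"`) `log2fc`, sorts by absolute fold change descending
#' (ties broken by lexicographic gene identifier), and takes the first
#' `k`. The default k = 50 reproduces the "top 50 up-regulated DEGs"
#' construction of the heme response score.
#'
#' @param de DE table from [rank_de()].
#' @param k Set size, default 50.
#' @param direction `"up"` (default) or `"down"`.
#' @param adj_p_cutoff BH-adjusted significance threshold, default 0.05.
#' @return Character vector of exactly `k` gene identifiers.
#' @export
build_score_set <- function(de, k = 50, direction = c("up", "down"),
                            adj_p_cutoff = 0.05) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "adj_p") %in% names(de)),
            k >= 1)
  sig <- de$adj_p < adj_p_cutoff &
    (if (direction == "up") de$log2fc > 0 else de$log2fc < 0)
  cand <- de[sig, , drop = FALSE]
  if (nrow(cand) < k)
    stop("only ", nrow(cand), " significant ", direction,
         "-regulated genes available; cannot build a set of size ", k,
         call. = FALSE)
  key <- if (direction == "up") -cand$log2fc else cand$log2fc
  cand <- cand[order(key, cand$gene), , drop = FALSE]
  cand$gene[seq_len(k)]
}

#' Score samples by mean variance-stabilized expression over a gene set
#'
#' @param x VST matrix (genes x samples).
#' @param genes Non-empty character vector of gene identifiers; all must
#'   be rows of `x`.
#' @param set_name Label for the score
#'   (e.g. `heme_stress`, `nrf2`, `heme_metab`, `iron_transport`).
#' @return Object of class `"gene_set_score"`: list with `set_name`,
#'   `genes`, and `score` (named per-sample numeric).
#' @export
score_samples <- function(x, genes, set_name = "score") {
  stopifnot(is.matrix(x), length(genes) >= 1L)
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0L)
    stop("genes absent from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(set_name = set_name, genes = genes,
                 score = colMeans(x[genes, , drop = FALSE])),
            class = "gene_set_score")
}

#' @export
print.gene_set_score <- function(x, ...) {
  cat(sprintf("Gene-set score '%s' (%d genes, %d samples)\n",
              x$set_name, length(x$genes), length(x$score)))
  print(round(x$score, 3))
  invisible(x)
}

#' Squared Pearson correlation between two gene-set scores
#'
#' @param s1,s2 [score_samples()] results over the identical sample set
#'   (`>= 3` samples).
#' @return r^2, the squared Pearson correlation of the per-sample scores.
#' @export
score_correlation <- function(s1, s2) {
  stopifnot(inherits(s1, "gene_set_score"), inherits(s2, "gene_set_score"))
  if (!setequal(names(s1$score), names(s2$score)))
    stop("scores cover different sample sets", call. = FALSE)
  if (length(s1$score) < 3L)
    stop("correlation needs at least 3 samples", call. = FALSE)
  stats::cor(s1$score, s2$score[names(s1$score)])^2
}

#' Read or write gene sets in GMT format
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors (gene sets).
#' @param description Second-column description written for each set.
#' @return `read_gmt()`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
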