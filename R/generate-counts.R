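#' Specify a synthetic RNA-seq count matrix with spiked gene programs
#'
#' Negative-binomial counts for five exposure conditions, with two disjoint
#' gene programs shifted by per-condition log2 fold changes: a heme-stress
#' program (oxidative-stress response) and a heme-metabolism program
#' (Nrf2-driven adaptation). The default fold-change table encodes the
#' ordinal structure seen across conditions — heme stress:
#' HemeHpx < Ctrl < HemeAlb < Hb < HbHp; heme metabolism elevated only for
#' HbHp — with absolute effect sizes chosen here (they are not published).
#'
#' @param n_genes Total genes.
#' @param samples_per_condition Samples per condition, `>= 2`.
#' @param library_size Expected total counts per sample.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param program_gene_counts Named integer vector, sizes of the
#'   `heme_stress` and `heme_metab` programs, each `>= 50`.
#' @param program_log2fc Conditions x programs numeric matrix of log2 fold
#'   changes relative to baseline expression.
#' @param conditions Condition labels (rows of `program_log2fc`).
#' @param seed Integer seed used by [generate_counts()].
#' @return A list of class `"synthetic_count_design"`.
#' @export
synthetic_count_design <- function(n_genes = 4000,
                                   samples_per_condition = 8,
                                   library_size = 2e5,
                                   dispersion = 0.1,
                                   program_gene_counts = c(heme_stress = 100,
                                                           heme_metab = 100),
                                   program_log2fc = NULL,
                                   conditions = hemoscape_conditions(),
                                   seed = 1L) {
  if (is.null(program_log2fc)) {
    program_log2fc <- cbind(
      heme_stress = c(Ctrl = 0, HemeAlb = 1.5, HemeHpx = -0.5,
                      Hb = 2.0, HbHp = 2.5),
      heme_metab  = c(Ctrl = 0, HemeAlb = 0, HemeHpx = 0,
                      Hb = 0, HbHp = 2.0))[conditions, , drop = FALSE]
  }
  program_log2fc <- as.matrix(program_log2fc)
  stopifnot(n_genes >= 1, samples_per_condition >= 2,
            library_size > 0, dispersion > 0)
  if (!all(c("heme_stress", "heme_metab") %in% names(program_gene_counts)))
    stop("'program_gene_counts' must name heme_stress and heme_metab",
         call. = FALSE)
  if (any(program_gene_counts < 50))
    stop("each gene program must contain at least 50 genes", call. = FALSE)
  if (sum(program_gene_counts) > n_genes)
    stop("programs exceed 'n_genes'; gene sets would overlap", call. = FALSE)
  if (!identical(rownames(program_log2fc), conditions) ||
      !identical(colnames(program_log2fc), c("heme_stress", "heme_metab")))
    stop("'program_log2fc' must have rows = conditions and columns ",
         "heme_stress, heme_metab", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 samples_per_condition = as.integer(samples_per_condition),
                 library_size = library_size,
                 dispersion = dispersion,
                 program_gene_counts = program_gene_counts,
                 program_log2fc = program_log2fc,
                 conditions = conditions,
                 seed = as.integer(seed)),
            class = "synthetic_count_design")
}

#' Generate a negative-binomial count matrix with known truth
#'
#' Baseline per-gene means are log-normal and scaled so the expected
#' column sum equals `library_size`; program genes are multiplied by
#' `2^log2fc` in each condition; counts are NB with the design dispersion.
#'
#' @param design A [synthetic_count_design()].
#' @return List with `counts` (genes x samples integer matrix), `samples`
#'   (sample sheet: `sample`, `condition`), and `truth` (`gene`, `program`
#'   in `none`/`heme_stress`/`heme_metab`).
#' @examples
#' d <- synthetic_count_design(n_genes = 500, samples_per_condition = 3,
#'                             library_size = 5e4, seed = 7)
#' x <- generate_counts(d)
#' dim(x$counts)
#' @export
generate_counts <- function(design) {
  stopifnot(inherits(design, "synthetic_count_design"))
  with_seed(design$seed, {
    g <- design$n_genes
    genes <- sprintf("gene%05d", seq_len(g))
    program <- rep("none", g)
    n_hs <- design$program_gene_counts[["heme_stress"]]
    n_hm <- design$program_gene_counts[["heme_metab"]]
    program[seq_len(n_hs)] <- "heme_stress"
    program[n_hs + seq_len(n_hm)] <- "heme_metab"

    base <- exp(stats::rnorm(g, log(50), 1))
    base <- base / sum(base) * design$library_size

    conds <- design$conditions
    m <- design$samples_per_condition
    sample_cond <- rep(conds, each = m)
    sample_ids <- paste0(sample_cond, "_", rep(seq_len(m), times = length(conds)))

    counts <- matrix(0L, g, length(sample_ids),
                     dimnames = list(genes, sample_ids))
    size <- 1 / design$dispersion
    for (j in seq_along(sample_ids)) {
      lfc <- design$program_log2fc[sample_cond[j], ]
      mu <- base
      mu[program == "heme_stress"] <- mu[program == "heme_stress"] *
        2^lfc[["heme_stress"]]
      mu[program == "heme_metab"] <- mu[program == "heme_metab"] *
        2^lfc[["heme_metab"]]
      counts[, j] <- stats::rnbinom(g, mu = mu, size = size)
    }
    list(counts = counts,
         samples = data.frame(sample = sample_ids, condition = sample_cond,
                              stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, program = program,
                            stringsAsFactors = FALSE))
  })
}
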