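#' Simulate a two-group RNA-seq count matrix with spiked differential genes
#'
#' Negative-binomial gene counts for two groups, with a fixed fraction of
#' genes truly differential: those genes have their group-2 mean multiplied
#' by `2^effect_log2`. Baseline means are drawn lognormally, giving the
#' heavy-tailed abundance spectrum typical of RNA-seq. The number of
#' differential genes is exact (`round(frac_de * n_genes)`); their identity
#' is a seeded random draw. Truth labels are returned so realized FDR and
#' recall can be evaluated downstream.
#'
#' @param n_genes number of genes.
#' @param group_sizes integer vector of two group sizes, each >= 2 (the CPM
#'   filter requires at least two samples per group).
#' @param frac_de fraction of genes truly differential, in \[0, 1\].
#' @param effect_log2 log2 fold change applied to group 2 for DE genes.
#' @param dispersion NB dispersion (1/size); must be > 0.
#' @param mean_log_mu mean of log baseline expression (natural log scale).
#' @param seed integer seed.
#' @return list of class `sim_counts`: `counts` (genes x samples integer
#'   matrix with dimnames), `group` (factor `control`/`treated`), `true_de`
#'   (logical per gene), plus the generator parameters.
#' @examples
#' sc <- simulate_counts(n_genes = 100, seed = 1)
#' sum(sc$true_de)  # exactly 10
#' @export
simulate_counts <- function(n_genes, group_sizes = c(3, 3), frac_de = 0.1,
                            effect_log2 = 2, dispersion = 0.1,
                            mean_log_mu = 5, seed = 1) {
  stopifnot(n_genes >= 1, length(group_sizes) == 2, all(group_sizes >= 2),
            frac_de >= 0, frac_de <= 1)
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  with_seed(seed, {
    n1 <- group_sizes[1]; n2 <- group_sizes[2]
    mu0 <- exp(stats::rnorm(n_genes, mean_log_mu, 1.5))
    n_de <- round(frac_de * n_genes)
    true_de <- logical(n_genes)
    if (n_de > 0) true_de[sample.int(n_genes, n_de)] <- TRUE
    mu2 <- mu0 * ifelse(true_de, 2^effect_log2, 1)
    size <- 1 / dispersion
    counts <- cbind(
      matrix(stats::rnbinom(n_genes * n1, mu = rep(mu0, n1), size = size),
             nrow = n_genes),
      matrix(stats::rnbinom(n_genes * n2, mu = rep(mu2, n2), size = size),
             nrow = n_genes)
    )
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(
      sprintf("gene%05d", seq_len(n_genes)),
      c(sprintf("ctrl_%d", seq_len(n1)), sprintf("trt_%d", seq_len(n2)))
    )
    structure(list(counts = counts,
                   group = factor(rep(c("control", "treated"), c(n1, n2)),
                                  levels = c("control", "treated")),
                   true_de = true_de,
                   frac_de = frac_de, effect_log2 = effect_log2,
                   dispersion = dispersion, seed = seed),
              class = "sim_counts")
  })
}
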