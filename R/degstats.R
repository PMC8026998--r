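#' Counts per million
#'
#' Library-size normalization: each count divided by its sample's total
#' counts, times one million. Columns of the result sum to 1e6.
#'
#' @param counts nonnegative genes x samples matrix (or a
#'   [simulate_counts()] object, whose matrix is used).
#' @return matrix of CPM values, same dimnames.
#' @export
cpm <- function(counts) {
  if (inherits(counts, "sim_counts")) counts <- counts$counts
  stopifnot(is.matrix(counts), all(counts >= 0))
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libs == 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2, libs, "/") * 1e6
}

#' Filter genes on a CPM threshold
#'
#' Retains genes with CPM strictly greater than `min_cpm` in at least
#' `min_samples` samples within at least one group — the standard expression
#' filter before differential testing (defaults: > 1 CPM in >= 2 samples of
#' one group). The filter is idempotent and preserves gene order.
#'
#' @param counts genes x samples count matrix (or [simulate_counts()]
#'   object).
#' @param group factor of two group labels per sample (taken from the
#'   `sim_counts` object if omitted).
#' @param min_cpm CPM threshold (strict inequality).
#' @param min_samples required samples above threshold within one group.
#' @return the count matrix restricted to the retained genes; attribute
#'   `kept` holds the logical keep mask over the input genes.
#' @export
filter_genes <- function(counts, group = NULL, min_cpm = 1, min_samples = 2) {
  if (inherits(counts, "sim_counts")) {
    if (is.null(group)) group <- counts$group
    counts <- counts$counts
  }
  group <- as.factor(group)
  stopifnot(ncol(counts) == length(group))
  if (any(table(group) < min_samples)) {
    stop(sprintf("each group needs >= %d samples", min_samples), call. = FALSE)
  }
  cpm_m <- cpm(counts)
  keep <- Reduce(`|`, lapply(levels(group), function(g) {
    rowSums(cpm_m[, group == g, drop = FALSE] > min_cpm) >= min_samples
  }))
  structure(counts[keep, , drop = FALSE], kept = keep)
}

# Row-wise equal-variance two-sample t statistics; constant rows give t = 0.
row_t_stats <- function(x, i1, i2) {
  n1 <- length(i1); n2 <- length(i2)
  x1 <- x[, i1, drop = FALSE]; x2 <- x[, i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, (m2 - m1) / se, 0)
  list(t = t, diff = m2 - m1)
}

#' Permutation-FDR two-sample t test
#'
#' Per-gene two-tailed equal-variance Student's t on log2 expression, with
#' significance calibrated by label permutations to a target false discovery
#' rate (defaults: FDR < 0.05, 250 randomizations). The |t| cutoff `c` is the
#' smallest observed |t| whose estimated FDR does not exceed the target,
#' where `FDR(c) = mean over permutations of #(null |t| >= c) /
#' max(1, #(observed |t| >= c))`. Genes at or above the cutoff are flagged
#' significant; the significant set is monotone in the FDR target.
#'
#' Permutations are drawn without replacement from the space of distinct
#' group assignments; when that space is no larger than `n_perm` (e.g. 20
#' assignments at 3 vs 3), all assignments except the identity are
#' enumerated instead of sampled.
#'
#' @param x genes x samples matrix of log2 expression (e.g.
#'   `log2(cpm(counts) + 1)`), or a raw count matrix with
#'   `input = "counts"` to apply that transform internally.
#' @param group two-level factor per sample.
#' @param n_perm number of label permutations.
#' @param fdr target false discovery rate.
#' @param seed integer seed.
#' @param input `"log2"` (default) or `"counts"`.
#' @return data frame of class `de_result`: `gene`, `t`, `mean_log2_diff`
#'   (second group minus first), `significant`; attributes `threshold_used`,
#'   `fdr_target`, `n_perm`, `n_perm_used`.
#' @export
perm_fdr_ttest <- function(x, group, n_perm = 250, fdr = 0.05, seed = 1,
                           input = c("log2", "counts")) {
  input <- match.arg(input)
  if (inherits(x, "sim_counts")) {
    if (missing(group)) group <- x$group
    x <- log2(cpm(x$counts) + 1)
  } else if (input == "counts") {
    x <- log2(cpm(x) + 1)
  }
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2, ncol(x) == length(group), n_perm >= 1)
  if (any(table(group) < 2)) stop("need >= 2 samples per group", call. = FALSE)
  i1 <- which(group == levels(group)[1])
  i2 <- which(group == levels(group)[2])
  N <- ncol(x); n1 <- length(i1)
  obs <- row_t_stats(x, i1, i2)
  abs_obs <- abs(obs$t)

  # Distinct-assignment space. The two-sided |t| is invariant under swapping
  # the two group labels, so for equal group sizes assignments are reduced to
  # partitions (complementary assignments collapse); the identity partition
  # is always excluded. Without this reduction the mirrored identity would
  # re-inject every observed |t| into the null pool and the estimated FDR
  # could never fall below 1/n_assignments at small n.
  total <- if (n1 == N - n1) choose(N, n1) / 2 else choose(N, n1)
  assignments <- with_seed(seed, {
    if (total <= 2e5) {
      all_c <- utils::combn(N, n1)
      if (n1 == N - n1) {
        all_c <- all_c[, all_c[1, ] == 1L, drop = FALSE]  # one per partition
        id <- sort(if (1L %in% i1) i1 else setdiff(seq_len(N), i1))
      } else {
        id <- sort(i1)
      }
      keep <- apply(all_c, 2, function(cc) !all(cc == id))
      all_c <- all_c[, keep, drop = FALSE]
      if (ncol(all_c) > n_perm) {
        all_c <- all_c[, sample.int(ncol(all_c), n_perm), drop = FALSE]
      }
      all_c
    } else {
      # space too large to enumerate: independent random draws (collision
      # probability negligible)
      vapply(seq_len(n_perm), function(i) sort(sample.int(N, n1)),
             integer(n1))
    }
  })
  n_used <- ncol(assignments)
  null_abs <- unlist(lapply(seq_len(n_used), function(j) {
    ia <- assignments[, j]
    abs(row_t_stats(x, ia, setdiff(seq_len(N), ia))$t)
  }))
  null_sorted <- sort(null_abs)

  ord <- order(abs_obs, decreasing = TRUE)
  cand <- abs_obs[ord]                      # cutoff candidates, descending
  n_null <- length(null_sorted)
  null_ge <- n_null - findInterval(cand - 1e-12, null_sorted)
  est_fdr <- (null_ge / n_used) / pmax(1, seq_along(cand))
  ok <- which(est_fdr <= fdr)
  if (length(ok)) {
    k <- max(ok)                            # smallest qualifying cutoff
    threshold <- cand[k]
    significant <- abs_obs >= threshold - 1e-12
  } else {
    threshold <- Inf
    significant <- rep(FALSE, length(abs_obs))
  }
  out <- data.frame(gene = rownames(x) %||% seq_len(nrow(x)),
                    t = obs$t, mean_log2_diff = obs$diff,
                    significant = significant, row.names = NULL)
  structure(out, threshold_used = threshold, fdr_target = fdr,
            n_perm = n_perm, n_perm_used = n_used,
            class = c("de_result", "data.frame"))
}

#' Relative qPCR expression by the delta-delta-CT method
#'
#' Per sample, `dCT = CT(target) - CT(reference)` against the housekeeping
#' gene; per group, `ddCT = mean dCT(group) - mean dCT(control group)` and
#' fold change `2^(-ddCT)`. Technical duplicates (repeated `sample_id`) are
#' averaged before analysis. A per-sample fold-change table (each sample's
#' dCT referenced to the control-group mean) is also returned for
#' nonparametric testing, e.g. with [mann_whitney()].
#'
#' @param records data frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @param control_group label of the reference group.
#' @return list of class `ddct_result`: `groups` (`group`, `n`, `mean_dct`,
#'   `ddct`, `fold_change`) and `samples` (`sample_id`, `group`, `dct`,
#'   `fold_change`).
#' @examples
#' recs <- data.frame(sample_id = c("c1", "c2", "t1", "t2"),
#'                    group = c("control", "control", "treated", "treated"),
#'                    ct_target = c(20, 20, 19, 19),
#'                    ct_reference = 15)
#' delta_delta_ct(recs, "control")$groups  # treated fold change 2
#' @export
delta_delta_ct <- function(records, control_group) {
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(records$ct_reference) || anyNA(records$ct_target)) {
    stop("missing CT value (target or reference)", call. = FALSE)
  }
  if (!control_group %in% records$group) {
    stop(sprintf("control group '%s' not present", control_group), call. = FALSE)
  }
  # average technical duplicates per sample
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ sample_id + group,
                          data = records, FUN = mean)
  agg$dct <- agg$ct_target - agg$ct_reference
  mean_dct <- tapply(agg$dct, agg$group, mean)
  ctrl <- mean_dct[[control_group]]
  groups <- data.frame(group = names(mean_dct),
                       n = as.vector(table(agg$group)[names(mean_dct)]),
                       mean_dct = as.vector(mean_dct),
                       ddct = as.vector(mean_dct) - ctrl,
                       row.names = NULL)
  groups$fold_change <- 2^(-groups$ddct)
  samples <- data.frame(sample_id = agg$sample_id, group = agg$group,
                        dct = agg$dct, fold_change = 2^(-(agg$dct - ctrl)))
  structure(list(groups = groups, samples = samples,
                 control_group = control_group),
            class = "ddct_result")
}
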