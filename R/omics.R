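#' Transcriptomic concordance and enrichment scoring
#'
#' Ranking of differentially expressed genes (DEGs), directional
#' concordance against signed reference marker sets, one-sided
#' Fisher's-exact over-representation with Bonferroni correction,
#' multi-condition cluster-comparison tables, row z-score matrices, a
#' stand-in differential-expression test for synthetic data, and the
#' plate/batch error-rate simulation.  Gene-level calls use
#' Benjamini-Hochberg FDR; set-level calls use Bonferroni, mirroring the
#' two conventions of the tools this module emulates.
#'
#' @name omics
NULL

#' Differential-expression table
#'
#' @param gene Unique gene identifiers.
#' @param log2fc Log2 fold-changes.
#' @param p Raw p-values in `[0, 1]`.
#' @param fdr Benjamini-Hochberg adjusted p-values; computed from `p` when
#'   omitted.
#' @return A `deg_table` data frame.
#' @export
deg_table <- function(gene, log2fc, p, fdr = NULL) {
  if (anyDuplicated(gene)) abort_input("gene identifiers must be unique")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort_input("p must lie in [0, 1]")
  fdr <- fdr %||% p.adjust(p, method = "BH")
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) abort_input("fdr must lie in [0, 1]")
  structure(data.frame(gene = as.character(gene), log2fc = log2fc,
                       p = p, fdr = fdr),
            class = c("deg_table", "data.frame"))
}

#' Signed marker gene set
#'
#' @param name Set name.
#' @param members Named integer vector: gene -> expected direction in
#'   `{-1, 0, +1}` (0 = direction unspecified).
#' @return A `marker_set`.
#' @export
marker_set <- function(name, members) {
  if (length(members) == 0L) abort_input("marker set '%s' is empty", name)
  if (is.null(names(members))) abort_input("members must be named by gene")
  if (!all(members %in% c(-1L, 0L, 1L)))
    abort_input("directions must be -1, 0 or +1")
  structure(list(name = name, members = members), class = "marker_set")
}

#' Top-N genes ranked by p-value
#'
#' Ascending p, ties broken by descending `|log2fc|` then gene id; the
#' ordering is a total order, so the result is invariant to input
#' shuffling.  `by = "expression"` instead ranks by a supplied mean
#' expression column (descending), for the alternative reading of
#' "highest expressed".
#'
#' @param table A [deg_table()] (optionally with a `mean_expr` column).
#' @param n Number of genes to return.
#' @param by `"p"` (default) or `"expression"`.
#' @return Character vector of gene ids, length `min(n, nrow(table))`.
#' @export
rank_top_genes <- function(table, n = 300L, by = c("p", "expression")) {
  by <- match.arg(by)
  if (nrow(table) == 0L) abort_input("empty DEG table")
  ord <- if (by == "p") {
    order(table$p, -abs(table$log2fc), table$gene)
  } else {
    if (is.null(table$mean_expr))
      abort_input("by = 'expression' needs a mean_expr column")
    order(-table$mean_expr, table$p, table$gene)
  }
  head(table$gene[ord], n)
}

#' Directional concordance of a DEG table with a reference marker set
#'
#' Counts, over the reference genes present in the table (`n_measured`):
#' `n_de` with `fdr < alpha`, and `n_directional` additionally matching
#' the expected sign (direction-0 members count if DE regardless of sign).
#' Percentages use `n_measured` as denominator; a set with no measured
#' member yields flagged `NA` percentages, not an error.
#'
#' @param table A [deg_table()].
#' @param ref A [marker_set()].
#' @param alpha FDR threshold for calling a gene DE.
#' @return A `concordance_result` list with the counts,
#'   `pct_overlap = 100 * n_de / n_measured` and
#'   `pct_directional = 100 * n_directional / n_measured`.
#' @export
concordance <- function(table, ref, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) abort_input("alpha must lie in (0, 1)")
  genes <- names(ref$members)
  idx <- match(genes, table$gene)
  measured <- !is.na(idx)
  n_measured <- sum(measured)
  de <- measured & table$fdr[idx] < alpha
  dir_ok <- de
  dir_ok[de] <- ref$members[de] == 0L |
    sign(table$log2fc[idx[de]]) == ref$members[de]
  res <- list(set_name = ref$name, n_ref = length(genes),
              n_measured = n_measured, n_de = sum(de),
              n_directional = sum(dir_ok),
              pct_overlap = if (n_measured) 100 * sum(de) / n_measured
                            else NA_real_,
              pct_directional = if (n_measured)
                100 * sum(dir_ok) / n_measured else NA_real_,
              no_measured_members = n_measured == 0L)
  structure(res, class = "concordance_result")
}

#' One-sided Fisher's-exact gene-set over-representation
#'
#' For each set, the hypergeometric upper tail `P(X >= k)` of the overlap
#' `k` between the query list (size `n`) and the set (size `K` within the
#' universe of size `N`), Bonferroni-corrected over the sets tested in
#' this call.  Rows are sorted by p.
#'
#' @param gene_list Character vector of query genes (must lie in the
#'   universe).
#' @param collection Named list of character vectors (gene sets), or of
#'   [marker_set()]s (directions ignored here).
#' @param universe Character vector of all assayed genes.
#' @return Data frame: term, k, K, n, N, gene_ratio, p, p_adj.
#' @export
enrich <- function(gene_list, collection, universe) {
  if (length(universe) == 0L) abort_input("empty universe")
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe))
    abort_input("gene list contains genes outside the universe")
  N <- length(universe)
  n <- length(gene_list)
  m <- length(collection)
  rows <- lapply(seq_len(m), function(i) {
    set <- collection[[i]]
    if (inherits(set, "marker_set")) set <- names(set$members)
    set <- intersect(set, universe)
    K <- length(set)
    k <- length(intersect(gene_list, set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = names(collection)[i] %||% as.character(i),
               k = k, K = K, n = n, N = N,
               gene_ratio = if (n) k / n else NA_real_, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Per-condition enrichment comparison table
#'
#' Runs [enrich()] for every condition's gene list and keeps rows with
#' `p_adj < p_cut`.  Conditions whose lists yield no surviving term do not
#' appear in the output at all (by design: they produced no significant
#' cluster).
#'
#' @param lists Named list: condition -> gene list.
#' @param collection,universe As in [enrich()].
#' @param p_cut Adjusted-p cutoff.
#' @return Long data frame: condition, term, k, gene_ratio, p, p_adj.
#' @export
compare_clusters <- function(lists, collection, universe, p_cut = 0.05) {
  if (length(lists) == 0L) abort_input("no condition lists supplied")
  out <- lapply(names(lists), function(cond) {
    e <- enrich(lists[[cond]], collection, universe)
    e <- e[e$p_adj < p_cut, , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    cbind(condition = cond, e[, c("term", "k", "gene_ratio", "p", "p_adj")])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(condition = character(0), term = character(0),
                      k = integer(0), gene_ratio = numeric(0),
                      p = numeric(0), p_adj = numeric(0))
  rownames(out) <- NULL
  out
}

#' Row-wise z-score standardisation with a missing-value mask
#'
#' Each row is centred and scaled to unit sample standard deviation
#' (denominator `n - 1`) over its unmasked cells.  Rows with fewer than
#' two unmasked cells are fully masked; zero-variance rows become zeros
#' and are flagged degenerate.
#'
#' @param values Numeric matrix (analytes/genes x samples/conditions).
#' @param mask Logical matrix, `TRUE` = missing/undetected (default: no
#'   mask, plus any `NA` cells).
#' @return A `zscore_matrix`: `z`, `mask`, `degenerate_rows`.
#' @export
zscore_matrix <- function(values, mask = NULL) {
  values <- as.matrix(values)
  mask <- mask %||% matrix(FALSE, nrow(values), ncol(values))
  mask <- mask | is.na(values)
  z <- matrix(NA_real_, nrow(values), ncol(values),
              dimnames = dimnames(values))
  degenerate <- logical(nrow(values))
  for (i in seq_len(nrow(values))) {
    use <- !mask[i, ]
    if (sum(use) < 2L) {
      mask[i, ] <- TRUE
      next
    }
    x <- values[i, use]
    s <- sd(x)
    if (s == 0) {
      z[i, use] <- 0
      degenerate[i] <- TRUE
    } else {
      z[i, use] <- (x - mean(x)) / s
    }
  }
  structure(list(z = z, mask = mask, degenerate_rows = degenerate),
            class = "zscore_matrix")
}

#' Stand-in differential expression test (per-gene Welch t)
#'
#' A deliberately simple two-group test for synthetic log-scale matrices
#' (the heavy-duty count-model machinery this stands in for is out of
#' scope): per-gene Welch t-test, Benjamini-Hochberg FDR, log2 fold-change
#' as the plain group-mean difference.  Genes with zero variance in both
#' groups get a small variance floor and are flagged.
#'
#' @param matrix Log2-scale expression matrix, genes x samples.
#' @param groups Vector of two group labels, one per column; the first
#'   level encountered is the reference.
#' @param alpha_fdr FDR threshold used for the convenience `de` flag.
#' @return A [deg_table()] with extra columns `de` and `var_floored`.
#' @export
simple_de <- function(matrix, groups, alpha_fdr = 0.05) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) abort_input("exactly two groups required")
  a <- matrix[, groups == lv[1], drop = FALSE]
  b <- matrix[, groups == lv[2], drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    abort_input("need >= 2 samples per group")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  floored <- va == 0 & vb == 0
  eps <- 1e-8
  va[floored] <- eps; vb[floored] <- eps
  na <- ncol(a); nb <- ncol(b)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  out <- deg_table(rownames(matrix) %||% seq_len(nrow(matrix)),
                   log2fc = mb - ma, p = p)
  out$de <- out$fdr < alpha_fdr
  out$var_floored <- floored
  out
}

#' Null plate/batch error-rate simulation
#'
#' Simulates `n_genes` two-group comparisons (`reps` replicates per group,
#' no true effect).  Within each simulation repeat every sample carries a
#' plate offset (`N(0, batch_sd)`, one draw per plate, shared across
#' genes) plus per-gene residual noise `N(0, residual_sd)`; groups are
#' assigned to different plates (the confounded layout that makes batch
#' effects bite).  A gene is miscalled in a repeat when its two-sided
#' Welch t-test p falls below `alpha`.  Reported are the per-gene error
#' rates across repeats, their median (the headline number, in percent)
#' and mean.
#'
#' The default test is the pooled two-sample t (exact nominal level under
#' the simulator's equal-variance null); `test = "welch"` matches the
#' [simple_de()] test instead, which is slightly conservative at three
#' replicates.
#'
#' @param n_genes Number of simulated genes.
#' @param reps Replicates per group.
#' @param batch_sd,residual_sd Log-scale standard deviations.
#' @param n_repeats Simulation repeats over which per-gene rates are
#'   estimated.
#' @param alpha Significance threshold.
#' @param test `"student"` (pooled) or `"welch"`.
#' @param seed RNG seed.
#' @return A `batch_sim_result`: `median_error_rate` and
#'   `mean_error_rate` (percent), `error_rates` (per gene), `n_genes`,
#'   `reps`, `n_repeats`, `alpha`.
#' @export
simulate_batch_error <- function(n_genes = 10000L, reps = 3L,
                                 batch_sd = 0.1, residual_sd = 0.5,
                                 n_repeats = 20L, alpha = 0.05,
                                 test = c("student", "welch"),
                                 seed = 1L) {
  if (batch_sd < 0) abort_config("batch_sd", "must be >= 0")
  if (residual_sd < 0) abort_config("residual_sd", "must be >= 0")
  test <- match.arg(test)
  p_fun <- if (test == "student") student_p_rows else welch_p_rows
  errors <- with_seed(seed, {
    err <- matrix(FALSE, n_genes, n_repeats)
    for (r in seq_len(n_repeats)) {
      # one plate per group: sample-level offsets shared across genes
      off_a <- rnorm(1, 0, batch_sd)
      off_b <- rnorm(1, 0, batch_sd)
      a <- matrix(rnorm(n_genes * reps, off_a, residual_sd), n_genes, reps)
      b <- matrix(rnorm(n_genes * reps, off_b, residual_sd), n_genes, reps)
      p <- p_fun(a, b)
      err[, r] <- p < alpha
    }
    err
  })
  rates <- rowMeans(errors)
  structure(list(n_genes = n_genes, reps = reps, n_repeats = n_repeats,
                 alpha = alpha, error_rates = rates,
                 median_error_rate = 100 * median(rates),
                 mean_error_rate = 100 * mean(rates)),
            class = "batch_sim_result")
}

# Vectorised two-sided pooled-variance t-test over matrix rows.
student_p_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  sp2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / (na + nb - 2)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tstat), na + nb - 2)
  p[!is.finite(p)] <- 1
  p
}

# Vectorised two-sided Welch t-test over matrix rows.  Degenerate rows
# (both variances zero) return p = 1.
welch_p_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1
  p
}
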