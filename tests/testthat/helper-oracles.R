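# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths: enumeration for the hypergeometric tail,
# filter-and-count for concordance, hand formulas elsewhere.

# Exhaustive hypergeometric upper tail P(X >= k) via choose(); only viable
# for small N, which is the point.
brute_hyper_tail <- function(k, K, n, N) {
  xs <- k:min(K, n)
  if (length(xs) == 0L || k > min(K, n)) return(if (k <= 0) 1 else 0)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Brute-force concordance counts on a joined table.
brute_concordance <- function(table, members, alpha = 0.05) {
  df <- data.frame(gene = names(members), dir = as.integer(members))
  j <- merge(df, table, by = "gene")
  de <- j[j$fdr < alpha, , drop = FALSE]
  directional <- de[de$dir == 0 | sign(de$log2fc) == de$dir, , drop = FALSE]
  list(n_ref = length(members), n_measured = nrow(j), n_de = nrow(de),
       n_directional = nrow(directional))
}

# Small deterministic DEG table builder.
toy_deg <- function(p, log2fc = rep(1, length(p)),
                    genes = sprintf("g%02d", seq_along(p))) {
  deg_table(genes, log2fc, p)
}
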