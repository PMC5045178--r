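# Small, fast geometry used throughout the unit tests: a ~5 um nucleus in a
# 24 x 96 x 96 stack. The full-size default geometry is exercised by the
# acceptance tests.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(stack_shape = c(24L, 96L, 96L),
         voxel_size = c(0.25, 0.15, 0.15),
         nucleus_semiaxes = c(2.0, 5, 5),
         size_cv = 0.05),
    list(...))
  do.call(imaging_spec, args)
}

# Reduced gene counts for fast expression tests (X kept >= 1000 where a
# median-recovery tolerance matters).
small_expr_spec <- function(...) {
  expression_spec(genes_per_chromosome = c(I = 300L, II = 300L, III = 300L,
                                           IV = 300L, V = 400L, X = 1200L),
                  ...)
}

# Independent enumeration oracle for the rank-sum test: all C(n, nx) splits
# of the midrank vector, written separately from the package implementation.
enum_rank_sum_p <- function(x, y, alternative) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  sums <- apply(combn(n, nx), 2, function(ix) sum(r[ix]))
  switch(alternative,
         greater = mean(sums >= W),
         less = mean(sums <= W),
         two.sided = mean(abs(sums - mu) >= abs(W - mu) - 1e-9))
}

# Build a ratio_table directly (for operations that only consume ratios).
make_ratio_table <- function(gene_id, chrom, log2_ratio,
                             position_mb = rep(1, length(gene_id))) {
  out <- data.frame(gene_id = gene_id, chrom = chrom,
                    position_mb = position_mb, log2_ratio = log2_ratio,
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_table", "data.frame")
  out
}
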