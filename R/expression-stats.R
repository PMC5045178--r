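#' Specification for a synthetic gene expression table
#'
#' Forward model for an L1-larva mRNA-seq-like design: per-gene baseline
#' expression is log-normal; each non-control condition multiplies the
#' baseline by `2^(class shift + symmetric gene-level noise)`; every
#' replicate of every condition adds symmetric log2 replicate noise.
#' Chromosome gene counts and lengths approximate the C. elegans genome
#' (the X length is taken as 17.0 Mb so the left/middle/right region
#' partition covers every X gene).
#'
#' @param genes_per_chromosome named integer vector over I, II, III, IV, V, X.
#' @param chrom_lengths_mb named numeric vector of chromosome lengths (Mb).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale baseline parameters.
#' @param condition_shifts named list: one entry per non-control condition,
#'   each a named numeric vector of log2 shifts keyed by "X", "A"
#'   (all autosomes) and/or individual chromosome names; unnamed classes
#'   default to 0.
#' @param control name of the control condition (shift 0, no gene noise).
#' @param gene_noise_sd sd of the symmetric per-gene log2 noise applied to
#'   each non-control condition.
#' @param replicate_noise_sd sd of per-replicate log2 noise (all conditions).
#' @param replicates replicates per condition (>= 1).
#' @param rpkm_filter expression filter used downstream (default 1).
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(genes_per_chromosome = c(I = 2900L, II = 3200L,
                                                     III = 2600L, IV = 3300L,
                                                     V = 5000L, X = 2800L),
                            chrom_lengths_mb = c(I = 15.07, II = 15.28,
                                                 III = 13.78, IV = 17.49,
                                                 V = 20.92, X = 17.0),
                            baseline_log2_mean = 3,
                            baseline_log2_sd = 2,
                            condition_shifts = list(
                              treatment = c(X = 0.062, A = -0.059)),
                            control = "control",
                            gene_noise_sd = 0.3,
                            replicate_noise_sd = 0.2,
                            replicates = 3L,
                            rpkm_filter = 1) {
  spec <- list(genes_per_chromosome = genes_per_chromosome,
               chrom_lengths_mb = chrom_lengths_mb,
               baseline_log2_mean = baseline_log2_mean,
               baseline_log2_sd = baseline_log2_sd,
               condition_shifts = condition_shifts,
               control = control,
               gene_noise_sd = gene_noise_sd,
               replicate_noise_sd = replicate_noise_sd,
               replicates = as.integer(replicates),
               rpkm_filter = rpkm_filter)
  class(spec) <- "expression_spec"
  chroms <- c("I", "II", "III", "IV", "V", "X")
  if (!all(names(spec$genes_per_chromosome) %in% chroms))
    stop("genes_per_chromosome names must be among I, II, III, IV, V, X")
  if (!all(names(spec$genes_per_chromosome) %in% names(spec$chrom_lengths_mb)))
    stop("every chromosome needs a length")
  if (spec$gene_noise_sd < 0 || spec$replicate_noise_sd < 0 ||
      spec$baseline_log2_sd < 0)
    stop("all sds must be >= 0")
  if (spec$replicates < 1L) stop("replicates must be >= 1")
  if (spec$control %in% names(spec$condition_shifts))
    stop("the control condition must not carry a shift entry")
  spec
}

shift_for_chrom <- function(shifts, chrom) {
  s <- rep(0, length(chrom))
  if ("A" %in% names(shifts)) s[chrom != "X"] <- shifts[["A"]]
  for (nm in intersect(names(shifts), c("I", "II", "III", "IV", "V", "X")))
    s[chrom == nm] <- shifts[[nm]]
  s
}

#' Simulate a gene expression table
#'
#' @param spec an [expression_spec()].
#' @param seed integer seed; identical `(spec, seed)` give identical tables.
#' @return A data.frame of class `expression_table`: `gene_id`, `chrom`,
#'   `position_mb`, then one column per sample named `<condition>_r<k>`.
#'   Attributes `conditions` and `replicates` describe the design.
#' @export
simulate_expression <- function(spec, seed) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(as.integer(seed))
  gpc <- spec$genes_per_chromosome
  chrom <- rep(names(gpc), gpc)
  n <- length(chrom)
  gene_id <- sprintf("gene_%05d", seq_len(n))
  position_mb <- runif(n, 0, spec$chrom_lengths_mb[chrom])
  baseline <- 2^rnorm(n, spec$baseline_log2_mean, spec$baseline_log2_sd)
  conditions <- c(spec$control, names(spec$condition_shifts))
  tab <- data.frame(gene_id = gene_id, chrom = chrom,
                    position_mb = position_mb, stringsAsFactors = FALSE)
  for (cond in conditions) {
    if (cond == spec$control) {
      mu <- baseline
    } else {
      shift <- shift_for_chrom(spec$condition_shifts[[cond]], chrom)
      gnoise <- rnorm(n, 0, spec$gene_noise_sd)
      mu <- baseline * 2^(shift + gnoise)
    }
    for (r in seq_len(spec$replicates)) {
      val <- mu * 2^rnorm(n, 0, spec$replicate_noise_sd)
      tab[[sprintf("%s_r%d", cond, r)]] <- val
    }
  }
  attr(tab, "conditions") <- conditions
  attr(tab, "replicates") <- spec$replicates
  class(tab) <- c("expression_table", "data.frame")
  tab
}

sample_columns <- function(table, condition) {
  cols <- grep(sprintf("^%s_r\\d+$", condition), names(table), value = TRUE)
  if (length(cols) == 0L)
    stop(sprintf("condition '%s' not present in the table", condition))
  cols
}

#' Per-gene log2 expression ratios between two conditions
#'
#' Genes whose mean expression across all samples is at or below
#' `rpkm_filter` are removed first (the analyses use genes with average
#' expression above 1 RPKM); the ratio is then
#' `log2(mean(condition replicates) / mean(control replicates))`. Genes with
#' a zero mean in either condition are removed and counted in the
#' `n_zero_dropped` attribute.
#'
#' @param table an `expression_table` (or any data.frame with the same
#'   layout).
#' @param condition,control condition names.
#' @param rpkm_filter filter threshold on the grand mean (default 1).
#' @return A data.frame of class `ratio_table`: `gene_id`, `chrom`,
#'   `position_mb`, `log2_ratio` (finite). Attributes `n_filtered` and
#'   `n_zero_dropped` count removed genes.
#' @export
log2_ratio_table <- function(table, condition, control, rpkm_filter = 1) {
  cond_cols <- sample_columns(table, condition)
  ctrl_cols <- sample_columns(table, control)
  all_cols <- grep("_r\\d+$", names(table), value = TRUE)
  grand_mean <- rowMeans(table[, all_cols, drop = FALSE])
  keep <- grand_mean > rpkm_filter
  n_filtered <- sum(!keep)
  t2 <- table[keep, , drop = FALSE]
  m_cond <- rowMeans(t2[, cond_cols, drop = FALSE])
  m_ctrl <- rowMeans(t2[, ctrl_cols, drop = FALSE])
  nonzero <- m_cond > 0 & m_ctrl > 0
  n_zero <- sum(!nonzero)
  out <- data.frame(gene_id = t2$gene_id[nonzero],
                    chrom = t2$chrom[nonzero],
                    position_mb = t2$position_mb[nonzero],
                    log2_ratio = log2(m_cond[nonzero] / m_ctrl[nonzero]),
                    stringsAsFactors = FALSE)
  attr(out, "n_filtered") <- n_filtered
  attr(out, "n_zero_dropped") <- n_zero
  attr(out, "condition") <- condition
  attr(out, "control") <- control
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Wilcoxon rank-sum test with midranks
#'
#' Rank-sum test on the sum of x's midranks. For combined sample size
#' `<= exact_max_n` the null distribution is computed by exhaustive
#' enumeration of all rank splits (exact even under ties); otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative "greater" (x tends larger), "less", or "two.sided".
#' @param exact_max_n largest combined n for the exact path (default 12).
#' @return list(p_value, statistic = rank sum of x, method).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("greater", "two.sided", "less"),
                              exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("empty input")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))                 # midranks
  W <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max_n) {
    splits <- combn(n, nx)
    Wperm <- colSums(matrix(r[splits], nrow = nx))
    p <- switch(alternative,
      greater = mean(Wperm >= W),
      less = mean(Wperm <= W),
      two.sided = mean(abs(Wperm - mu) >= abs(W - mu) - 1e-9))
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      # every observation tied: the data carry no evidence either way
      return(list(p_value = 1, statistic = W,
                  method = "degenerate (all observations tied)"))
    }
    p <- switch(alternative,
      greater = pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE),
      less = pnorm((W - mu + 0.5) / sigma, lower.tail = TRUE),
      two.sided = min(1, 2 * pnorm((abs(W - mu) - 0.5) / sigma,
                                   lower.tail = FALSE)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(p_value = p, statistic = W, method = method)
}

autosome_names <- c("I", "II", "III", "IV", "V")

#' Chromosome-level shift tests on a ratio table
#'
#' Reports the median log2 ratio for the X, for all autosomes pooled, and
#' for each autosome; tests the X against all autosomes and against each
#' autosome with a one-sided (X greater) Wilcoxon rank-sum test — the
#' working hypothesis being X derepression — and each autosome against the
#' rest of the genome with a two-sided test.
#'
#' @param ratios a `ratio_table`.
#' @return list of class `shift_report` with data.frames `medians`
#'   (class, n, median) and `tests` (comparison, alternative, p_value,
#'   stars).
#' @export
chromosome_shift_tests <- function(ratios) {
  if (nrow(ratios) == 0L) stop("empty ratio table")
  x <- ratios$log2_ratio[ratios$chrom == "X"]
  auto <- ratios$log2_ratio[ratios$chrom %in% autosome_names]
  if (length(x) == 0L || length(auto) == 0L)
    stop("missing chromosome class: need X and autosomal genes")
  present_autos <- intersect(autosome_names, unique(ratios$chrom))
  med_rows <- rbind(
    data.frame(class = "X", n = length(x), median = median(x)),
    data.frame(class = "autosomes", n = length(auto), median = median(auto)),
    do.call(rbind, lapply(present_autos, function(ch) {
      v <- ratios$log2_ratio[ratios$chrom == ch]
      data.frame(class = ch, n = length(v), median = median(v))
    }))
  )
  tests <- list(data.frame(
    comparison = "X vs autosomes", alternative = "greater",
    p_value = wilcoxon_rank_sum(x, auto, "greater")$p_value))
  for (ch in present_autos) {
    v <- ratios$log2_ratio[ratios$chrom == ch]
    tests <- c(tests, list(data.frame(
      comparison = sprintf("X vs %s", ch), alternative = "greater",
      p_value = wilcoxon_rank_sum(x, v, "greater")$p_value)))
    rest <- ratios$log2_ratio[ratios$chrom != ch]
    tests <- c(tests, list(data.frame(
      comparison = sprintf("%s vs rest", ch), alternative = "two.sided",
      p_value = wilcoxon_rank_sum(v, rest, "two.sided")$p_value)))
  }
  tests <- do.call(rbind, tests)
  tests$stars <- vapply(tests$p_value, significance_stars, character(1))
  structure(list(medians = med_rows, tests = tests), class = "shift_report")
}

#' X-chromosome region boundaries
#'
#' The left/middle/right partition of the X used for regional comparisons:
#' 0-4 Mb left, 4-15.75 Mb middle, 15.75-17 Mb right. Intervals are
#' half-open on the right except the final one, which is closed at 17 Mb,
#' so boundary positions are assigned deterministically.
#'
#' @return data.frame with columns `region`, `start_mb`, `end_mb`.
#' @export
x_region_boundaries <- function() {
  data.frame(region = c("left", "middle", "right"),
             start_mb = c(0, 4, 15.75),
             end_mb = c(4, 15.75, 17),
             stringsAsFactors = FALSE)
}

assign_region <- function(position_mb, boundaries = x_region_boundaries()) {
  nb <- nrow(boundaries)
  reg <- rep(NA_character_, length(position_mb))
  for (i in seq_len(nb)) {
    hit <- position_mb >= boundaries$start_mb[i] &
      (position_mb < boundaries$end_mb[i] |
         (i == nb & position_mb <= boundaries$end_mb[i]))
    reg[hit] <- boundaries$region[i]
  }
  reg
}

#' Compare X-chromosome regions
#'
#' Assigns each X gene to left/middle/right by position and reports the
#' per-region median log2 ratio plus the three pairwise two-sided Wilcoxon
#' rank-sum tests.
#'
#' @param ratios a `ratio_table`.
#' @param boundaries as returned by [x_region_boundaries()].
#' @return list(medians, tests) data.frames.
#' @export
region_compare <- function(ratios, boundaries = x_region_boundaries()) {
  xr <- ratios[ratios$chrom == "X", , drop = FALSE]
  if (nrow(xr) == 0L) stop("no X genes in the ratio table")
  xr$region <- assign_region(xr$position_mb, boundaries)
  if (any(is.na(xr$region)))
    stop("X gene positions outside the region boundaries")
  groups <- split(xr$log2_ratio, xr$region)
  for (rg in boundaries$region)
    if (is.null(groups[[rg]]) || length(groups[[rg]]) == 0L)
      stop(sprintf("empty region: %s", rg))
  medians <- data.frame(
    region = boundaries$region,
    n = vapply(boundaries$region, function(r) length(groups[[r]]), integer(1)),
    median = vapply(boundaries$region, function(r) median(groups[[r]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  pairs <- combn(boundaries$region, 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    data.frame(comparison = sprintf("%s vs %s", a, b),
               p_value = wilcoxon_rank_sum(groups[[a]], groups[[b]],
                                           "two.sided")$p_value,
               stringsAsFactors = FALSE)
  }))
  tests$stars <- vapply(tests$p_value, significance_stars, character(1))
  list(medians = medians, tests = tests)
}

#' Quadrant analysis of two ratio tables
#'
#' Inner-joins two ratio tables on gene id and classifies each shared gene
#' on each axis as up (log2 ratio >= cutoff) or down (<= -cutoff); genes
#' within the +/-cutoff band on either axis belong to no quadrant and are
#' reported separately. Fractions are per chromosome class (X vs autosome)
#' over all shared genes of that class.
#'
#' @param ratios_a,ratios_b `ratio_table`s sharing gene ids.
#' @param cutoff log2 cutoff for calling a change (default 0.1, i.e. 10%).
#' @return data.frame with columns `class`, `category` (up_up, up_down,
#'   down_up, down_down, within_band), `count`, `fraction`.
#' @export
quadrant_analysis <- function(ratios_a, ratios_b, cutoff = 0.1) {
  j <- merge(ratios_a[, c("gene_id", "chrom", "log2_ratio")],
             ratios_b[, c("gene_id", "log2_ratio")],
             by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(j) == 0L) stop("empty join: the tables share no gene ids")
  cls <- ifelse(j$chrom == "X", "X", "autosomes")
  classify <- function(v) {
    if (cutoff > 0) ifelse(v >= cutoff, "up", ifelse(v <= -cutoff, "down", "band"))
    else ifelse(v >= 0, "up", "down")
  }
  ca <- classify(j$log2_ratio_a)
  cb <- classify(j$log2_ratio_b)
  category <- ifelse(ca == "band" | cb == "band", "within_band",
                     paste(ca, cb, sep = "_"))
  cats <- c("up_up", "up_down", "down_up", "down_down", "within_band")
  out <- do.call(rbind, lapply(unique(cls), function(cl) {
    sub <- category[cls == cl]
    data.frame(class = cl, category = cats,
               count = vapply(cats, function(ct) sum(sub == ct), integer(1)),
               fraction = vapply(cats, function(ct) mean(sub == ct), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Per-chromosome correlation of two ratio tables
#'
#' Pearson correlation and the R-squared of the simple linear regression of
#' table b's ratios on table a's (equal to the squared correlation),
#' reported for the X, each autosome, and all autosomes pooled.
#'
#' @param ratios_a,ratios_b `ratio_table`s sharing gene ids.
#' @return data.frame with `class`, `n`, `pearson_r`, `r_squared`.
#' @export
correlation_summary <- function(ratios_a, ratios_b) {
  j <- merge(ratios_a[, c("gene_id", "chrom", "log2_ratio")],
             ratios_b[, c("gene_id", "log2_ratio")],
             by = "gene_id", suffixes = c("_a", "_b"))
  classes <- c("X", autosome_names, "autosomes")
  rows <- lapply(classes, function(cl) {
    sub <- if (cl == "autosomes") j[j$chrom != "X", ] else j[j$chrom == cl, ]
    if (nrow(sub) < 3L) return(NULL)
    if (sd(sub$log2_ratio_a) == 0 || sd(sub$log2_ratio_b) == 0)
      stop(sprintf("zero variance in class %s", cl))
    r <- cor(sub$log2_ratio_a, sub$log2_ratio_b)
    data.frame(class = cl, n = nrow(sub), pearson_r = r, r_squared = r^2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("fewer than 3 shared genes in every class")
  out
}

#' @export
print.shift_report <- function(x, ...) {
  cat("<shift_report> medians:\n")
  print(x$medians, row.names = FALSE)
  cat("tests:\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}
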