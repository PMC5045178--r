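#' Read a run configuration
#'
#' Configurations are human-editable YAML; every randomized step takes its
#' seed from the config, and per-nucleus / per-gene seeds are derived by the
#' documented splitting rule (see [generate_cohort()]).
#'
#' @param path YAML file path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

collect_errors <- function(errs) {
  if (length(errs) > 0L)
    stop(paste(c("invalid config:", errs), collapse = "\n  - "))
}

validate_imaging_config <- function(cfg) {
  errs <- character(0)
  if (is.null(cfg$seed)) errs <- c(errs, "missing seed")
  if (is.null(cfg$genotypes) || length(cfg$genotypes) < 2L)
    errs <- c(errs, "need >= 2 genotype specs")
  labels <- vapply(cfg$genotypes, function(g) g$label %||% "", character(1))
  if (any(labels == "")) errs <- c(errs, "every genotype needs a label")
  if (anyDuplicated(labels)) errs <- c(errs, "genotype labels must be unique")
  nref <- sum(vapply(cfg$genotypes, function(g) isTRUE(g$reference), logical(1)))
  if (nref != 1L) errs <- c(errs, "exactly one genotype must set reference: true")
  for (g in cfg$genotypes) {
    tf <- g$territory_fraction
    if (is.null(tf) || tf <= 0 || tf >= 1)
      errs <- c(errs, sprintf("genotype '%s': territory_fraction must be in (0,1)",
                              g$label %||% "?"))
  }
  collect_errors(errs)
  cfg
}

genotype_spec <- function(cfg, g) {
  geo <- cfg$geometry %||% list()
  do.call(imaging_spec, utils::modifyList(geo, list(
    territory_fraction = g$territory_fraction,
    radial_bias = g$radial_bias %||% 0.8,
    n_territories = as.integer(g$n_territories %||% 2L)
  )))
}

#' Run an end-to-end synthetic imaging experiment
#'
#' For every genotype in the config, generates a synthetic cohort, runs the
#' volume quantification and the three-zone assay, and compares every
#' genotype against the reference (volume fraction and central-zone
#' fraction) with the classic Student's t-test and significance stars.
#' Identical configs give identical outputs.
#'
#' @param config a list or a YAML path with fields: `seed`, optional
#'   `geometry` (arguments of [imaging_spec()]), `n_per_genotype` (default
#'   20), `genotypes` (list of `label`, `territory_fraction`, `radial_bias`,
#'   `n_territories`, and `reference: true` on exactly one), optional
#'   `segmentation`/`zonal` option lists, optional `out_dir`.
#' @param out_dir overrides `config$out_dir`; when non-NULL the per-nucleus
#'   table, comparison tables, eligibility summary and manifest are written
#'   there as TSVs.
#' @return list with `measurements` (per-nucleus data.frame),
#'   `volume_comparisons`, `central_comparisons`, `eligibility`, `manifest`.
#' @export
run_imaging_experiment <- function(config, out_dir = NULL) {
  cfg <- validate_imaging_config(as_config(config))
  out_dir <- out_dir %||% cfg$out_dir
  n <- cfg$n_per_genotype %||% 20L
  labels <- vapply(cfg$genotypes, `[[`, character(1), "label")
  reference <- labels[vapply(cfg$genotypes, function(g) isTRUE(g$reference),
                             logical(1))]
  seg_cfg <- cfg$segmentation %||% list()
  zon_cfg <- utils::modifyList(seg_cfg, cfg$zonal %||% list())

  meas <- list(); manifest <- list()
  for (gi in seq_along(cfg$genotypes)) {
    g <- cfg$genotypes[[gi]]
    spec <- genotype_spec(cfg, g)
    base_seed <- derive_seed(cfg$seed, gi * 1000L)
    cohort <- generate_cohort(spec, n, base_seed)
    vol <- measure_volume_cohort(cohort, seg_cfg)
    zon <- run_zonal_cohort(cohort, zon_cfg)
    df <- cbind(genotype = g$label, vol,
                zon[, c("plane_index", "eligible", "axis_ratio", "solidity",
                        "peripheral", "intermediate", "central",
                        "true_central")])
    meas[[gi]] <- df
    manifest[[gi]] <- data.frame(genotype = g$label,
                                 nucleus_id = vol$nucleus_id,
                                 seed = vol$seed,
                                 base_seed = base_seed,
                                 true_volume_fraction = vol$true_volume_fraction,
                                 stringsAsFactors = FALSE)
  }
  measurements <- do.call(rbind, meas)
  manifest <- do.call(rbind, manifest)

  vol_cmp <- compare_genotypes(
    data.frame(label = measurements$genotype,
               value = measurements$volume_fraction_percent), reference)
  elig <- measurements[measurements$eligible, ]
  cen_cmp <- if (length(unique(elig$genotype)) >= 2L &&
                 reference %in% elig$genotype) {
    compare_genotypes(data.frame(label = elig$genotype, value = elig$central),
                      reference)
  } else NULL
  eligibility <- do.call(rbind, lapply(split(measurements, measurements$genotype),
    function(d) data.frame(genotype = d$genotype[1], n = nrow(d),
                           n_eligible = sum(d$eligible),
                           percent_eligible = 100 * mean(d$eligible),
                           stringsAsFactors = FALSE)))
  rownames(eligibility) <- NULL

  result <- list(measurements = measurements, volume_comparisons = vol_cmp,
                 central_comparisons = cen_cmp, eligibility = eligibility,
                 manifest = manifest, reference = reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(measurements, file.path(out_dir, "nuclei.tsv"))
    write_tsv(vol_cmp, file.path(out_dir, "volume_comparisons.tsv"))
    if (!is.null(cen_cmp))
      write_tsv(cen_cmp, file.path(out_dir, "central_zone_comparisons.tsv"))
    write_tsv(eligibility, file.path(out_dir, "eligibility.tsv"))
    write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  }
  result
}

validate_expression_config <- function(cfg) {
  errs <- character(0)
  if (is.null(cfg$seed)) errs <- c(errs, "missing seed")
  tr <- cfg$treatments
  if (is.null(tr) || length(tr) < 1L)
    errs <- c(errs, "need >= 1 treatment with shift parameters")
  for (t in tr %||% list())
    if (is.null(t$label)) errs <- c(errs, "every treatment needs a label")
  collect_errors(errs)
  cfg
}

#' Run an end-to-end synthetic expression experiment
#'
#' Simulates an expression table for a control plus the configured
#' treatments, then for every treatment computes the per-gene log2 ratio
#' table (1-RPKM filtered), the chromosome shift tests, and the X-region
#' comparison; when two or more treatments are configured the first two are
#' additionally compared by quadrant analysis and per-chromosome
#' correlations.
#'
#' @param config list or YAML path: `seed`, optional `generator` (arguments
#'   of [expression_spec()] other than `condition_shifts`), `treatments`
#'   (list of `label` plus named shifts, e.g. `X: 0.062`, `A: -0.059`),
#'   optional `out_dir`.
#' @param out_dir overrides `config$out_dir`.
#' @return list with `table`, per-treatment `ratios`, `shift_reports`,
#'   `region_reports`, and (when applicable) `quadrants`, `correlations`.
#' @export
run_expression_experiment <- function(config, out_dir = NULL) {
  cfg <- validate_expression_config(as_config(config))
  out_dir <- out_dir %||% cfg$out_dir
  shifts <- lapply(cfg$treatments, function(t) {
    s <- unlist(t[setdiff(names(t), "label")])
    if (is.null(s)) s <- c(A = 0)
    s
  })
  names(shifts) <- vapply(cfg$treatments, `[[`, character(1), "label")
  gen_args <- cfg$generator %||% list()
  gen_args$condition_shifts <- shifts
  spec <- do.call(expression_spec, gen_args)
  tab <- simulate_expression(spec, cfg$seed)

  ratios <- list(); shift_reports <- list(); region_reports <- list()
  for (lab in names(shifts)) {
    rt <- log2_ratio_table(tab, lab, spec$control, spec$rpkm_filter)
    ratios[[lab]] <- rt
    shift_reports[[lab]] <- chromosome_shift_tests(rt)
    region_reports[[lab]] <- region_compare(rt)
  }
  result <- list(table = tab, ratios = ratios, shift_reports = shift_reports,
                 region_reports = region_reports)
  if (length(shifts) >= 2L) {
    a <- names(shifts)[1]; b <- names(shifts)[2]
    result$quadrants <- quadrant_analysis(ratios[[a]], ratios[[b]])
    result$correlations <- correlation_summary(ratios[[a]], ratios[[b]])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    med <- do.call(rbind, lapply(names(shift_reports), function(lab)
      cbind(treatment = lab, shift_reports[[lab]]$medians)))
    tst <- do.call(rbind, lapply(names(shift_reports), function(lab)
      cbind(treatment = lab, shift_reports[[lab]]$tests)))
    reg <- do.call(rbind, lapply(names(region_reports), function(lab)
      cbind(treatment = lab, region_reports[[lab]]$medians)))
    write_tsv(med, file.path(out_dir, "chromosome_medians.tsv"))
    write_tsv(tst, file.path(out_dir, "chromosome_tests.tsv"))
    write_tsv(reg, file.path(out_dir, "x_region_medians.tsv"))
    if (!is.null(result$quadrants))
      write_tsv(result$quadrants, file.path(out_dir, "quadrants.tsv"))
    if (!is.null(result$correlations))
      write_tsv(result$correlations, file.path(out_dir, "correlations.tsv"))
  }
  result
}
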