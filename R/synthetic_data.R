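#' Configuration for synthetic count-matrix generation
#'
#' The generator emulates the statistical shape of nascent-RNA invariant-set
#' counts: per-region abundances spanning orders of magnitude (log10-normal),
#' negative binomial overdispersion, a global true log2 normalization factor
#' between the two samples, and optional contamination — a fraction of
#' regions receiving an extra region-specific log2 perturbation in the
#' reference sample, emulating a perturbation that reaches nominally
#' invariant regions.
#'
#' @param n_regions Number of regions (>= 1).
#' @param true_log2_factor True log2 normalization factor: reference means
#'   are `2^true_log2_factor` times query means.
#' @param mean_log10_expression,sd_log10_expression Mean and sd of the
#'   log10 per-region abundance distribution.
#' @param dispersion NB size parameter; `var = mu + mu^2 / dispersion`.
#' @param depth_multiplier Multiplies both samples' means (sequencing depth).
#' @param contamination_fraction Fraction of regions perturbed in the
#'   reference sample, in `[0, 1]`.
#' @param contamination_effect_sd SD (log2 units) of the per-region
#'   perturbation effects.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_regions, true_log2_factor = 0,
                             mean_log10_expression = 2,
                             sd_log10_expression = 1,
                             dispersion = 10, depth_multiplier = 1,
                             contamination_fraction = 0,
                             contamination_effect_sd = 0, seed = NULL) {
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (depth_multiplier <= 0) stop("depth_multiplier must be > 0")
  if (contamination_fraction < 0 || contamination_fraction > 1)
    stop("contamination_fraction must be in [0, 1]")
  if (contamination_effect_sd < 0) stop("contamination_effect_sd must be >= 0")
  structure(list(n_regions = as.integer(n_regions),
                 true_log2_factor = true_log2_factor,
                 mean_log10_expression = mean_log10_expression,
                 sd_log10_expression = sd_log10_expression,
                 dispersion = dispersion,
                 depth_multiplier = depth_multiplier,
                 contamination_fraction = contamination_fraction,
                 contamination_effect_sd = contamination_effect_sd,
                 seed = seed),
            class = "synthetic_config")
}

#' Simulate a query/reference sample pair with known normalization truth
#'
#' Region base abundances `lambda_j` are drawn log10-normal; query counts
#' are `NB(depth * lambda_j, dispersion)` and reference counts are
#' `NB(depth * lambda_j * 2^true_log2_factor * 2^delta_j, dispersion)`,
#' where `delta_j ~ Normal(0, contamination_effect_sd)` for the contaminated
#' region subset and 0 elsewhere.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_truth` list: `config`, `matrix` (a [count_matrix()]
#'   with samples `query` and `reference`), `per_region_means` (list of the
#'   two mean vectors), `perturbed_region_ids`.
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  base <- simulate_base(config)
  simulate_counts_at_depth(config, base, config$depth_multiplier,
                           count_seed_offset = 1L)
}

# Depth-independent ingredients (abundances, contaminated subset, effects),
# drawn under the config seed so depth series can share them.
simulate_base <- function(config) {
  local_seed(config$seed, {
    lambda <- 10^stats::rnorm(config$n_regions,
                              config$mean_log10_expression,
                              config$sd_log10_expression)
    n_pert <- round(config$contamination_fraction * config$n_regions)
    pert_idx <- if (n_pert > 0) sort(sample.int(config$n_regions, n_pert))
                else integer(0)
    delta <- numeric(config$n_regions)
    if (n_pert > 0)
      delta[pert_idx] <- stats::rnorm(n_pert, 0, config$contamination_effect_sd)
    list(lambda = lambda, delta = delta, pert_idx = pert_idx)
  })
}

simulate_counts_at_depth <- function(config, base, depth, count_seed_offset) {
  mu_q <- depth * base$lambda
  mu_r <- depth * base$lambda * 2^config$true_log2_factor * 2^base$delta
  counts <- local_seed(
    if (is.null(config$seed)) NULL else config$seed + count_seed_offset, {
      cbind(query = stats::rnbinom(config$n_regions, mu = mu_q,
                                   size = config$dispersion),
            reference = stats::rnbinom(config$n_regions, mu = mu_r,
                                       size = config$dispersion))
    })
  ids <- sprintf("region_%05d", seq_len(config$n_regions))
  rownames(counts) <- ids
  structure(list(config = config,
                 matrix = count_matrix(counts),
                 per_region_means = list(query = mu_q, reference = mu_r),
                 perturbed_region_ids = ids[base$pert_idx]),
            class = "synthetic_truth")
}

#' Simulate a matched depth series
#'
#' One simulation per depth multiplier, sharing the same base abundances
#' and contamination effects (same base seed), so sequencing depth is the
#' only factor that varies across the series.
#'
#' @param config A [synthetic_config()]; its own `depth_multiplier` is
#'   ignored in favor of `depth_multipliers`.
#' @param depth_multipliers Nonempty vector of positive depth multipliers.
#' @return List of `synthetic_truth`, one per multiplier.
#' @export
simulate_depth_series <- function(config, depth_multipliers) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(depth_multipliers) < 1L) stop("depth_multipliers must be nonempty")
  if (any(depth_multipliers <= 0)) stop("depth multipliers must be > 0")
  base <- simulate_base(config)
  lapply(seq_along(depth_multipliers), function(i) {
    cfg <- config
    cfg$depth_multiplier <- depth_multipliers[i]
    simulate_counts_at_depth(cfg, base, depth_multipliers[i],
                             count_seed_offset = i)
  })
}

#' Write a synthetic pair to disk
#'
#' Writes the standard counts TSV plus a JSON truth sidecar holding the
#' generating configuration and the perturbed region ids.
#'
#' @param truth A `synthetic_truth` from [simulate_pair()].
#' @param prefix Path prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_truth.json`.
#' @export
write_synthetic <- function(truth, prefix) {
  stopifnot(inherits(truth, "synthetic_truth"))
  counts_path <- paste0(prefix, "_counts.tsv")
  truth_path <- paste0(prefix, "_truth.json")
  write_counts_tsv(truth$matrix, counts_path)
  jsonlite::write_json(
    list(config = unclass(truth$config),
         perturbed_region_ids = truth$perturbed_region_ids),
    truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(counts_path, truth_path))
}
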