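## Synthetic-data configuration. The defaults ARE the study conditions the
## analyses are tested under; they are not tuning knobs.

#' Configuration for the synthetic-data generators
#'
#' Defaults target the effect sizes the analysis layers are designed to
#' detect: E3 ligases ~10-fold less abundant than alternate partners,
#' planted co-degrading modules with a 5% half-life coefficient of
#' variation (so pairwise ratios concentrate above 0.8), five modules of
#' eight proteins against 500 background proteins, and a two-component
#' interaction confidence mixture with a known below-0.3 subset.
#'
#' @param seed master seed; every generator derives its own RNG stream
#'   from it, so identical configs give byte-identical outputs.
#' @param n_substrates number of UPS substrates with tripartite degrons.
#' @param n_partners_per_substrate interaction partners per substrate.
#' @param masking_fraction expected fraction of partners whose binding
#'   feature overlaps a degron (Bernoulli per partner).
#' @param low_conf_fraction fraction of interactions drawn from the
#'   below-threshold confidence component (< 0.3).
#' @param ups_fraction fraction of partners annotated with UPS-branch GO
#'   terms (filtered out by the masking analysis).
#' @param n_datasets number of abundance datasets.
#' @param role_median_log_ppm named numeric log10-ppm medians for roles
#'   `substrate`, `e3`, `ap`; `ap` defaults to `e3 + log10(e3_ap_fold)`.
#' @param e3_ap_fold target AP:E3 median abundance ratio (> 1, default 10).
#' @param abundance_log_sd per-protein log10 noise sd (default 0.4).
#' @param latent_log_sd sd of the dataset-level latent factor shared by
#'   substrates and E3s (induces cross-dataset correlation; default 0.2).
#' @param missing_rate probability a protein is absent from a dataset.
#' @param n_filler background proteins per abundance dataset.
#' @param n_modules planted co-degradation modules.
#' @param module_size proteins per module (>= 2; backbone chain length).
#' @param n_background background network proteins.
#' @param background_degree mean background node degree (default 1). The
#'   module diameter constraint caps the planted co-degrading edges at
#'   `n_modules * module_size`, so the background edge count sets the
#'   power to detect the planted similar-category excess over the
#'   random-network envelope; the default keeps that excess near four
#'   envelope standard deviations (see the methods vignette).
#' @param within_module_halflife_cv half-life coefficient of variation
#'   within a module (default 0.05).
#' @param background_halflife_logsd log-sd of background half-lives
#'   (default 0.6).
#' @param within_module_coexpr mean within-module co-expression (Pearson
#'   r; default 0.7).
#' @param semsim_shared_terms specific GO terms shared by a module's
#'   members (default 3).
#' @return validated config (classed list `degronon_synth_config`).
#' @export
synthConfig <- function(seed = 1L,
                        n_substrates = 20L,
                        n_partners_per_substrate = 20L,
                        masking_fraction = 0.5,
                        low_conf_fraction = 0.15,
                        ups_fraction = 0.1,
                        n_datasets = 50L,
                        role_median_log_ppm = NULL,
                        e3_ap_fold = 10,
                        abundance_log_sd = 0.4,
                        latent_log_sd = 0.2,
                        missing_rate = 0.1,
                        n_filler = 300L,
                        n_modules = 5L,
                        module_size = 8L,
                        n_background = 500L,
                        background_degree = 1,
                        within_module_halflife_cv = 0.05,
                        background_halflife_logsd = 0.6,
                        within_module_coexpr = 0.7,
                        semsim_shared_terms = 3L) {
  if (is.null(role_median_log_ppm))
    role_median_log_ppm <- c(substrate = 1.5, e3 = 1.0,
                             ap = 1.0 + log10(e3_ap_fold))
  cfg <- list(seed = as.integer(seed),
              n_substrates = n_substrates,
              n_partners_per_substrate = n_partners_per_substrate,
              masking_fraction = masking_fraction,
              low_conf_fraction = low_conf_fraction,
              ups_fraction = ups_fraction,
              n_datasets = n_datasets,
              role_median_log_ppm = role_median_log_ppm,
              e3_ap_fold = e3_ap_fold,
              abundance_log_sd = abundance_log_sd,
              latent_log_sd = latent_log_sd,
              missing_rate = missing_rate,
              n_filler = n_filler,
              n_modules = n_modules,
              module_size = module_size,
              n_background = n_background,
              background_degree = background_degree,
              within_module_halflife_cv = within_module_halflife_cv,
              background_halflife_logsd = background_halflife_logsd,
              within_module_coexpr = within_module_coexpr,
              semsim_shared_terms = semsim_shared_terms)
  .validateSynthConfig(cfg)
  structure(cfg, class = "degronon_synth_config")
}

.validateSynthConfig <- function(cfg) {
  counts <- c("n_substrates", "n_partners_per_substrate", "n_datasets",
              "n_modules", "module_size", "n_background", "n_filler",
              "semsim_shared_terms")
  for (nm in counts)
    if (!isCount(cfg[[nm]]))
      stopConfig("%s must be a count >= 1 (got %s)", nm, cfg[[nm]])
  props <- c("masking_fraction", "low_conf_fraction", "ups_fraction",
             "missing_rate", "within_module_coexpr")
  for (nm in props)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stopConfig("%s must be a proportion in [0, 1]", nm)
  if (!is.finite(cfg$e3_ap_fold) || cfg$e3_ap_fold <= 1)
    stopConfig("e3_ap_fold must be > 1")
  if (cfg$module_size < 2) stopConfig("module_size must be >= 2")
  if (cfg$within_module_halflife_cv < 0)
    stopConfig("within_module_halflife_cv must be >= 0")
  if (!all(c("substrate", "e3", "ap") %in% names(cfg$role_median_log_ppm)))
    stopConfig("role_median_log_ppm must name substrate, e3, ap")
  invisible(cfg)
}
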