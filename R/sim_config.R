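## Marker genes and co-expression block anchors. Block sizes default to the
## three major clusters of the Ma-LMM01 genome-wide expression dendrogram:
## a small lysogeny module (IS607 transposase gp135 + serine recombinase
## gp136, the other transposases gp031/gp032 and two hypotheticals), a
## 60-gene packaging/lysis module, and a 112-gene replication/structural
## module containing the tail sheath gp091 and its co-expressed tail-tube
## (gp088, gp092) and head (gp086, gp087) genes.
LYSOGENY_ANCHORS <- c("gp135", "gp136", "gp031", "gp032", "gp171", "gp067")
PACKAGING_ANCHORS <- c("gp069", "gp095", "gp118", "gp134", "gp128")
REPLICATION_ANCHORS <- c("gp091", "gp086", "gp087", "gp088", "gp092")
CORE_MARKERS <- c("gp091", "gp135", "gp136")
BLOCK_LEVELS <- c("lysogeny", "packaging_lysis", "replication_structural", "host")

#' Environmental variables emitted by the simulator
#'
#' Limnological sonde and nutrient variables measured per sample: water
#' temperature (deg C), electrical conductivity, total dissolved solids,
#' salinity, pH, turbidity (NTU), phycocyanin, dissolved oxygen, Secchi
#' depth, water depth, and the nitrogen/phosphorus series (TN, TDN, NH4,
#' TP, TDP, PO4) plus chlorophyll a.
#'
#' @return character vector of variable names.
#' @export
env_variable_names <- function() {
  c("WaterTem", "EC", "TDS", "Sal", "pH", "NTU", "PC", "DO", "SD",
    "WaterDep", "TN", "TDN", "NH4", "TP", "TDP", "PO4", "CHLa")
}

## typical eutrophic shallow-lake summer values used to put the z-scored
## draws on interpretable scales (mean, sd per variable)
ENV_SCALES <- list(
  WaterTem = c(25, 4), EC = c(550, 100), TDS = c(450, 80), Sal = c(0.25, 0.05),
  pH = c(8.3, 0.4), NTU = c(40, 20), PC = c(30, 15), DO = c(8, 2),
  SD = c(0.4, 0.15), WaterDep = c(2.5, 0.5), TN = c(3, 1.2), TDN = c(2, 0.8),
  NH4 = c(0.5, 0.3), TP = c(0.2, 0.08), TDP = c(0.1, 0.05),
  PO4 = c(0.05, 0.03), CHLa = c(40, 25)
)

#' Simulation configuration
#'
#' Parameters of the synthetic metatranscriptome generator. Defaults emulate
#' the study conditions the pipeline was designed for: 33 usable samples, a
#' 184-gene phage genome, paired-end 125 bp libraries of 1e5-1e6 read pairs,
#' negative-binomial counts with moderate overdispersion, a 10-fold
#' state-responsive expression swing, and latent lytic/lysogenic states tied
#' to pH (towards lysogenic) and total dissolved solids (towards lytic)
#' through a logistic link.
#'
#' @param n_samples number of samples.
#' @param n_phage_genes number of phage ORFs (>= 10; marker genes are always
#'   placed).
#' @param n_host_genes number of host ORFs (rpoB always included).
#' @param library_size_range numeric length-2, read pairs per sample drawn
#'   uniformly in this range.
#' @param dispersion negative-binomial dispersion (> 0); variance is
#'   mu + dispersion * mu^2.
#' @param state_fold_change fold change (>= 1) applied to state-responsive
#'   blocks in the state they respond to: the lysogeny block is up-regulated
#'   in lysogenic samples, the packaging/lysis and replication/structural
#'   blocks in lytic samples; host genes are state-independent.
#' @param env_state_coefficients named numeric vector of logistic-regression
#'   coefficients over standardized environmental variables; names must be a
#'   subset of [env_variable_names()].
#' @param env_intercept logistic intercept.
#' @param env_correlation exchangeable correlation among environmental
#'   variables (real limnological tables are strongly collinear).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   gene abundances.
#' @param marker_sdlog reduced log-normal spread for the marker genes, so
#'   that the gp091:gp135 baseline ratio stays near 1 and the observed ratio
#'   reflects the state effect (the field ratio range of roughly 1.2- to
#'   79-fold in lytic samples implies near-balanced marker baselines).
#' @param read_length read length in bases (paired-end).
#' @param seq_error_rate per-base substitution probability in `[0, 0.1]`.
#' @param decoy_fraction fraction of emitted SAM pairs that are decoys
#'   (cross-genome, low-identity or short alignments), in `[0, 0.5)`.
#' @param seed integer RNG seed; identical config + seed gives byte-identical
#'   outputs.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 33,
                       n_phage_genes = 184,
                       n_host_genes = 10,
                       library_size_range = c(1e5, 1e6),
                       dispersion = 0.3,
                       state_fold_change = 10,
                       env_state_coefficients = c(pH = 1.5, TDS = -1.5),
                       env_intercept = 0,
                       env_correlation = 0.3,
                       baseline_meanlog = 0,
                       baseline_sdlog = 1,
                       marker_sdlog = 0.25,
                       read_length = 125,
                       seq_error_rate = 0,
                       decoy_fraction = 0,
                       seed = 1) {
  cfg <- list(
    n_samples = n_samples, n_phage_genes = n_phage_genes,
    n_host_genes = n_host_genes,
    library_size_range = as.numeric(library_size_range),
    dispersion = dispersion, state_fold_change = state_fold_change,
    env_state_coefficients = env_state_coefficients,
    env_intercept = env_intercept, env_correlation = env_correlation,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    marker_sdlog = marker_sdlog, read_length = read_length,
    seq_error_rate = seq_error_rate, decoy_fraction = decoy_fraction,
    seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_samples", "n_phage_genes", "n_host_genes", "read_length"))
    if (!is_count(cfg[[f]])) stop_config(f, " must be a positive integer")
  if (cfg$n_phage_genes < 10)
    stop_config("n_phage_genes too small to place all named marker genes (minimum 10)")
  if (length(cfg$library_size_range) != 2L ||
      any(cfg$library_size_range <= 0) ||
      cfg$library_size_range[1] > cfg$library_size_range[2])
    stop_config("library_size_range must be an increasing pair of positive counts")
  if (!is.numeric(cfg$dispersion) || cfg$dispersion <= 0)
    stop_config("dispersion must be > 0")
  if (!is.numeric(cfg$state_fold_change) || cfg$state_fold_change < 1)
    stop_config("state_fold_change must be >= 1")
  if (any(!is.finite(cfg$env_state_coefficients)))
    stop_config("env_state_coefficients must be finite")
  if (length(cfg$env_state_coefficients) &&
      !all(names(cfg$env_state_coefficients) %in% env_variable_names()))
    stop_config("env_state_coefficients names must be environmental variables")
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate > 0.1)
    stop_config("seq_error_rate must lie in [0, 0.1]")
  if (cfg$decoy_fraction < 0 || cfg$decoy_fraction >= 0.5)
    stop_config("decoy_fraction must lie in [0, 0.5)")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop_config("seed must be a single integer")
  invisible(cfg)
}
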