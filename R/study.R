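#' Default study configuration
#'
#' Builds the complete run configuration for the simulation experiment as
#' a named list (YAML-serializable, see [read_run_config()]). At
#' `scale = 1` the cohort sizes mirror the reference design: a base panel
#' of 661 African, 503 European and 347 admixed individuals, 300 admixed
#' imputation targets, and a pool of 3,000 Native American reference
#' individuals added in increments of
#' 0/100/134/200/400/600/800/1000/1500/2000/3000. The shipped desk-scale
#' configuration (`scale = 0.1`, see [desk_config()]) keeps the same
#' ratios on a 50 Mb chromosome.
#'
#' @param scale Multiplier applied to all cohort sizes.
#' @param seed Global seed; expanded into per-stage seeds (see
#'   [stage_seeds()]).
#' @param length_bp Chromosome length (default 50 Mb).
#' @param n_sites Number of segregating sites to simulate.
#' @param sizes Added-reference increments; default scales the full
#'   schedule.
#' @return A validated configuration list.
#' @export
default_config <- function(scale = 1, seed = 1L, length_bp = 50e6,
                           n_sites = 6000L, sizes = NULL) {
  if (is.null(sizes)) {
    sizes <- unique(round(c(0, 100, 134, 200, 400, 600, 800, 1000,
                            1500, 2000, 3000) * scale))
  }
  cfg <- list(
    seed = as.integer(seed),
    chromosome = list(length_bp = length_bp, rate_cM_per_Mb = 1),
    n_sites = as.integer(n_sites),
    sources = list(
      AFR = list(divergence_F = 0.10, n_founders = 40L,
                 founder_switch_rate = 30, mutation_flip_rate = 1e-4),
      EUR = list(divergence_F = 0.12, n_founders = 40L,
                 founder_switch_rate = 30, mutation_flip_rate = 1e-4),
      NAT = list(divergence_F = 0.18, n_founders = 40L,
                 founder_switch_rate = 30, mutation_flip_rate = 1e-4)),
    donors_per_pop = 60L,
    panel = list(n_afr = round(661 * scale), n_eur = round(503 * scale),
                 n_admixed = round(347 * scale)),
    n_targets = round(300 * scale),
    nat_pool = max(sizes),
    admixture = list(afr = 1 / 6, eur = 1 / 3, nat = 1 / 2,
                     generations = 12L),
    array = list(ascertainment_pop = "EUR",
                 mean_spacing_bp = round(length_bp / (600 * scale * 10)),
                 histogram_proportions = c(0.10, 0.15, 0.20, 0.25, 0.30)),
    ls = list(ne_eff = 1e4, lambda = 1e-3, min_switch = 1e-8),
    bins = c(0.5, 0.05, 0.01, 0.003),
    threshold = list(min_maf = 0.01, min_info = 0.3),
    sizes = as.integer(sizes),
    r2_mode = "pooled")
  validate_config(cfg)
}

#' Desk-scale configuration (0.1 scale)
#'
#' The configuration used throughout the package tests: base panel of
#' 66 AFR + 50 EUR + 35 admixed individuals, 30 targets, NAT additions
#' 0/20/50/100, 6,000 sites on a 50 Mb chromosome (1 cM/Mb), array of
#' ~600 typed sites.
#'
#' @param seed Global seed.
#' @param sizes Added-reference increments (default `c(0, 20, 50, 100)`).
#' @return A validated configuration list.
#' @export
desk_config <- function(seed = 1L, sizes = c(0L, 20L, 50L, 100L)) {
  cfg <- default_config(scale = 0.1, seed = seed, sizes = sizes)
  cfg$panel <- list(n_afr = 66L, n_eur = 50L, n_admixed = 35L)
  cfg$n_targets <- 30L
  cfg$array$mean_spacing_bp <- 83333L # ~600 typed sites on 50 Mb
  validate_config(cfg)
}

config_keys <- c("seed", "chromosome", "n_sites", "sources",
                 "donors_per_pop", "panel", "n_targets", "nat_pool",
                 "admixture", "array", "ls", "bins", "threshold",
                 "sizes", "r2_mode")

#' Validate a run configuration
#'
#' Checks that all required keys are present, no unknown keys exist, and
#' scalar fields are in range.
#'
#' @param cfg Configuration list.
#' @return The configuration, invisibly amended with integer types.
#' @export
validate_config <- function(cfg) {
  missing_keys <- setdiff(config_keys, names(cfg))
  if (length(missing_keys))
    stop("configuration is missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(cfg), config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!all(c("AFR", "EUR", "NAT") %in% names(cfg$sources)))
    stop("`sources` must configure AFR, EUR and NAT", call. = FALSE)
  props <- with(cfg$admixture, c(AFR = afr, EUR = eur, NAT = nat))
  if (abs(sum(props) - 1) > 1e-9)
    stop("admixture proportions must sum to 1", call. = FALSE)
  cfg$sizes <- sort(unique(as.integer(cfg$sizes)))
  if (cfg$nat_pool < max(cfg$sizes))
    stop("`nat_pool` is smaller than the largest requested size",
         call. = FALSE)
  cfg
}

#' Expand the global seed into per-stage seeds
#'
#' One global seed deterministically yields independent seeds for the
#' source simulation, the admixture mosaic, and the array ascertainment,
#' so single stages can be rerun without rerunning the whole pipeline.
#'
#' @param seed Global integer seed.
#' @return Named integer vector with elements `sources`, `admix`,
#'   `array`.
#' @export
stage_seeds <- function(seed) {
  set.seed(as.integer(seed))
  stats::setNames(sample.int(.Machine$integer.max, 3L),
                  c("sources", "admix", "array"))
}

#' Simulate the full study world from a configuration
#'
#' Generates the source populations, the admixed cohort (reference
#' admixed individuals plus imputation targets, with truth tracts for
#' all), the base reference panel, the NAT reference pool, and the
#' ascertained array scheme. Admixture donors are a dedicated slice of
#' each source population, disjoint from the haplotypes used as
#' references, so reference panels are related to, but never identical
#' with, the haplotypes the admixed cohort copied from.
#'
#' @param cfg A configuration from [default_config()] /
#'   [desk_config()] / [read_run_config()].
#' @return A list (`study_world`) with elements `chrom`, `sources`,
#'   `base_panel`, `nat_pool`, `targets`, `target_tracks`, `admixed_all`,
#'   `all_tracks`, `scheme`, `typed_idx`, `heldout_idx`, `truth_maf`,
#'   `params`, `seeds`, `config`.
#' @export
simulate_study <- function(cfg) {
  cfg <- validate_config(cfg)
  seeds <- stage_seeds(cfg$seed)
  chrom <- chromosome_spec(cfg$chromosome$length_bp,
                           cfg$chromosome$rate_cM_per_Mb)

  n_ref <- c(AFR = 2L * cfg$panel$n_afr, EUR = 2L * cfg$panel$n_eur,
             NAT = 2L * cfg$nat_pool)
  pops <- lapply(c("AFR", "EUR", "NAT"), function(lab) {
    s <- cfg$sources[[lab]]
    source_pop_config(lab,
                      n_haplotypes = n_ref[[lab]] + cfg$donors_per_pop,
                      n_founders = s$n_founders,
                      divergence_F = s$divergence_F,
                      founder_switch_rate = s$founder_switch_rate,
                      mutation_flip_rate = s$mutation_flip_rate)
  })
  sources <- simulate_sources(chrom, pops, cfg$n_sites, seeds[["sources"]])

  ## reference slice = first haplotypes of each pop; donor slice = rest
  ref_rows <- donor_rows <- integer(0)
  for (lab in c("AFR", "EUR", "NAT")) {
    rows <- which(sources$pop == lab)
    ref_rows <- c(ref_rows, rows[seq_len(n_ref[[lab]])])
    donor_rows <- c(donor_rows, rows[-seq_len(n_ref[[lab]])])
  }
  donors <- hs_haps(sources, donor_rows)

  n_adm <- cfg$panel$n_admixed + cfg$n_targets
  adm_cfg <- admixture_config(
    proportions = c(AFR = cfg$admixture$afr, EUR = cfg$admixture$eur,
                    NAT = cfg$admixture$nat),
    generations_ago = cfg$admixture$generations,
    n_individuals = n_adm)
  adm <- simulate_admixed(donors, adm_cfg, chrom, seeds[["admix"]])

  adm_inds <- unique(adm$haps$ind)
  panel_adm_ids <- adm_inds[seq_len(cfg$panel$n_admixed)]
  target_ids <- setdiff(adm_inds, panel_adm_ids)
  afr_ref <- hs_haps(sources, which(sources$pop == "AFR")[
    seq_len(n_ref[["AFR"]])])
  eur_ref <- hs_haps(sources, which(sources$pop == "EUR")[
    seq_len(n_ref[["EUR"]])])
  nat_pool <- hs_haps(sources, which(sources$pop == "NAT")[
    seq_len(n_ref[["NAT"]])])
  base_panel <- hs_bind(hs_bind(afr_ref, eur_ref),
                        hs_individuals(adm$haps, panel_adm_ids))
  targets <- hs_individuals(adm$haps, target_ids)
  target_tracks <- ancestry_tracks(
    adm$tracks[adm$tracks$ind %in% target_ids, , drop = FALSE],
    chrom$length_bp)

  scheme <- ascertain_sites(
    sources, chrom,
    ascertainment_pop = cfg$array$ascertainment_pop,
    target_mean_spacing_bp = cfg$array$mean_spacing_bp,
    histogram = maf_histogram(proportions =
                                cfg$array$histogram_proportions),
    seed = seeds[["array"]])
  masked <- mask_to_array(targets, scheme)

  adm_freq <- site_frequencies(adm$haps)

  structure(list(
    chrom = chrom, sources = sources, base_panel = base_panel,
    nat_pool = nat_pool, targets = targets,
    target_tracks = target_tracks, admixed_all = adm$haps,
    all_tracks = adm$tracks, scheme = scheme,
    typed_idx = masked$typed_idx, heldout_idx = masked$heldout_idx,
    truth_freq = adm_freq$freq, truth_maf = adm_freq$maf,
    params = ls_params(cfg$ls$ne_eff, cfg$ls$lambda, cfg$ls$min_switch),
    seeds = seeds, config = cfg), class = "study_world")
}

#' Run the full incremental-reference-panel experiment
#'
#' Simulates the study world from the configuration, runs
#' [incremental_experiment()] over the configured added-reference sizes,
#' performs the gap analysis, and assembles a run manifest (resolved
#' configuration, per-stage seeds, package version, aggregation mode).
#'
#' @param cfg A run configuration.
#' @return List of class `experiment_result` with elements `table`
#'   (accuracy table), `gap` (gap analysis), `world`, `manifest`.
#' @export
run_experiment <- function(cfg) {
  cfg <- validate_config(cfg)
  world <- simulate_study(cfg)
  bins <- freq_bins(cfg$bins)
  thr <- quality_threshold(cfg$threshold$min_maf, cfg$threshold$min_info)
  table <- incremental_experiment(world, cfg$sizes, world$params,
                                  bins, thr, mode = cfg$r2_mode)
  gap <- gap_analysis(table)
  manifest <- list(
    config = cfg,
    stage_seeds = as.list(world$seeds),
    n_typed_sites = length(world$typed_idx),
    n_heldout_sites = length(world$heldout_idx),
    r2_mode = cfg$r2_mode,
    package_version = as.character(utils::packageVersion("admiximpute")))
  structure(list(table = table, gap = gap, world = world,
                 manifest = manifest),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %d accuracy rows over sizes %s\n",
              nrow(x$table),
              paste(unique(x$table$added_ref_count), collapse = "/")))
  invisible(x)
}

#' Composition of a reference panel by source
#'
#' Tabulates counts and percentages of panel members by an arbitrary
#' source/origin label (e.g. contributing project or country), for panel
#' bookkeeping and manifests.
#'
#' @param labels Character vector with one origin label per panel member.
#' @return Data frame with columns `source`, `n`, `pct` (percent of the
#'   panel, 0-100).
#' @export
source_composition <- function(labels) {
  tab <- table(labels)
  out <- data.frame(source = names(tab), n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(labels),
                    stringsAsFactors = FALSE)
  out[order(-out$n), , drop = FALSE]
}
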