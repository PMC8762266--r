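#' Stratified squared Pearson correlation of imputed vs true dosages
#'
#' Within each stratum, either all (individual, site) dosage pairs are
#' pooled and a single squared Pearson correlation is computed (default;
#' stable for sparse rare-variant strata), or an r-squared is computed
#' per individual and then averaged (`mode = "per_individual"`). Strata
#' in which either vector has zero variance, or the true dosages take
#' fewer than two distinct values, are flagged undefined (`r2 = NA`),
#' never reported as 0.
#'
#' @param imputed,true Numeric vectors of imputed and true dosages,
#'   aligned element-wise.
#' @param strata Factor or character vector assigning each pair to a
#'   stratum.
#' @param individual Individual identifier per pair; required for
#'   `mode = "per_individual"`.
#' @param mode `"pooled"` or `"per_individual"`.
#' @return Data frame with columns `stratum`, `n`, `r2`, `defined`.
#' @export
dosage_r2 <- function(imputed, true, strata, individual = NULL,
                      mode = c("pooled", "per_individual")) {
  mode <- match.arg(mode)
  n <- length(imputed)
  if (length(true) != n || length(strata) != n)
    stop("`imputed`, `true` and `strata` must be aligned", call. = FALSE)
  if (mode == "per_individual" &&
      (is.null(individual) || length(individual) != n))
    stop("`individual` must be supplied and aligned for per-individual ",
         "aggregation", call. = FALSE)
  r2_one <- function(x, y) {
    if (length(x) < 2L || length(unique(y)) < 2L ||
        stats::var(x) == 0 || stats::var(y) == 0)
      return(NA_real_)
    stats::cor(x, y)^2
  }
  groups <- split(seq_len(n), strata)
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    r2 <- if (mode == "pooled") {
      r2_one(imputed[i], true[i])
    } else {
      per <- vapply(split(i, individual[i]), function(j)
        r2_one(imputed[j], true[j]), numeric(1))
      if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
    }
    data.frame(stratum = g, n = length(i), r2 = r2,
               defined = !is.na(r2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Quality threshold for GWAS-usable variants
#'
#' The standard threshold retains sites with `MAF >= min_maf` (inclusive)
#' and `INFO > min_info` (strict).
#'
#' @param min_maf Minimum minor-allele frequency (default 0.01).
#' @param min_info Minimum INFO score, strict (default 0.3).
#' @return An object of class `quality_threshold`.
#' @export
quality_threshold <- function(min_maf = 0.01, min_info = 0.3) {
  if (min_maf < 0 || min_maf > 0.5)
    stop("`min_maf` must lie in [0, 0.5]", call. = FALSE)
  if (min_info < 0 || min_info > 1)
    stop("`min_info` must lie in [0, 1]", call. = FALSE)
  structure(list(min_maf = min_maf, min_info = min_info),
            class = "quality_threshold")
}

#' Count sites passing the quality threshold
#'
#' @param maf,info Per-site MAF and INFO vectors, aligned.
#' @param thr A [quality_threshold()].
#' @param strata Optional stratum assignment per site; when supplied the
#'   counts are returned per stratum.
#' @return A single count, or a named integer vector per stratum.
#' @export
count_above_threshold <- function(maf, info, thr = quality_threshold(),
                                  strata = NULL) {
  if (length(maf) != length(info))
    stop("`maf` and `info` must be aligned", call. = FALSE)
  pass <- maf >= thr$min_maf & info > thr$min_info
  if (is.null(strata)) return(sum(pass))
  vapply(split(pass, strata), sum, integer(1))
}

#' Per-individual threshold counts from single-sample imputation runs
#'
#' Mirrors per-individual leave-one-out outputs: for each individual the
#' INFO score is computed from that individual's own genotype
#' probabilities (N = 1) while the MAF is taken from the reference panel.
#'
#' @param gp A [genotype_probs()] for the cohort.
#' @param panel_maf Reference-panel MAF per site (aligned with `gp`).
#' @param thr A [quality_threshold()].
#' @param site_idx Optional site indices to restrict the count to (e.g.
#'   held-out sites only).
#' @return Named integer vector of counts, one per individual.
#' @export
per_individual_threshold_counts <- function(gp, panel_maf,
                                            thr = quality_threshold(),
                                            site_idx = NULL) {
  stopifnot(inherits(gp, "genotype_probs"))
  if (length(panel_maf) != ncol(gp$p_AA))
    stop("`panel_maf` must align with the sites of `gp`", call. = FALSE)
  if (is.null(site_idx)) site_idx <- seq_along(panel_maf)
  N <- nrow(gp$p_AA)
  counts <- integer(N)
  for (i in seq_len(N)) {
    one <- genotype_probs(gp$p_AA[i, , drop = FALSE],
                          gp$p_Aa[i, , drop = FALSE],
                          gp$p_aa[i, , drop = FALSE],
                          gp$positions_bp, gp$ind[i])
    info_i <- info_scores(one)
    counts[i] <- count_above_threshold(panel_maf[site_idx],
                                       info_i[site_idx], thr)
  }
  stats::setNames(counts, gp$ind)
}

#' Paired comparison of per-individual counts under two panels
#'
#' Classical two-tailed paired t-test on per-individual differences
#' (panel B minus panel A). Zero-variance differences leave the p-value
#' undefined (flagged), never fabricated.
#'
#' @param counts_a,counts_b Numeric vectors of per-individual counts
#'   under panels A and B (same individuals, `n >= 2`).
#' @return List with `mean_diff`, `t`, `df`, `p_value`, `defined`.
#' @export
compare_panels_paired <- function(counts_a, counts_b) {
  n <- length(counts_a)
  if (length(counts_b) != n)
    stop("count vectors must cover the same individuals", call. = FALSE)
  if (n < 2L) stop("paired comparison requires n >= 2", call. = FALSE)
  d <- counts_b - counts_a
  if (stats::sd(d) == 0)
    return(list(mean_diff = mean(d), t = NA_real_, df = n - 1L,
                p_value = NA_real_, defined = FALSE))
  tt <- stats::t.test(counts_b, counts_a, paired = TRUE,
                      alternative = "two.sided")
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, defined = TRUE)
}

#' Stratified accuracy table for one imputed cohort
#'
#' Evaluates a cohort's imputed genotype probabilities against the truth
#' haplotypes at the held-out (non-array) sites, stratified by
#' local-ancestry diplotype and MAF class. Rows are emitted per
#' (diplotype, bin) cell and additionally per diplotype pooled over bins
#' (`bin = "all"`). Observations in the `EXCLUDED` MAF class are dropped.
#'
#' Before pooling, imputed and true dosages are polarized to the cohort
#' minor allele (`d -> 2 - d` at sites whose truth allele-1 frequency
#' exceeds 0.5). Per-site correlations are invariant to this flip, but a
#' pooled correlation across sites of mixed orientation would otherwise
#' credit allele orientation — true dosages near 0 at minor-allele-0
#' sites, near 2 at minor-allele-1 sites — as imputation accuracy.
#'
#' @param gp A [genotype_probs()] over all panel sites for the targets.
#' @param truth A [haplotype_set()] with the targets' true haplotypes at
#'   all sites.
#' @param tracks [ancestry_tracks()] for the target individuals.
#' @param heldout_idx Indices (into the panel/truth sites) of the
#'   held-out evaluation sites.
#' @param truth_freq Truth allele-1 frequency per site (all sites;
#'   typically from the full admixed cohort); drives both MAF binning
#'   (`maf = min(f, 1 - f)`) and minor-allele polarization.
#' @param bins A [freq_bins()].
#' @param thr A [quality_threshold()].
#' @param mode r-squared aggregation mode, see [dosage_r2()].
#' @return Data frame with columns `diplotype`, `bin`, `n_observations`,
#'   `r2`, `defined`, `mean_info`, `snps_above_threshold`.
#' @export
evaluate_imputation <- function(gp, truth, tracks, heldout_idx, truth_freq,
                                bins = freq_bins(),
                                thr = quality_threshold(),
                                mode = c("pooled", "per_individual")) {
  stopifnot(inherits(gp, "genotype_probs"),
            inherits(truth, "haplotype_set"),
            inherits(tracks, "ancestry_tracks"))
  mode <- match.arg(mode)
  if (!identical(gp$positions_bp, truth$positions_bp))
    stop("`gp` and `truth` are not aligned on the same sites",
         call. = FALSE)
  if (length(truth_freq) != ncol(gp$p_AA))
    stop("`truth_freq` must cover all sites of `gp`", call. = FALSE)
  inds <- gp$ind
  dos <- dosages(gp)[, heldout_idx, drop = FALSE]
  info <- info_scores(gp)[heldout_idx]
  freq_h <- truth_freq[heldout_idx]
  maf_h <- pmin(freq_h, 1 - freq_h)
  pos_h <- truth$positions_bp[heldout_idx]

  true_dos <- t(vapply(inds, function(id) {
    rows <- which(truth$ind == id)
    colSums(truth$alleles[rows, heldout_idx, drop = FALSE])
  }, numeric(length(heldout_idx))))

  ## polarize both dosage matrices to the cohort minor allele
  flip <- freq_h > 0.5
  dos[, flip] <- 2 - dos[, flip, drop = FALSE]
  true_dos[, flip] <- 2 - true_dos[, flip, drop = FALSE]

  strat <- stratify_observations(tracks, inds, pos_h, maf_h, bins)
  ## stratify_observations iterates individuals in order, sites within
  obs_imp <- as.vector(t(dos))
  obs_true <- as.vector(t(true_dos))
  obs_info <- rep(info, times = length(inds))
  obs_maf <- strat$maf
  keep <- strat$bin != "EXCLUDED"

  cell <- function(sel, dip, bin_label) {
    if (!any(sel))
      return(data.frame(diplotype = dip, bin = bin_label,
                        n_observations = 0L, r2 = NA_real_,
                        defined = FALSE, mean_info = NA_real_,
                        snps_above_threshold = 0L,
                        stringsAsFactors = FALSE))
    r <- dosage_r2(obs_imp[sel], obs_true[sel],
                   strata = rep("x", sum(sel)),
                   individual = strat$individual[sel], mode = mode)
    data.frame(diplotype = dip, bin = bin_label,
               n_observations = sum(sel), r2 = r$r2,
               defined = r$defined,
               mean_info = mean(obs_info[sel]),
               snps_above_threshold =
                 count_above_threshold(obs_maf[sel], obs_info[sel], thr),
               stringsAsFactors = FALSE)
  }
  dips <- sort(unique(strat$diplotype[keep]))
  rows <- list()
  for (dip in dips) {
    in_dip <- keep & strat$diplotype == dip
    for (b in bins$labels)
      rows[[length(rows) + 1L]] <- cell(in_dip & strat$bin == b, dip, b)
    rows[[length(rows) + 1L]] <- cell(in_dip, dip, "all")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "r2_mode") <- mode
  out
}

#' Incremental-reference-panel experiment
#'
#' For each requested added-reference size `s`, the panel is the base
#' panel plus the first `s` individuals of the underrepresented-ancestry
#' pool (nested subsets in a fixed order), all targets are imputed, and a
#' stratified accuracy table is emitted keyed by `s`.
#'
#' @param world A simulated study as returned by [simulate_study()] (any
#'   list with elements `base_panel`, `nat_pool`, `targets`,
#'   `target_tracks`, `typed_idx`, `heldout_idx`, `truth_freq`).
#' @param sizes Integer vector of added NAT reference counts, ascending.
#' @param params An [ls_params()].
#' @param bins A [freq_bins()].
#' @param thr A [quality_threshold()].
#' @param mode r-squared aggregation mode, see [dosage_r2()].
#' @return Accuracy table with a leading `added_ref_count` column.
#' @export
incremental_experiment <- function(world, sizes, params = ls_params(),
                                   bins = freq_bins(),
                                   thr = quality_threshold(),
                                   mode = "pooled") {
  sizes <- sort(unique(as.integer(sizes)))
  pool_inds <- unique(world$nat_pool$ind)
  if (max(sizes) > length(pool_inds))
    stop("reference pool holds ", length(pool_inds),
         " individuals; cannot add ", max(sizes), call. = FALSE)
  targets_typed <- hs_sites(world$targets, world$typed_idx)
  out <- list()
  for (s in sizes) {
    panel <- if (s == 0L) world$base_panel else
      hs_bind(world$base_panel,
              hs_individuals(world$nat_pool, pool_inds[seq_len(s)]))
    gp <- impute_cohort(targets_typed, panel, params)
    tab <- evaluate_imputation(gp, world$targets, world$target_tracks,
                               world$heldout_idx, world$truth_freq,
                               bins, thr, mode)
    out[[length(out) + 1L]] <- cbind(added_ref_count = s, tab)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "r2_mode") <- mode
  res
}

#' Gap analysis: added genomes needed to close the accuracy gap
#'
#' For every MAF class in an incremental accuracy table, finds the
#' smallest added-reference size at which the NAT_NAT diplotype reaches
#' the accuracy of the EUR_EUR diplotype, and computes the
#' improvement-over-baseline curve `delta_r2(s) = r2(s) - r2(0)` for the
#' NAT_NAT stratum. Strata with undefined accuracy are skipped, never
#' fabricated.
#'
#' @param table Accuracy table from [incremental_experiment()].
#' @param target_diplotype Underrepresented stratum (default
#'   `"NAT_NAT"`).
#' @param reference_diplotype Well-represented stratum (default
#'   `"EUR_EUR"`).
#' @return List with data frames `gap` (`bin`, `size_needed`, `reached`)
#'   and `delta` (`bin`, `added_ref_count`, `delta_r2`).
#' @export
gap_analysis <- function(table, target_diplotype = "NAT_NAT",
                         reference_diplotype = "EUR_EUR") {
  need <- c("added_ref_count", "diplotype", "bin", "r2")
  if (!all(need %in% names(table)))
    stop("accuracy table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "),
         call. = FALSE)
  bins_present <- setdiff(unique(table$bin), "all")
  gap_rows <- list(); delta_rows <- list()
  for (b in bins_present) {
    tb <- table[table$bin == b, , drop = FALSE]
    nat <- tb[tb$diplotype == target_diplotype, , drop = FALSE]
    eur <- tb[tb$diplotype == reference_diplotype, , drop = FALSE]
    if (!nrow(nat) || !nrow(eur)) {
      gap_rows[[b]] <- data.frame(bin = b, size_needed = NA_integer_,
                                  reached = FALSE, flagged = TRUE)
      next
    }
    sizes <- sort(unique(nat$added_ref_count))
    r2n <- nat$r2[match(sizes, nat$added_ref_count)]
    r2e <- eur$r2[match(sizes, eur$added_ref_count)]
    ok <- !is.na(r2n) & !is.na(r2e)
    hit <- sizes[ok][which(r2n[ok] >= r2e[ok])]
    gap_rows[[b]] <- data.frame(
      bin = b,
      size_needed = if (length(hit)) min(hit) else NA_integer_,
      reached = length(hit) > 0, flagged = !any(ok),
      stringsAsFactors = FALSE)
    base <- r2n[sizes == min(sizes)]
    delta_rows[[b]] <- data.frame(bin = b, added_ref_count = sizes,
                                  delta_r2 = r2n - base,
                                  stringsAsFactors = FALSE)
  }
  gap <- do.call(rbind, gap_rows)
  delta <- do.call(rbind, delta_rows)
  rownames(gap) <- rownames(delta) <- NULL
  list(gap = gap, delta = delta)
}
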