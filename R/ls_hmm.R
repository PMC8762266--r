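#' Parameters of the haplotype-copying hidden Markov model
#'
#' The imputation engine models a target haplotype as an imperfect mosaic
#' of the `H` reference haplotypes (the Li-Stephens model). Between
#' adjacent typed sites separated by `delta` Morgans the copying template
#' switches with probability `s = max(min_switch, 1 - exp(-4 * ne_eff *
#' delta / H))`, landing uniformly on any of the `H` templates; at a typed
#' site the observed allele differs from the copied allele with
#' probability `lambda` (mis-copy / mutation).
#'
#' @param ne_eff Effective population size scaling the switch rate
#'   (default 1e4, the standard Li-Stephens setting).
#' @param lambda Mis-copy probability in (0, 0.5); default 1e-3.
#' @param min_switch Floor on the per-interval switch probability
#'   (default 1e-8), keeping the chain irreducible at zero genetic
#'   distance.
#' @return An object of class `ls_params`.
#' @export
ls_params <- function(ne_eff = 1e4, lambda = 1e-3, min_switch = 1e-8) {
  if (ne_eff <= 0) stop("`ne_eff` must be positive", call. = FALSE)
  if (lambda <= 0 || lambda >= 0.5)
    stop("`lambda` must lie in (0, 0.5)", call. = FALSE)
  if (min_switch < 0 || min_switch >= 1)
    stop("`min_switch` must lie in [0, 1)", call. = FALSE)
  structure(list(ne_eff = ne_eff, lambda = lambda,
                 min_switch = min_switch),
            class = "ls_params")
}

ls_switch_prob <- function(cM, H, params) {
  delta_M <- diff(cM) / 100
  pmin(pmax(params$min_switch, 1 - exp(-4 * params$ne_eff * delta_M / H)),
       1 - 1e-12)
}

ls_emissions <- function(target, panel_t, lambda) {
  ## panel_t: L x H matrix of reference alleles at the typed sites
  E <- lambda + (1 - 2 * lambda) * (panel_t == target)
  E[is.na(target), ] <- 1 # missing target allele: site uninformative
  E
}

#' Copying-state posteriors for one target haplotype
#'
#' Runs the scaled forward-backward algorithm of the haplotype-copying
#' model over the typed sites. Rows of the returned matrix sum to 1.
#'
#' @param target Integer vector of 0/1 target alleles at the typed sites;
#'   `NA` marks a missing observation (the site is skipped for this
#'   haplotype).
#' @param panel Reference alleles at the typed sites: an `H x L` 0/1
#'   matrix (haplotypes in rows) or a [haplotype_set()].
#' @param cM Genetic positions (cM) of the typed sites; taken from the
#'   haplotype set when `panel` is one.
#' @param params An [ls_params()] object.
#' @return `L x H` matrix of posterior copying probabilities.
#' @export
ls_posteriors <- function(target, panel, cM = NULL, params = ls_params()) {
  if (inherits(panel, "haplotype_set")) {
    if (is.null(cM)) cM <- panel$positions_cM
    panel <- panel$alleles
  }
  H <- nrow(panel); L <- length(target)
  if (L < 1L) stop("at least one typed site is required", call. = FALSE)
  if (ncol(panel) != L || length(cM) != L)
    stop("`panel` and `cM` must cover the same typed sites as `target`",
         call. = FALSE)
  if (!all(target %in% c(0L, 1L, NA)))
    stop("target alleles must be 0/1 (NA for missing)", call. = FALSE)
  E <- ls_emissions(target, t(panel), params$lambda)
  s <- if (L > 1L) ls_switch_prob(cM, H, params) else numeric(0)

  Fwd <- matrix(0, L, H)
  f <- E[1L, ] / H
  f <- f / sum(f)
  Fwd[1L, ] <- f
  if (L > 1L) for (j in 2:L) {
    f <- E[j, ] * ((1 - s[j - 1L]) * f + s[j - 1L] / H)
    f <- f / sum(f)
    Fwd[j, ] <- f
  }

  b <- rep(1 / H, H)
  g <- Fwd[L, ] * b
  G <- matrix(0, L, H)
  G[L, ] <- g / sum(g)
  if (L > 1L) for (j in (L - 1L):1L) {
    v <- E[j + 1L, ] * b
    b <- (1 - s[j]) * v + (s[j] / H) * sum(v)
    b <- b / sum(b)
    g <- Fwd[j, ] * b
    G[j, ] <- g / sum(g)
  }
  G
}

#' Allele probabilities at all panel sites for one target haplotype
#'
#' Turns typed-site copying posteriors into a per-site probability that
#' the target haplotype carries allele 1, at every site of the reference
#' panel. At a typed site `j` the probability is
#' `sum_h gamma_j(h) * [(1 - lambda) * a_h + lambda * (1 - a_h)]`. At an
#' untyped site the copying posterior is interpolated linearly in genetic
#' distance between the flanking typed sites (a convex combination, so no
#' renormalization is needed); before the first and after the last typed
#' site the nearest typed-site posterior is used.
#'
#' @param gamma `Lt x H` posterior matrix from [ls_posteriors()].
#' @param panel Reference panel over all sites: `H x L` matrix or
#'   [haplotype_set()].
#' @param typed_idx Integer indices (into the panel's sites) of the typed
#'   sites, in increasing order.
#' @param cM_all Genetic positions of all panel sites; taken from the
#'   haplotype set when `panel` is one.
#' @param lambda Mis-copy probability used in the emission model.
#' @return Numeric vector of length `L`: `P(allele = 1)` per site.
#' @export
interpolate_alleles <- function(gamma, panel, typed_idx, cM_all = NULL,
                                lambda = ls_params()$lambda) {
  if (inherits(panel, "haplotype_set")) {
    if (is.null(cM_all)) cM_all <- panel$positions_cM
    panel <- panel$alleles
  }
  L <- ncol(panel)
  Lt <- length(typed_idx)
  if (nrow(gamma) != Lt)
    stop("`gamma` must have one row per typed site", call. = FALSE)
  if (any(diff(typed_idx) <= 0))
    stop("`typed_idx` must be increasing", call. = FALSE)
  m <- numeric(L)
  ## typed sites: copied-allele probability directly from the posterior
  m[typed_idx] <- rowSums(gamma * t(panel[, typed_idx, drop = FALSE]))
  untyped <- setdiff(seq_len(L), typed_idx)
  if (length(untyped)) {
    left <- findInterval(untyped, typed_idx)
    for (j in unique(left)) {
      u <- untyped[left == j]
      A_u <- panel[, u, drop = FALSE]
      if (j == 0L) {
        m[u] <- as.vector(crossprod(A_u, gamma[1L, ]))
      } else if (j == Lt) {
        m[u] <- as.vector(crossprod(A_u, gamma[Lt, ]))
      } else {
        d_tot <- cM_all[typed_idx[j + 1L]] - cM_all[typed_idx[j]]
        w <- if (d_tot > 0)
          (cM_all[typed_idx[j + 1L]] - cM_all[u]) / d_tot else rep(0.5, length(u))
        gl <- as.vector(crossprod(A_u, gamma[j, ]))
        gr <- as.vector(crossprod(A_u, gamma[j + 1L, ]))
        m[u] <- w * gl + (1 - w) * gr
      }
    }
  }
  (1 - lambda) * m + lambda * (1 - m)
}

#' Impute one haplotype at every panel site
#'
#' Convenience wrapper: runs [ls_posteriors()] on the typed sites and
#' [interpolate_alleles()] over all panel sites.
#'
#' @param target_typed 0/1 alleles of the target haplotype at the typed
#'   sites.
#' @param panel A [haplotype_set()] reference panel (all sites).
#' @param typed_idx Indices of the typed sites within the panel's sites.
#' @param params An [ls_params()].
#' @return Numeric vector of `P(allele = 1)` at every panel site.
#' @export
impute_haplotype <- function(target_typed, panel, typed_idx,
                             params = ls_params()) {
  stopifnot(inherits(panel, "haplotype_set"))
  gamma <- ls_posteriors(target_typed,
                         panel$alleles[, typed_idx, drop = FALSE],
                         panel$positions_cM[typed_idx], params)
  interpolate_alleles(gamma, panel, typed_idx, lambda = params$lambda)
}

#' Genotype probabilities for one diploid individual
#'
#' Imputes each of the individual's two phased haplotypes independently
#' and combines the haploid allele-1 probabilities `a`, `b` into genotype
#' probabilities `P(AA) = (1-a)(1-b)`, `P(Aa) = a(1-b) + (1-a)b`,
#' `P(aa) = ab` (`AA` is homozygous reference).
#'
#' @param hapA_typed,hapB_typed 0/1 alleles of the two haplotypes at the
#'   typed sites (same sites for both).
#' @inheritParams impute_haplotype
#' @return List with numeric vectors `p_AA`, `p_Aa`, `p_aa` over all
#'   panel sites.
#' @export
impute_individual <- function(hapA_typed, hapB_typed, panel, typed_idx,
                              params = ls_params()) {
  if (length(hapA_typed) != length(hapB_typed))
    stop("the two haplotypes must be typed at the same sites",
         call. = FALSE)
  a <- impute_haplotype(hapA_typed, panel, typed_idx, params)
  b <- impute_haplotype(hapB_typed, panel, typed_idx, params)
  list(p_AA = (1 - a) * (1 - b),
       p_Aa = a * (1 - b) + (1 - a) * b,
       p_aa = a * b)
}

## haploid allele-1 probabilities -> (P(AA), P(Aa), P(aa))
combine_haploid_probs <- function(a, b) {
  c((1 - a) * (1 - b), a * (1 - b) + (1 - a) * b, a * b)
}

#' Container for per-individual, per-site genotype probabilities
#'
#' @param p_AA,p_Aa,p_aa `N x L` matrices of genotype probabilities
#'   (rows: individuals); each triplet must be non-negative and sum to 1
#'   within 1e-9.
#' @param positions_bp Site positions (0-based bp).
#' @param ind Individual identifiers (length `N`).
#' @return An object of class `genotype_probs`.
#' @export
genotype_probs <- function(p_AA, p_Aa, p_aa, positions_bp, ind) {
  stopifnot(all(dim(p_AA) == dim(p_Aa)), all(dim(p_AA) == dim(p_aa)))
  if (nrow(p_AA) != length(ind) || ncol(p_AA) != length(positions_bp))
    stop("probability matrices must be N individuals x L sites",
         call. = FALSE)
  tot <- p_AA + p_Aa + p_aa
  if (min(p_AA, p_Aa, p_aa) < -1e-12 || max(abs(tot - 1)) > 1e-9)
    stop("genotype probability triplets must be non-negative and sum to 1",
         call. = FALSE)
  structure(list(p_AA = p_AA, p_Aa = p_Aa, p_aa = p_aa,
                 positions_bp = as.numeric(positions_bp),
                 ind = as.character(ind)),
            class = "genotype_probs")
}

#' @export
print.genotype_probs <- function(x, ...) {
  cat(sprintf("genotype_probs: %d individuals x %d sites\n",
              nrow(x$p_AA), ncol(x$p_AA)))
  invisible(x)
}

#' Impute a cohort of phased target individuals against a panel
#'
#' The targets must be typed at a subset of the panel's sites (matched by
#' physical position). Each individual's two haplotypes are imputed
#' independently; results are assembled into a [genotype_probs()] over
#' all panel sites.
#'
#' @param targets_typed A [haplotype_set()] of target haplotypes at the
#'   typed sites only.
#' @param panel A [haplotype_set()] reference panel.
#' @param params An [ls_params()].
#' @return A [genotype_probs()] for the target individuals.
#' @export
impute_cohort <- function(targets_typed, panel, params = ls_params()) {
  stopifnot(inherits(targets_typed, "haplotype_set"),
            inherits(panel, "haplotype_set"))
  typed_idx <- match(targets_typed$positions_bp, panel$positions_bp)
  if (anyNA(typed_idx))
    stop("targets are typed at sites absent from the panel",
         call. = FALSE)
  inds <- unique(targets_typed$ind)
  L <- n_sites(panel)
  p_AA <- p_Aa <- p_aa <- matrix(0, length(inds), L)
  for (i in seq_along(inds)) {
    rows <- which(targets_typed$ind == inds[i])
    if (length(rows) != 2L)
      stop("individual ", inds[i], " does not have exactly 2 haplotypes",
           call. = FALSE)
    gp <- impute_individual(targets_typed$alleles[rows[1L], ],
                            targets_typed$alleles[rows[2L], ],
                            panel, typed_idx, params)
    p_AA[i, ] <- gp$p_AA; p_Aa[i, ] <- gp$p_Aa; p_aa[i, ] <- gp$p_aa
  }
  genotype_probs(p_AA, p_Aa, p_aa, panel$positions_bp, inds)
}

#' Expected alternate-allele dosages
#'
#' `dosage = P(Aa) + 2 * P(aa)`, in `[0, 2]`.
#'
#' @param gp A [genotype_probs()].
#' @return `N x L` matrix of dosages.
#' @export
dosages <- function(gp) {
  stopifnot(inherits(gp, "genotype_probs"))
  gp$p_Aa + 2 * gp$p_aa
}

#' IMPUTE-style INFO score per site
#'
#' With per-individual expected dosage `e_i = P_i(Aa) + 2 P_i(aa)` and
#' second moment `f_i = P_i(Aa) + 4 P_i(aa)`, the estimated allele
#' frequency is `theta = sum(e_i) / (2N)` and
#' `INFO = 1 - sum(f_i - e_i^2) / (2 N theta (1 - theta))`, the ratio of
#' observed to Hardy-Weinberg dosage information. By convention INFO = 1
#' when `theta` is 0 or 1 (no uncertainty possible); values are clipped
#' to `[0, 1]`.
#'
#' @param gp A [genotype_probs()] (N >= 1 individuals).
#' @return Numeric vector of length `L` of INFO scores.
#' @export
info_scores <- function(gp) {
  stopifnot(inherits(gp, "genotype_probs"))
  N <- nrow(gp$p_AA)
  if (N < 1L) stop("INFO requires at least one individual", call. = FALSE)
  e <- gp$p_Aa + 2 * gp$p_aa
  f <- gp$p_Aa + 4 * gp$p_aa
  theta <- colSums(e) / (2 * N)
  num <- colSums(f - e^2)
  info <- rep(1, ncol(e))
  ok <- theta > 0 & theta < 1
  info[ok] <- 1 - num[ok] / (2 * N * theta[ok] * (1 - theta[ok]))
  pmin(pmax(info, 0), 1)
}
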