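#' Configure a differentiated source population
#'
#' Source populations are generated under a founder-mosaic model: per-site
#' population allele frequencies are drawn from a Balding-Nichols
#' distribution around a shared ancestral frequency, a small set of founder
#' haplotypes samples alleles from those frequencies, and every sampled
#' haplotype is a recombinant mosaic of founders with optional per-site
#' allele flips standing in for mutation. This gives each population
#' realistic allele-frequency differentiation (controlled by
#' `divergence_F`, analogous to F_ST) and within-population linkage
#' disequilibrium (controlled by the founder count and switch rate).
#'
#' @param label Population label, one of `"AFR"`, `"EUR"`, `"NAT"`.
#' @param n_haplotypes Number of haplotypes to sample (>= 2).
#' @param n_founders Number of founder haplotypes (>= 2). Fewer founders
#'   mean stronger haplotype sharing and longer-range LD.
#' @param divergence_F Balding-Nichols differentiation coefficient in
#'   (0, 1); 0 is accepted as the degenerate no-drift limit.
#' @param founder_switch_rate Founder-mosaic switch rate per Morgan (>= 0).
#' @param mutation_flip_rate Per-site allele flip probability (>= 0).
#' @return An object of class `source_pop_config`.
#' @export
source_pop_config <- function(label, n_haplotypes, n_founders = 20L,
                              divergence_F = 0.1,
                              founder_switch_rate = 30,
                              mutation_flip_rate = 0) {
  label <- as.character(label)
  if (length(label) != 1L || !label %in% c("AFR", "EUR", "NAT"))
    stop("`label` must be one of AFR, EUR, NAT", call. = FALSE)
  if (n_haplotypes < 2L) stop("`n_haplotypes` must be >= 2", call. = FALSE)
  if (n_founders < 2L) stop("`n_founders` must be >= 2", call. = FALSE)
  if (divergence_F < 0 || divergence_F >= 1)
    stop("`divergence_F` must lie in [0, 1)", call. = FALSE)
  if (founder_switch_rate < 0 || mutation_flip_rate < 0)
    stop("rates must be non-negative", call. = FALSE)
  structure(list(label = label,
                 n_haplotypes = as.integer(n_haplotypes),
                 n_founders = as.integer(n_founders),
                 divergence_F = divergence_F,
                 founder_switch_rate = founder_switch_rate,
                 mutation_flip_rate = mutation_flip_rate),
            class = "source_pop_config")
}

## Balding-Nichols draw: beta around ancestral frequency q with coefficient F
rbalding_nichols <- function(n, q, F) {
  if (F <= 0) return(q)
  stats::rbeta(n, q * (1 - F) / F, (1 - q) * (1 - F) / F)
}

## Founder index per site for one mosaic haplotype: switch points are a
## Poisson process (per Morgan) along the genetic map; one founder per
## segment, chosen uniformly with replacement.
mosaic_founder_index <- function(site_cM, total_M, n_founders, rate) {
  n_switch <- if (rate > 0) stats::rpois(1L, rate * total_M) else 0L
  if (n_switch == 0L)
    return(rep(sample.int(n_founders, 1L), length(site_cM)))
  breaks <- sort(stats::runif(n_switch, 0, total_M * 100))
  founders <- sample.int(n_founders, n_switch + 1L, replace = TRUE)
  founders[findInterval(site_cM, breaks) + 1L]
}

#' Simulate phased haplotypes for differentiated source populations
#'
#' Draws, for each site, an ancestral allele frequency uniform on
#' (0.02, 0.98), then per-population frequencies from a Balding-Nichols
#' distribution; founder haplotypes sample alleles independently and
#' sampled haplotypes are founder mosaics with Poisson switch points along
#' the genetic map and independent per-site allele flips. Sites that end up
#' monomorphic across all populations are redrawn so that exactly
#' `n_sites` segregating sites are returned (redraws are capped at
#' `10 * n_sites` total site draws).
#'
#' @param chrom A [chromosome_spec()].
#' @param pops List of [source_pop_config()] objects with distinct labels.
#' @param n_sites Number of segregating sites to simulate (>= 2).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [haplotype_set()] containing all populations' haplotypes.
#' @export
simulate_sources <- function(chrom, pops, n_sites, seed) {
  stopifnot(inherits(chrom, "chromosome_spec"))
  if (inherits(pops, "source_pop_config")) pops <- list(pops)
  labels <- vapply(pops, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("population labels must be unique", call. = FALSE)
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("`n_sites` must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))

  positions_bp <- sort(sample.int(chrom$length_bp, n_sites)) - 1
  positions_cM <- bp_to_cM(chrom, positions_bp)
  total_M <- chrom_morgans(chrom)
  H_tot <- sum(vapply(pops, `[[`, integer(1), "n_haplotypes"))

  ## mosaic structure first (fixed), allele columns redrawn as needed
  founder_of <- vector("list", length(pops))
  for (k in seq_along(pops)) {
    p <- pops[[k]]
    founder_of[[k]] <- t(vapply(seq_len(p$n_haplotypes), function(i)
      mosaic_founder_index(positions_cM, total_M, p$n_founders,
                           p$founder_switch_rate),
      integer(n_sites)))
  }

  draw_columns <- function(cols) {
    nc <- length(cols)
    q <- stats::runif(nc, 0.02, 0.98)
    out <- matrix(0L, H_tot, nc)
    row0 <- 0L
    for (k in seq_along(pops)) {
      p <- pops[[k]]
      pk <- rbalding_nichols(nc, q, p$divergence_F)
      if (length(pk) == 1L) pk <- rep(pk, nc)
      founders <- matrix(stats::rbinom(p$n_founders * nc, 1L,
                                       rep(pk, each = p$n_founders)),
                         nrow = p$n_founders)
      fidx <- founder_of[[k]][, cols, drop = FALSE]
      hap <- matrix(founders[cbind(as.vector(fidx),
                                   rep(seq_len(nc), each = p$n_haplotypes))],
                    nrow = p$n_haplotypes)
      if (p$mutation_flip_rate > 0) {
        flips <- matrix(stats::rbinom(p$n_haplotypes * nc, 1L,
                                      p$mutation_flip_rate),
                        nrow = p$n_haplotypes)
        hap <- (hap + flips) %% 2L
      }
      out[row0 + seq_len(p$n_haplotypes), ] <- hap
      row0 <- row0 + p$n_haplotypes
    }
    out
  }

  alleles <- draw_columns(seq_len(n_sites))
  drawn <- n_sites
  repeat {
    cs <- colSums(alleles)
    mono <- which(cs == 0L | cs == H_tot)
    if (!length(mono)) break
    if (drawn + length(mono) > 10L * n_sites)
      stop("monomorphic-site resampling exceeded 10x n_sites draws; ",
           "increase divergence or haplotype counts", call. = FALSE)
    alleles[, mono] <- draw_columns(mono)
    drawn <- drawn + length(mono)
  }

  pop <- rep(labels, vapply(pops, `[[`, integer(1), "n_haplotypes"))
  haplotype_set(alleles, positions_bp, positions_cM, pop)
}
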