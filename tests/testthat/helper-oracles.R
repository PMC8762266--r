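# Independent oracles and small fixture builders used across tests.

# Exhaustive-path posterior oracle for the copying HMM: sums over all H^L
# copying paths explicitly. Independent of the forward-backward code path.
enum_posteriors <- function(target, panel, cM, params) {
  H <- nrow(panel); L <- length(target)
  s <- if (L > 1) {
    pmin(pmax(params$min_switch,
              1 - exp(-4 * params$ne_eff * diff(cM) / 100 / H)),
         1 - 1e-12)
  } else numeric(0)
  lam <- params$lambda
  paths <- as.matrix(expand.grid(rep(list(seq_len(H)), L)))
  np <- nrow(paths)
  E <- matrix(lam, L, H)
  for (j in seq_len(L)) E[j, panel[, j] == target[j]] <- 1 - lam
  logp <- rep(log(1 / H), np)
  for (j in seq_len(L)) {
    logp <- logp + log(E[cbind(rep(j, np), paths[, j])])
    if (j > 1) {
      same <- paths[, j] == paths[, j - 1]
      logp <- logp + log(ifelse(same, (1 - s[j - 1]) + s[j - 1] / H,
                                s[j - 1] / H))
    }
  }
  p <- exp(logp - max(logp))
  post <- matrix(0, L, H)
  for (j in seq_len(L))
    post[j, ] <- vapply(seq_len(H), function(h) sum(p[paths[, j] == h]),
                        numeric(1))
  post / sum(p)
}

# Hudson's two-population F_ST estimator from sample allele frequencies
# (ratio-of-averages form with finite-sample correction).
hudson_fst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Haplotype set with prescribed per-column allele-1 counts.
make_hapset <- function(counts, H, spacing_bp = 1000, pop = "ALL") {
  L <- length(counts)
  alleles <- vapply(counts, function(k) sample(rep(c(1L, 0L), c(k, H - k))),
                    integer(H))
  pos <- seq(0, by = spacing_bp, length.out = L)
  haplotype_set(alleles, pos, pos / 1e4, pop = pop)
}

# Tiny but complete study configuration for fast end-to-end tests.
micro_config <- function(seed = 1L, sizes = c(0L, 10L), n_sites = 600L) {
  cfg <- desk_config(seed = seed, sizes = sizes)
  cfg$n_sites <- n_sites
  cfg$panel <- list(n_afr = 8L, n_eur = 6L, n_admixed = 5L)
  cfg$n_targets <- 4L
  cfg$nat_pool <- max(10L, max(sizes))
  cfg$donors_per_pop <- 20L
  cfg$array$mean_spacing_bp <- 250000L # ~200 typed of 600
  cfg$ls$ne_eff <- 500 # persistent copying over the micro panel sizes
  validate_config(cfg)
}
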