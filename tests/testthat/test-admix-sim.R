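chrom50 <- chromosome_spec(50e6)

test_that("source simulation is deterministic and fully segregating", {
  pops <- list(source_pop_config("AFR", 20, divergence_F = 0.1),
               source_pop_config("EUR", 20, divergence_F = 0.15))
  a <- simulate_sources(chrom50, pops, 300, seed = 7)
  b <- simulate_sources(chrom50, pops, 300, seed = 7)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$positions_bp, b$positions_bp)
  cs <- colSums(a$alleles)
  expect_true(all(cs > 0 & cs < n_haps(a)))
  d <- simulate_sources(chrom50, pops, 300, seed = 8)
  expect_false(identical(a$alleles, d$alleles))
})

test_that("without founder switches every haplotype copies one founder", {
  pops <- list(source_pop_config("NAT", 30, n_founders = 3,
                                 founder_switch_rate = 0,
                                 mutation_flip_rate = 0))
  haps <- simulate_sources(chrom50, pops, 200, seed = 1)
  expect_lte(nrow(unique(haps$alleles)), 3L)
})

test_that("duplicate labels and bad site counts are rejected", {
  pops <- list(source_pop_config("AFR", 10), source_pop_config("AFR", 10))
  expect_error(simulate_sources(chrom50, pops, 100, 1), "unique")
  expect_error(simulate_sources(chrom50,
                                list(source_pop_config("AFR", 10)), 1, 1),
               "n_sites")
})

test_that("realized differentiation matches the Balding-Nichols target", {
  ## Hudson F_ST between two populations, each drifted F from the shared
  ## ancestral frequency, estimates F itself; founder count equals the
  ## sample size so founder resampling adds negligible extra variance.
  for (seed in 1:10) {
    pops <- list(source_pop_config("AFR", 200, n_founders = 200,
                                   divergence_F = 0.1,
                                   mutation_flip_rate = 0),
                 source_pop_config("EUR", 200, n_founders = 200,
                                   divergence_F = 0.1,
                                   mutation_flip_rate = 0))
    haps <- simulate_sources(chrom50, pops, 2000, seed = seed)
    p1 <- colMeans(haps$alleles[haps$pop == "AFR", ])
    p2 <- colMeans(haps$alleles[haps$pop == "EUR", ])
    expect_lt(abs(hudson_fst(p1, p2, 200, 200) - 0.1), 0.03)
  }
})

sources_small <- simulate_sources(
  chrom50,
  list(source_pop_config("AFR", 8, n_founders = 4),
       source_pop_config("EUR", 8, n_founders = 4),
       source_pop_config("NAT", 8, n_founders = 4)),
  n_sites = 20, seed = 3)

test_that("degenerate mixture yields a single full-length tract", {
  cfg <- admixture_config(c(AFR = 1, EUR = 0, NAT = 0),
                          generations_ago = 12, n_individuals = 5)
  adm <- simulate_admixed(sources_small, cfg, chrom50, seed = 2)
  expect_equal(nrow(adm$tracks), 10L)
  expect_true(all(adm$tracks$ancestry == "AFR"))
  expect_true(all(adm$tracks$start_bp == 0))
  expect_true(all(adm$tracks$end_bp == chrom50$length_bp))
})

test_that("tracts tile the chromosome and merge same-ancestry neighbours", {
  cfg <- admixture_config(n_individuals = 20)
  adm <- simulate_admixed(sources_small, cfg, chrom50, seed = 5)
  for (h in split(adm$tracks, adm$tracks$hap)) {
    h <- h[order(h$start_bp), ]
    expect_equal(h$start_bp[1], 0)
    expect_equal(h$end_bp[nrow(h)], chrom50$length_bp)
    if (nrow(h) > 1) {
      expect_equal(h$start_bp[-1], h$end_bp[-nrow(h)])
      expect_true(all(h$ancestry[-1] != h$ancestry[-nrow(h)]))
    }
  }
})

test_that("ancestry-change points match the thinned-Poisson expectation", {
  ## switches at rate g per Morgan are ancestry changes only when the
  ## redrawn ancestry differs: expected changes = g * M * (1 - sum p_k^2)
  chrom1M <- chromosome_spec(100e6) # 1 Morgan
  p <- c(AFR = 1 / 6, EUR = 1 / 3, NAT = 1 / 2)
  cfg <- admixture_config(p, generations_ago = 12, n_individuals = 500)
  adm <- simulate_admixed(sources_small2 <- simulate_sources(
    chrom1M, list(source_pop_config("AFR", 6, n_founders = 3),
                  source_pop_config("EUR", 6, n_founders = 3),
                  source_pop_config("NAT", 6, n_founders = 3)),
    n_sites = 10, seed = 4), cfg, chrom1M, seed = 11)
  changes <- tapply(adm$tracks$hap, adm$tracks$hap, length) - 1
  expected <- 12 * 1 * (1 - sum(p^2))
  se <- stats::sd(changes) / sqrt(length(changes))
  expect_lt(abs(mean(changes) - expected), 3 * se + 0.05)
})

test_that("an ancestry without sources is rejected", {
  two_pop <- hs_haps(sources_small, which(sources_small$pop != "NAT"))
  cfg <- admixture_config(n_individuals = 2)
  expect_error(simulate_admixed(two_pop, cfg, chrom50, seed = 1),
               "NAT")
})

test_that("cohort ancestry fractions recover the nominal proportions", {
  ## grand mean over 20 seeds at 300 individuals on a 2-Morgan chromosome
  chrom2M <- chromosome_spec(200e6)
  src <- simulate_sources(
    chrom2M, list(source_pop_config("AFR", 6, n_founders = 3),
                  source_pop_config("EUR", 6, n_founders = 3),
                  source_pop_config("NAT", 6, n_founders = 3)),
    n_sites = 10, seed = 9)
  cfg <- admixture_config(n_individuals = 300)
  grand <- rowMeans(vapply(1:20, function(s) {
    adm <- simulate_admixed(src, cfg, chrom2M, seed = s)
    ancestry_fractions(adm$tracks)$cohort_mean[c("AFR", "EUR", "NAT")]
  }, numeric(3)))
  expect_lt(abs(grand[["AFR"]] - 1 / 6), 0.01)
  expect_lt(abs(grand[["EUR"]] - 1 / 3), 0.01)
  expect_lt(abs(grand[["NAT"]] - 1 / 2), 0.01)
})

test_that("ancestry fractions equal a brute-force per-bp recount", {
  toy_len <- 10000
  df <- data.frame(
    hap = rep(c("I1.1", "I1.2"), c(3, 2)),
    ind = "I1",
    start_bp = c(0, 1200, 7000, 0, 5000),
    end_bp = c(1200, 7000, 10000, 5000, 10000),
    ancestry = c("AFR", "NAT", "EUR", "EUR", "NAT"))
  tr <- ancestry_tracks(df, toy_len)
  fr <- ancestry_fractions(tr)
  ## brute force: expand every base pair and count labels
  brute <- function(hap) {
    d <- df[df$hap == hap, ]
    lab <- character(toy_len)
    for (i in seq_len(nrow(d)))
      lab[(d$start_bp[i] + 1):d$end_bp[i]] <- d$ancestry[i]
    table(factor(lab, levels = c("AFR", "EUR", "NAT"))) / toy_len
  }
  b1 <- brute("I1.1"); b2 <- brute("I1.2")
  h1 <- fr$per_haplotype[fr$per_haplotype$hap == "I1.1", c("AFR", "EUR", "NAT")]
  expect_equal(unlist(h1, use.names = FALSE), as.vector(b1),
               tolerance = 1e-12)
  expect_equal(unlist(fr$per_individual[1, c("AFR", "EUR", "NAT")],
                      use.names = FALSE),
               as.vector((b1 + b2) / 2), tolerance = 1e-12)
  expect_equal(sum(fr$per_individual[1, c("AFR", "EUR", "NAT")]), 1)
})

test_that("two single-ancestry haplotypes give half-half fractions", {
  df <- data.frame(hap = c("X.1", "X.2"), ind = "X",
                   start_bp = c(0, 0), end_bp = c(100, 100),
                   ancestry = c("EUR", "NAT"))
  fr <- ancestry_fractions(ancestry_tracks(df, 100))
  expect_equal(unlist(fr$per_individual[1, c("EUR", "NAT")],
                      use.names = FALSE), c(0.5, 0.5))
})

test_that("broken tract tilings are rejected", {
  expect_error(ancestry_tracks(data.frame(
    hap = "A.1", ind = "A", start_bp = 10, end_bp = 100,
    ancestry = "AFR"), 100), "tile")
  expect_error(ancestry_tracks(data.frame(
    hap = c("A.1", "A.1"), ind = "A", start_bp = c(0, 60),
    end_bp = c(50, 100), ancestry = c("AFR", "EUR")), 100), "tile")
})

test_that("admixed frequency spectrum is invariant to source ordering", {
  pops <- list(source_pop_config("AFR", 40), source_pop_config("EUR", 40),
               source_pop_config("NAT", 40))
  src <- simulate_sources(chrom50, pops, 1000, seed = 21)
  perm <- unlist(lapply(c("AFR", "EUR", "NAT"), function(p) {
    rows <- which(src$pop == p)
    set.seed(99); sample(rows)
  }))
  src_perm <- hs_haps(src, perm)
  cfg <- admixture_config(n_individuals = 40)
  f1 <- site_frequencies(simulate_admixed(src, cfg, chrom50, 31)$haps)$freq
  f2 <- site_frequencies(simulate_admixed(src_perm, cfg, chrom50, 31)$haps)$freq
  p <- suppressWarnings(stats::ks.test(f1, f2)$p.value)
  expect_gt(p, 0.01)
})
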