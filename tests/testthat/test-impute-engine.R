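params_default <- ls_params()

test_that("a single reference haplotype absorbs all posterior mass", {
  panel <- matrix(c(0L, 1L, 0L, 1L), nrow = 1)
  g <- ls_posteriors(c(0L, 0L, 1L, 1L), panel, cM = c(0, 1, 2, 3),
                     params_default)
  expect_equal(dim(g), c(4L, 1L))
  expect_equal(as.vector(g), rep(1, 4))
})

test_that("a perfectly matching haplotype dominates the posterior", {
  set.seed(5)
  L <- 30
  hstar <- sample(0:1, L, replace = TRUE)
  panel <- rbind(hstar,
                 (hstar + sample(c(0L, 1L), L, TRUE, c(0.7, 0.3))) %% 2L,
                 sample(0:1, L, replace = TRUE))
  ## switch-rate scale chosen so the chain is persistent over the toy
  ## panel (4 * ne_eff * delta / H far below 1 per interval)
  g <- ls_posteriors(hstar, panel, cM = seq(0, 0.29, length.out = L),
                     ls_params(ne_eff = 10, lambda = 1e-6))
  expect_true(all(g[, 1] > 0.99))
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(11)
  for (rep in 1:10) {
    H <- sample(2:4, 1); L <- sample(2:6, 1)
    panel <- matrix(sample(0:1, H * L, replace = TRUE), H, L)
    target <- sample(0:1, L, replace = TRUE)
    cM <- sort(stats::runif(L, 0, 10))
    pr <- ls_params(ne_eff = stats::runif(1, 1e3, 2e4),
                    lambda = stats::runif(1, 1e-4, 0.1))
    g <- ls_posteriors(target, panel, cM, pr)
    expect_equal(g, enum_posteriors(target, panel, cM, pr),
                 tolerance = 1e-10)
    expect_equal(rowSums(g), rep(1, L), tolerance = 1e-9)
  }
})

test_that("posteriors are equivariant under reference relabelling", {
  set.seed(12)
  H <- 6; L <- 15
  panel <- matrix(sample(0:1, H * L, replace = TRUE), H, L)
  target <- sample(0:1, L, replace = TRUE)
  cM <- seq(0, 14, length.out = L)
  g <- ls_posteriors(target, panel, cM, params_default)
  perm <- sample(H)
  g_perm <- ls_posteriors(target, panel[perm, ], cM, params_default)
  expect_equal(g_perm, g[, perm], tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  panel <- matrix(0L, 2, 3)
  expect_error(ls_posteriors(integer(0), panel[, 0, drop = FALSE],
                             numeric(0), params_default), "at least one")
  expect_error(ls_posteriors(c(0L, 2L, 1L), panel, c(0, 1, 2),
                             params_default), "0/1")
})

test_that("interpolation honours genetic distance and panel consensus", {
  ## 2 reference haplotypes over 3 sites; middle site untyped
  panel <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))
  cM <- c(0, 1, 2)
  lam <- 0.01
  gamma <- rbind(c(1, 0), c(0, 1)) # concentrated on different haps
  p <- interpolate_alleles(gamma, panel, typed_idx = c(1L, 3L),
                           cM_all = cM, lambda = lam)
  ## midpoint: gamma_u = (0.5, 0.5); alleles at site 2 are (1, 0)
  expect_equal(p[2], (1 - lam) * 0.5 + lam * 0.5)
  ## typed sites keep their own posterior-weighted allele probability
  expect_equal(p[1], (1 - lam) * 1 + lam * 0)
  expect_equal(p[3], (1 - lam) * 1 + lam * 0)

  ## untyped site at the same genetic position (and allele column) as a
  ## typed site reproduces that site's allele probability
  panel2 <- rbind(c(1L, 1L, 0L), c(0L, 0L, 1L))
  p2 <- interpolate_alleles(gamma, panel2, typed_idx = c(1L, 3L),
                            cM_all = c(0, 0, 2), lambda = lam)
  expect_equal(p2[2], p2[1])

  ## unanimous panel pins the probability at 1 - lambda
  panel3 <- rbind(c(1L, 1L, 1L), c(0L, 1L, 1L))
  p3 <- interpolate_alleles(gamma, panel3, typed_idx = c(1L, 3L),
                            cM_all = cM, lambda = lam)
  expect_equal(p3[2], 1 - lam)
})

test_that("haploid probabilities combine into genotype triplets", {
  comb <- admiximpute:::combine_haploid_probs
  expect_equal(comb(0, 0), c(1, 0, 0))
  expect_equal(comb(1, 0), c(0, 1, 0))
  expect_equal(comb(0.5, 0.3), c(0.35, 0.50, 0.15))
  expect_equal(sum(comb(0.123, 0.987)), 1)
})

test_that("dosage follows P(Aa) + 2 P(aa)", {
  gp <- genotype_probs(p_AA = rbind(c(1, 0, 0.2)),
                       p_Aa = rbind(c(0, 0, 0.5)),
                       p_aa = rbind(c(0, 1, 0.3)),
                       positions_bp = c(0, 10, 20), ind = "I1")
  expect_equal(as.vector(dosages(gp)), c(0, 2, 1.1))
})

test_that("INFO matches the hand-computed formula and conventions", {
  certain <- genotype_probs(rbind(c(1, 0)), rbind(c(0, 0)),
                            rbind(c(0, 1)), c(0, 10), "I1")
  expect_equal(info_scores(certain), c(1, 1)) # no uncertainty
  all_AA <- genotype_probs(rbind(1), rbind(0), rbind(0), 0, "I1")
  expect_equal(info_scores(all_AA), 1)        # theta = 0 convention
  two <- genotype_probs(p_AA = rbind(0.25, 0.25), p_Aa = rbind(0.5, 0.5),
                        p_aa = rbind(0.25, 0.25), 0, c("I1", "I2"))
  ## e = (1,1), f = (1.5,1.5), theta = 0.5 ->
  ## info = 1 - (0.5 + 0.5)/(4 * 0.25) = 0
  expect_equal(info_scores(two), 0)
})

test_that("allele flips mirror dosages and leave INFO unchanged", {
  set.seed(14)
  chrom <- chromosome_spec(10e6)
  src <- simulate_sources(
    chrom, list(source_pop_config("NAT", 30, n_founders = 10)),
    n_sites = 120, seed = 6)
  cfg <- admixture_config(c(AFR = 0, EUR = 0, NAT = 1), 5, 4)
  tg <- simulate_admixed(src, cfg, chrom, seed = 7)$haps
  typed_idx <- seq(1, 120, by = 3)
  gp <- impute_cohort(hs_sites(tg, typed_idx), src, params_default)
  flip_site <- 50L # untyped
  src2 <- src; src2$alleles[, flip_site] <- 1L - src2$alleles[, flip_site]
  tg2 <- tg; tg2$alleles[, flip_site] <- 1L - tg2$alleles[, flip_site]
  gp2 <- impute_cohort(hs_sites(tg2, typed_idx), src2, params_default)
  expect_equal(dosages(gp2)[, flip_site], 2 - dosages(gp)[, flip_site],
               tolerance = 1e-12)
  expect_equal(info_scores(gp2)[flip_site], info_scores(gp)[flip_site],
               tolerance = 1e-9)
  expect_equal(dosages(gp2)[, -flip_site], dosages(gp)[, -flip_site],
               tolerance = 1e-12)
})

test_that("panels with identical sites merge by concatenation", {
  set.seed(15)
  a <- make_hapset(sample(1:9, 30, replace = TRUE), H = 10, pop = "AFR")
  b <- make_hapset(sample(1:5, 30, replace = TRUE), H = 6, pop = "NAT")
  b$ind <- paste0("B_", b$ind); b$hap_labels <- paste0("B_", b$hap_labels)
  for (mode in c("intersect", "cross_impute")) {
    m <- merge_panels(a, b, mode)
    expect_equal(n_haps(m), 16L)
    expect_identical(m$alleles, rbind(a$alleles, b$alleles))
  }
})

test_that("cross-imputation takes the site union and fills by LD", {
  ## panel A: 3 sites, haplotypes either all-0 or all-1 (deterministic LD)
  pos <- c(0, 1000, 2000)
  a <- haplotype_set(rbind(c(0L, 0L, 0L), c(0L, 0L, 0L),
                           c(1L, 1L, 1L), c(1L, 1L, 1L)),
                     pos, pos / 1e4, pop = "AFR")
  ## panel B: typed only at the flanks, missing the middle site
  b <- haplotype_set(rbind(c(1L, 1L), c(0L, 0L)),
                     pos[c(1, 3)], pos[c(1, 3)] / 1e4, pop = "NAT",
                     ind = c("B_1", "B_1", "B_2", "B_2")[c(1, 3)],
                     hap_labels = c("B_1.1", "B_1.2"))
  m <- merge_panels(a, b, "cross_impute")
  expect_equal(m$positions_bp, pos)
  expect_equal(n_haps(m), 6L)
  ## filled middle alleles equal the truth implied by the flanks
  expect_equal(m$alleles[5, 2], 1L)
  expect_equal(m$alleles[6, 2], 0L)
  ## subset union: B's sites are a subset of A's, so union = A's sites
  expect_error(merge_panels(a, haplotype_set(
    rbind(0L, 1L), 5000, 0.5, pop = "NAT",
    ind = c("C_1", "C_1"), hap_labels = c("C_1.1", "C_1.2")),
    "intersect"), "no sites")
})

test_that("leave-one-out recovers a twin but not a private variant", {
  set.seed(16)
  chrom <- chromosome_spec(10e6)
  src <- simulate_sources(
    chrom, list(source_pop_config("NAT", 10, n_founders = 5,
                                  mutation_flip_rate = 0)),
    n_sites = 150, seed = 8)
  ## duplicate individual 1 as a twin (individuals 1 and 2 identical)
  alle <- src$alleles
  alle[3:4, ] <- alle[1:2, ]
  ## give individual 3 a private doubleton at an untyped site
  private_site <- 75L
  alle[, private_site] <- 0L
  alle[5:6, private_site] <- 1L
  panel <- haplotype_set(alle, src$positions_bp, src$positions_cM,
                         pop = "NAT")
  typed_idx <- seq(2, 150, by = 3)
  stopifnot(!private_site %in% typed_idx)
  inds <- unique(panel$ind)
  pr <- ls_params(ne_eff = 100, lambda = 1e-4)
  gp <- leave_one_out_impute(panel, inds[c(1, 3)], typed_idx, pr)
  ## twin retained in the panel: held-out dosages match truth
  heldout <- setdiff(seq_len(150), typed_idx)
  truth1 <- colSums(alle[1:2, heldout])
  expect_gt(stats::cor(dosages(gp)[1, heldout], truth1)^2, 0.99)
  ## the private variant's only carrier was removed: dosage collapses
  expect_lt(dosages(gp)[2, private_site], 0.2)
  gp_in <- impute_cohort(hs_sites(hs_individuals(panel, inds[3]),
                                  typed_idx),
                         panel, pr)
  expect_gt(dosages(gp_in)[1, private_site],
            dosages(gp)[2, private_site])
  expect_error(leave_one_out_impute(panel, "GHOST", typed_idx),
               "absent")
})
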