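test_that("pooled r2 matches a hand-computed Pearson correlation", {
  true <- c(0, 1, 2, 1)
  imp <- c(0, 0.6, 1.4, 1.0)
  ## independent closed-form computation: cov^2 / (varX * varY)
  cv <- sum((imp - mean(imp)) * (true - mean(true))) / 3
  hand <- cv^2 / (sum((imp - mean(imp))^2) / 3 *
                    sum((true - mean(true))^2) / 3)
  got <- dosage_r2(imp, true, rep("s", 4))
  expect_equal(got$r2, hand, tolerance = 1e-12)
  ## perfect and perfectly anti-correlated imputation both give 1
  expect_equal(dosage_r2(true, true, rep("s", 4))$r2, 1)
  expect_equal(dosage_r2(2 - true, true, rep("s", 4))$r2, 1)
})

test_that("degenerate strata are flagged undefined, not zero", {
  got <- dosage_r2(c(0.1, 0.2, 0.3), c(1, 1, 1), rep("s", 3))
  expect_false(got$defined)
  expect_true(is.na(got$r2))
  got2 <- dosage_r2(c(0.5, 0.5), c(0, 2), rep("s", 2))
  expect_false(got2$defined)
})

test_that("r2 is invariant to observation order within a stratum", {
  set.seed(20)
  imp <- stats::runif(50, 0, 2)
  true <- sample(0:2, 50, replace = TRUE)
  perm <- sample(50)
  expect_equal(dosage_r2(imp, true, rep("s", 50))$r2,
               dosage_r2(imp[perm], true[perm], rep("s", 50))$r2)
})

test_that("per-individual aggregation averages per-individual r2", {
  imp <- c(0, 1, 2, 0.1, 0.9, 1.8)
  true <- c(0, 1, 2, 0, 1, 2)
  ind <- rep(c("A", "B"), each = 3)
  got <- dosage_r2(imp, true, rep("s", 6), individual = ind,
                   mode = "per_individual")
  byhand <- mean(c(stats::cor(imp[1:3], true[1:3])^2,
                   stats::cor(imp[4:6], true[4:6])^2))
  expect_equal(got$r2, byhand, tolerance = 1e-12)
})

test_that("threshold counting applies the inclusive/strict rules", {
  maf <- c(0.02, 0.005, 0.02, 0.02, 0.5)
  info <- c(0.9, 0.9, 0.3, 0.31, 1.0)
  expect_equal(count_above_threshold(maf, info), 3L)
  expect_equal(count_above_threshold(rep(0, 5), info), 0L)
  expect_equal(count_above_threshold(maf, info, quality_threshold(0, 0)),
               sum(info > 0))
  by_stratum <- count_above_threshold(maf, info,
                                      strata = c("a", "a", "b", "b", "b"))
  expect_equal(unname(by_stratum), c(1L, 2L))
})

test_that("paired panel comparison matches the closed-form t-test", {
  a <- c(10, 20, 30)
  b <- c(11, 22, 33) # differences 1, 2, 3
  got <- compare_panels_paired(a, b)
  d <- b - a
  t_hand <- mean(d) / (stats::sd(d) / sqrt(3))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 2)
  expect_equal(got$mean_diff, 2)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  ## antisymmetry
  rev <- compare_panels_paired(b, a)
  expect_equal(rev$mean_diff, -got$mean_diff)
  expect_equal(rev$t, -got$t, tolerance = 1e-12)
  expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)
  ## identical counts: flagged undefined
  same <- compare_panels_paired(a, a)
  expect_false(same$defined)
  expect_equal(same$mean_diff, 0)
  expect_error(compare_panels_paired(1, 2), "n >= 2")
})

test_that("gap analysis finds the first size closing the gap", {
  mk <- function(nat, eur) {
    sizes <- c(0, 200, 400, 800)
    rbind(data.frame(added_ref_count = sizes, diplotype = "NAT_NAT",
                     bin = "common", r2 = nat),
          data.frame(added_ref_count = sizes, diplotype = "EUR_EUR",
                     bin = "common", r2 = eur))
  }
  ## crossing between 200 and 400
  g <- gap_analysis(mk(c(0.5, 0.7, 0.92, 0.95), rep(0.9, 4)))
  expect_equal(g$gap$size_needed, 400)
  expect_true(g$gap$reached)
  expect_equal(g$delta$delta_r2, c(0, 0.2, 0.42, 0.45))
  ## already closed at zero
  g0 <- gap_analysis(mk(c(0.9, 0.91, 0.92, 0.93), rep(0.9, 4)))
  expect_equal(g0$gap$size_needed, 0)
  ## never reached
  gn <- gap_analysis(mk(c(0.1, 0.2, 0.3, 0.4), rep(0.9, 4)))
  expect_false(gn$gap$reached)
  expect_true(is.na(gn$gap$size_needed))
})

world_micro <- simulate_study(micro_config(seed = 2, sizes = c(0L, 10L)))

test_that("a single zero size reproduces a plain panel evaluation", {
  tab <- incremental_experiment(world_micro, 0L, world_micro$params)
  gp <- impute_cohort(hs_sites(world_micro$targets,
                               world_micro$typed_idx),
                      world_micro$base_panel, world_micro$params)
  direct <- evaluate_imputation(gp, world_micro$targets,
                                world_micro$target_tracks,
                                world_micro$heldout_idx,
                                world_micro$truth_freq)
  expect_equal(tab[, -1], direct, ignore_attr = TRUE)
  expect_true(all(tab$added_ref_count == 0))
  expect_error(incremental_experiment(world_micro, 1000L),
               "cannot add")
})

test_that("planting the targets in the added references lifts r2 to ~1", {
  w <- world_micro
  dup <- w$targets
  dup$ind <- paste0("DUP_", dup$ind)
  dup$hap_labels <- paste0("DUP_", dup$hap_labels)
  dup$pop <- rep("NAT", length(dup$pop))
  w$nat_pool <- dup
  n_dup <- length(unique(dup$ind))
  tab <- incremental_experiment(w, c(0L, n_dup), w$params)
  all_rows <- tab[tab$bin == "all" & tab$defined, ]
  base <- all_rows[all_rows$added_ref_count == 0, ]
  with_dup <- all_rows[all_rows$added_ref_count == n_dup, ]
  shared <- intersect(base$diplotype, with_dup$diplotype)
  expect_true(all(with_dup$r2[match(shared, with_dup$diplotype)] > 0.99))
  expect_true(mean(with_dup$r2[match(shared, with_dup$diplotype)]) >
                mean(base$r2[match(shared, base$diplotype)]))
})
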