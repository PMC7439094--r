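# Synthetic study generator: determinism, degenerate closed forms,
# design structure, censoring, and Monte-Carlo calibration of the
# injected effects.

null_config <- function(seed, n_metabolites = 50, noise_cv = 0.3,
                        lod_quantile = 0) {
  synthetic_config(n_metabolites = n_metabolites, n_diet_responsive = 0,
                   frac_strain_affected = 0, strain_effect_sd = 0,
                   responder_specs = list(), batch_sd = 0.1,
                   noise_cv = noise_cv, lod_quantile = lod_quantile,
                   seed = seed)
}

test_that("identical config and seed give bit-identical studies", {
  a <- simulate_study(synthetic_config(n_metabolites = 80, seed = 11))
  b <- simulate_study(synthetic_config(n_metabolites = 80, seed = 11))
  expect_identical(a$abundance$values, b$abundance$values)
  expect_identical(a$design, b$design)
  expect_identical(a$truth$lod_censored, b$truth$lod_censored)
  c <- simulate_study(synthetic_config(n_metabolites = 80, seed = 12))
  expect_false(identical(a$abundance$values, c$abundance$values))
})

test_that("noise-free effect-free study reduces to baseline times day factor", {
  cfg <- null_config(seed = 3, noise_cv = 0)
  sim <- simulate_study(cfg)
  expected <- exp(outer(sim$truth$day_factors[as.character(sim$design$run_day)],
                        sim$truth$baseline_log, "+"))
  dimnames(expected) <- dimnames(sim$abundance$values)
  expect_equal(sim$abundance$values, expected, tolerance = 1e-12)
})

test_that("design matches the declared panel: group sizes and totals", {
  sim <- simulate_study(synthetic_config(n_metabolites = 10,
                                         n_diet_responsive = 3, seed = 5))
  tab <- table(sim$design$strain, sim$design$diet)
  expect_equal(sum(tab), 72)
  expect_true(all(tab >= 3 & tab <= 6))
  expect_equal(nlevels(sim$design$strain), 8)
  # round-robin run days: every day holds close to n/4 samples
  expect_true(all(abs(table(sim$design$run_day) - 18) <= 1))
  # explicit group-size override is honored
  gs <- matrix(4L, 8, 2)
  sim2 <- simulate_study(synthetic_config(n_metabolites = 10,
                                          n_diet_responsive = 3,
                                          group_sizes = gs, n_total = 64,
                                          seed = 5))
  expect_true(all(table(sim2$design$strain, sim2$design$diet) == 4))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_diet_responsive = 30, n_metabolites = 20),
               "exceed")
  expect_error(synthetic_config(lod_quantile = 1), "lod_quantile")
  expect_error(synthetic_config(group_size_range = c(1L, 6L)), "below 2")
  expect_error(synthetic_config(
    responder_specs = list(list(strain = "NOPE", set = "fatty_acid",
                                log2fc = 1))), "panel")
})

test_that("censoring removes exactly the lowest LOD fraction per metabolite", {
  cfg <- synthetic_config(n_metabolites = 40, n_diet_responsive = 10,
                          lod_quantile = 0.1, seed = 9)
  sim <- simulate_study(cfg)
  k <- floor(0.1 * nrow(sim$abundance$values))
  expect_true(k >= 1)
  expect_true(all(colSums(is.na(sim$abundance$values)) == k))
  # censored cells recorded in the truth, and they are the low tail:
  # every observed value exceeds the metabolite's censoring threshold
  expect_equal(nrow(sim$truth$lod_censored), k * 40)
  cfg0 <- synthetic_config(n_metabolites = 40, n_diet_responsive = 10,
                           lod_quantile = 0.1, seed = 9,
                           noise_cv = 0)  # same structure, checkable ordering
  expect_true(all(colSums(is.na(simulate_study(cfg0)$abundance$values)) == k))
})

test_that("null generator is calibrated: gated diet tests reject at ~5%", {
  sim <- simulate_study(null_config(seed = 21, n_metabolites = 300))
  d <- sim$design
  rej <- vapply(seq_len(300), function(j) {
    x <- sim$abundance$values[, j]
    suppressWarnings(
      gated_test(list(x[d$diet == "VDS"], x[d$diet == "VDD"]))$p) < 0.05
  }, NA)
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("marginal log-scale spread matches the configured noise CV", {
  cfg <- synthetic_config(n_strains = 1L, strains = "CC011",
                          group_sizes = matrix(50L, 1, 2), n_total = 100,
                          n_metabolites = 150, n_diet_responsive = 0,
                          frac_strain_affected = 0, responder_specs = list(),
                          batch_sd = 0, noise_cv = 0.3, lod_quantile = 0,
                          seed = 31)
  sim <- simulate_study(cfg)
  sds <- apply(log(sim$abundance$values), 2, sd)
  expect_equal(mean(sds), sqrt(log(1 + 0.3^2)), tolerance = 0.03)
})

test_that("responder strain's empirical fold change recovers its target", {
  # strain pinned at 4.5-fold on the fatty-acid subset; ratio of VDD/VDS
  # group means over replicates should sit within 25% of 4.5 at n = 5/group
  ratios <- vapply(1:50, function(r) {
    cfg <- synthetic_config(
      n_strains = 2L, strains = c("CC011", "CC017"),
      group_sizes = matrix(5L, 2, 2), n_total = 20,
      n_metabolites = 30, n_diet_responsive = 13,
      responsive_set_sizes = c(fatty_acid = 13L),
      responder_specs = list(list(strain = "CC017", set = "fatty_acid",
                                  log2fc = log2(4.5))),
      frac_strain_affected = 0, lod_quantile = 0, seed = 400 + r)
    sim <- simulate_study(cfg)
    idx <- sim$design$strain == "CC017"
    v <- sim$abundance$values[, sim$truth$diet_responsive_ids, drop = FALSE]
    mean(colMeans(v[idx & sim$design$diet == "VDD", ]) /
         colMeans(v[idx & sim$design$diet == "VDS", ]))
  }, 0)
  expect_gt(mean(ratios), 4.5 * 0.75)
  expect_lt(mean(ratios), 4.5 * 1.25)
})

test_that("25(OH)D simulation honors closed forms and recovers its means", {
  d <- study_design(data.frame(
    sample_id = paste0("s", 1:8),
    strain = rep(c("CC011", "CC017"), each = 4),
    diet = rep(c("VDS", "VDS", "VDD", "VDD"), 2)))
  v <- simulate_25ohd(d, c(CC011 = 15.9, CC017 = 7.4),
                      c(CC011 = 0.34, CC017 = 0.57), cv = 0)
  expect_equal(unname(v[d$strain == "CC011" & d$diet == "VDD"]),
               rep(10.494, 2))
  expect_equal(unname(v[d$strain == "CC017" & d$diet == "VDD"]),
               rep(3.182, 2))
  expect_true(all(v > 0))
  # Monte-Carlo: sample means recover the configured means within 2 SE
  big <- study_design(data.frame(
    sample_id = paste0("s", 1:200),
    strain = "CC011",
    diet = rep(c("VDS", "VDD"), each = 100)))
  reps <- vapply(1:100, function(r) {
    x <- simulate_25ohd(big, c(CC011 = 15.9), 0.34, cv = 0.2, seed = r)
    c(mean(x[1:100]), mean(x[101:200]))
  }, numeric(2))
  se_vds <- sd(reps[1, ]) / sqrt(100)
  se_vdd <- sd(reps[2, ]) / sqrt(100)
  expect_lt(abs(mean(reps[1, ]) - 15.9), 2 * se_vds)
  expect_lt(abs(mean(reps[2, ]) - 15.9 * 0.66), 2 * se_vdd)
  expect_error(simulate_25ohd(d, c(CC011 = -1, CC017 = 7.4), 0.3),
               "negative")
  expect_error(simulate_25ohd(d, c(CC011 = 15.9, CC017 = 7.4), 1.2),
               "\\[0, 1\\]")
})

test_that("pathway-set construction controls truth overlap exactly", {
  ids <- paste0("m", 1:200)
  truth <- paste0("m", 1:78)
  # set equals universe when asked for all metabolites
  all_in <- make_pathway_sets(paste0("m", 1:10), 10, 0, character(), seed = 1)
  expect_setequal(all_in$responsive_set, paste0("m", 1:10))
  # zero overlap keeps the responsive set disjoint from truth
  s0 <- make_pathway_sets(ids, c(50, 30), 0, truth, seed = 2)
  expect_length(intersect(s0$responsive_set, truth), 0)
  # floor(0.8 * 78) = 62 truth members at overlap 0.8, size 100
  s8 <- make_pathway_sets(ids, 100, 0.8, truth, seed = 3)
  expect_length(intersect(s8$responsive_set, truth), 62)
  expect_length(s8$responsive_set, 100)
  expect_error(make_pathway_sets(ids, 300, 0.5, truth), "exceeds")
  expect_error(make_pathway_sets(ids, 50, 1.4, truth), "\\[0, 1\\]")
})
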