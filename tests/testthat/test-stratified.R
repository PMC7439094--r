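# Stratified statistics: fold changes, percentage reduction, the gated test
# battery, the Brown-Mood median test, Tukey-Kramer letters, and the
# VIP / fold-change selection filter.

test_that("fold change of group means follows its definition", {
  d <- study_design(data.frame(sample_id = paste0("s", 1:6), strain = "A",
                               diet = rep(c("VDS", "VDD"), each = 3)))
  m <- abundance_matrix(matrix(c(1, 1, 1, 2, 2, 2), ncol = 1,
                               dimnames = list(d$sample_id, "met")))
  expect_equal(fold_change(m, d)$fold_change, 2)
  same <- abundance_matrix(matrix(1, 6, 1, dimnames = list(d$sample_id, "m")))
  expect_equal(fold_change(same, d)$fold_change, 1)
  # zero VDS mean is flagged undefined, not dropped
  z <- abundance_matrix(matrix(c(0, 0, 0, 1, 1, 1), ncol = 1,
                               dimnames = list(d$sample_id, "met")))
  fz <- fold_change(z, d)
  expect_true(fz$undefined)
  expect_true(is.na(fz$fold_change))
})

test_that("per-strain fold change tracks an injected responder", {
  # responder pinned at 4.5-fold, noise CV 0.3, n = 5/group: the strain's
  # estimated fold over the responsive set falls in [3.4, 5.6] in at least
  # 90 of 100 replicates
  inside <- vapply(1:100, function(r) {
    cfg <- synthetic_config(
      n_strains = 2L, strains = c("CC011", "CC017"),
      group_sizes = matrix(5L, 2, 2), n_total = 20,
      n_metabolites = 10, n_diet_responsive = 5,
      responsive_set_sizes = c(fatty_acid = 5L),
      responder_specs = list(list(strain = "CC017", set = "fatty_acid",
                                  log2fc = log2(4.5))),
      frac_strain_affected = 0, lod_quantile = 0, batch_sd = 0,
      seed = 700 + r)
    sim <- simulate_study(cfg)
    fc <- fold_change(sim$abundance, sim$design, by_strain = TRUE)
    est <- mean(fc$fold_change[fc$strain == "CC017" &
                            fc$metabolite %in% sim$truth$diet_responsive_ids])
    est >= 3.4 && est <= 5.6
  }, NA)
  expect_gte(mean(inside), 0.9)
})

test_that("percentage reduction matches the printed worked example", {
  d <- study_design(data.frame(sample_id = c("v1", "v2", "d1"),
                               strain = "CC011",
                               diet = c("VDS", "VDS", "VDD")))
  vals <- c(v1 = 15.4, v2 = 16.4, d1 = 10.5)  # VDS mean 15.9
  pr <- pct_reduction_25ohd(vals, d)
  expect_equal(pr$per_sample$pct_change, 100 * (10.5 - 15.9) / 15.9,
               tolerance = 1e-12)
  expect_equal(round(pr$per_strain$mean_pct), -34)
  # VDD sample at the VDS mean -> 0%; all-zero VDD -> -100%
  expect_equal(pct_reduction_25ohd(c(v1 = 15.4, v2 = 16.4, d1 = 15.9),
                                   d)$per_sample$pct_change, 0)
  expect_equal(pct_reduction_25ohd(c(v1 = 15.4, v2 = 16.4, d1 = 0),
                                   d)$per_strain$mean_pct, -100)
  dd <- study_design(data.frame(sample_id = "x", strain = "A", diet = "VDD"))
  expect_error(pct_reduction_25ohd(c(x = 1), dd), "no VDS")
})

test_that("mean of per-sample reductions equals reduction of the mean", {
  set.seed(5)
  d <- study_design(data.frame(sample_id = paste0("s", 1:12), strain = "A",
                               diet = rep(c("VDS", "VDD"), each = 6)))
  v <- setNames(rlnorm(12, 2, 0.3), d$sample_id)
  pr <- pct_reduction_25ohd(v, d)
  vds_mean <- mean(v[1:6])
  expect_equal(pr$per_strain$mean_pct,
               100 * (mean(v[7:12]) - vds_mean) / vds_mean,
               tolerance = 1e-12)
})

test_that("the gated battery picks the branch the assumptions dictate", {
  set.seed(11)
  a <- rnorm(20); b <- rnorm(20, 3)
  res <- gated_test(list(a, b))
  expect_true(res$branch %in% c("parametric", "welch"))
  expect_lt(res$p, 0.001)
  # identical constant groups: degenerate, p = 1, with a warning
  expect_warning(res0 <- gated_test(list(rep(1, 5), rep(1, 5))), "identical")
  expect_equal(res0$p, 1)
  # heavy-tailed data routes to the rank tests most of the time
  nonpar <- vapply(1:100, function(s) {
    set.seed(s + 300)
    gated_test(list(rlnorm(15, 0, 1), rlnorm(15, 0, 1)))$branch ==
      "nonparametric"
  }, NA)
  expect_gt(mean(nonpar), 0.5)
  # >2 groups use ANOVA-family or Kruskal-Wallis
  set.seed(12)
  res3 <- gated_test(list(rnorm(15), rnorm(15), rnorm(15, 0, 4)))
  expect_true(res3$test %in% c("welch-anova", "kruskal-wallis"))
  expect_error(gated_test(list(rnorm(5))), "at least two")
  expect_error(gated_test(list(rnorm(5), 1)), "at least 2")
})

test_that("gated branch rate under normal data tracks the gate level", {
  # with normal groups the nonparametric branch fires when either group's
  # Shapiro-Wilk false-positives: rate approx 1 - 0.95^2 = 0.0975
  rate <- mean(vapply(1:200, function(s) {
    set.seed(s + 5000)
    gated_test(list(rnorm(15), rnorm(15)))$branch == "nonparametric"
  }, NA))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.18)
})

test_that("median test matches contingency-table oracles", {
  # separated groups: all of one below, all of the other above the grand
  # median; Fisher p for the 3/3 split is 0.1
  res <- median_test(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(res$p, 0.1, tolerance = 1e-10)
  expect_identical(res$method, "fisher")
  expect_equal(median_test(list(c(1, 2, 3), c(1, 2, 3)))$p, 1)
  # agreement with direct table tests across random instances
  for (s in 1:50) {
    set.seed(s + 40)
    g1 <- rnorm(sample(6:15, 1)); g2 <- rnorm(sample(6:15, 1), sd = 2)
    res <- median_test(list(g1, g2))
    grand <- median(c(g1, g2))
    tab <- rbind(c(sum(g1 <= grand), sum(g1 > grand)),
                 c(sum(g2 <= grand), sum(g2 > grand)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- if (any(expected < 5)) fisher.test(tab)$p.value else
      chisq.test(tab, correct = FALSE)$p.value
    expect_equal(res$p, oracle, tolerance = 1e-8)
  }
})

test_that("Tukey-Kramer reproduces the studentized-range oracle", {
  set.seed(21)
  groups <- list(a = rnorm(10), b = rnorm(10, 0.5), c = rnorm(10, 3))
  tk <- tukey_kramer(groups)
  for (r in seq_len(nrow(tk$pairwise))) {
    i <- match(tk$pairwise$group1[r], names(groups))
    j <- match(tk$pairwise$group2[r], names(groups))
    expect_equal(tk$pairwise$p[r], unname(oracle_tukey_p(groups, i, j)),
                 tolerance = 1e-6)
  }
  # unbalanced groups still match the Kramer-corrected oracle
  set.seed(22)
  ub <- list(a = rnorm(5), b = rnorm(12, 1), c = rnorm(8, 2), d = rnorm(6))
  tku <- tukey_kramer(ub)
  for (r in seq_len(nrow(tku$pairwise))) {
    i <- match(tku$pairwise$group1[r], names(ub))
    j <- match(tku$pairwise$group2[r], names(ub))
    expect_equal(tku$pairwise$p[r], unname(oracle_tukey_p(ub, i, j)),
                 tolerance = 1e-6)
  }
})

test_that("compact letters separate exactly the significant pairs", {
  set.seed(23)
  # exactly equal observed means: no pair can be significant
  eq <- lapply(1:3, function(i) { x <- rnorm(10); x - mean(x) })
  names(eq) <- c("a", "b", "c")
  expect_equal(unname(tukey_kramer(eq)$letters), c("a", "a", "a"))
  sep <- list(a = rnorm(10, 0), b = rnorm(10, 0), c = rnorm(10, 10))
  expect_equal(unname(tukey_kramer(sep)$letters), c("a", "a", "b"))
  expect_error(tukey_kramer(list(rnorm(5), rnorm(5))), "3 groups")
  expect_error(tukey_kramer(list(a = 1, b = rnorm(3), c = rnorm(3))),
               "at least 2")
})

test_that("statistics are invariant to sample reordering", {
  set.seed(24)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  gp <- lapply(g, sample)
  expect_equal(suppressWarnings(gated_test(g)$p),
               suppressWarnings(gated_test(gp)$p), tolerance = 1e-12)
  expect_equal(median_test(g)$p, median_test(gp)$p, tolerance = 1e-12)
  expect_equal(tukey_kramer(g)$letters, tukey_kramer(gp)$letters)
})

test_that("the VIP / fold-change filter applies inclusive thresholds", {
  vip <- data.frame(metabolite = c("m1", "m2", "m3", "m4"),
                    vip_pred = 1, vip_ortho = 1,
                    rms_vip = c(1.5, 1.49, 2.0, 2.0))
  resp <- data.frame(metabolite = c("m1", "m2", "m3", "m4"),
                     fold_change = c(2.0, 3.0, 0.6, 1.2))
  out <- robust_change_filter(vip, resp)
  # VIP exactly 1.5 is included; 1.49 is not
  expect_equal(out$selected, c(TRUE, FALSE, TRUE, TRUE))
  # FC 0.6 counts as robust (1/0.6 >= 1.5); FC 1.2 does not
  expect_equal(out$robust, c(TRUE, FALSE, TRUE, FALSE))
  resp_bad <- resp[1:3, ]
  expect_error(robust_change_filter(vip, resp_bad), "different")
})

test_that("the strain response table assembles all per-metabolite pieces", {
  st <- small_corrected_study(seed = 53, n_metabolites = 8)
  tab <- strain_response_table(st$pp, st$sim$design)
  expect_equal(nrow(tab$per_metabolite), 8)
  expect_true(all(tab$per_metabolite$diet_p >= 0 &
                    tab$per_metabolite$diet_p <= 1, na.rm = TRUE))
  expect_equal(nrow(tab$per_strain), 8 * 8)  # 8 strains x 8 metabolites
  expect_true(all(tab$per_strain$fold_change > 0))
  letts <- tab$per_strain$tukey_letter
  expect_true(all(nchar(letts[!is.na(letts)]) >= 1))
  # BH columns are monotone transforms of the raw p-values
  expect_true(all(tab$per_metabolite$diet_q_bh >=
                    tab$per_metabolite$diet_p - 1e-12, na.rm = TRUE))
})
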