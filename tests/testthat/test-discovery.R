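test_that("the Cox screen recovers a known hazard ratio", {
  set.seed(401)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t_true <- rexp(n, rate = 0.2 * 0.5^x) # true HR 0.5 per unit of x
  res <- cox_univariate(x, t_true, rep(1, n))
  expect_equal(res$status, "ok")
  expect_gt(res$effect, 0.4)
  expect_lt(res$effect, 0.62)
  expect_lt(res$p_value, 0.001)
  expect_true(res$ci_low < res$effect & res$effect < res$ci_high)
})

test_that("Cox p-values are uniform under label permutation", {
  set.seed(402)
  n <- 120
  x <- rnorm(n)
  time <- rexp(n, 0.2)
  event <- rbinom(n, 1, 0.8)
  p <- replicate(200, cox_univariate(sample(x), time, event)$p_value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("degenerate Cox inputs are reported as skip-status rows", {
  expect_equal(cox_univariate(rep(0, 10), rexp(10), rep(1, 10))$status,
               "skipped_constant")
  expect_equal(cox_univariate(rnorm(10), rexp(10), rep(0, 10))$status,
               "skipped_sparse")
})

test_that("perfect separation reports an unbounded HR with a log-rank p", {
  # covariate splits survival perfectly: monotone likelihood
  time <- c(1, 2, 3, 4, 50, 60, 70, 80)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_warning(res <- cox_univariate(x, time, rep(1, 8)), "monotone")
  expect_equal(res$status, "ok")
  expect_true(is.infinite(res$effect) || res$effect == 0)
  expect_lt(res$p_value, 0.05)
})

test_that("KM medians and the log-rank test match hand-computable cases", {
  km <- km_logrank(c(rep(0, 5), rep(1, 5)), c(1:5, 6:10), rep(1, 10))
  td <- tidy(km)
  expect_equal(td$median[td$group == "without AE"], 3)
  expect_equal(td$median[td$group == "with AE"], 8)
  expect_lt(glance(km)$p_value, 0.01)
  expect_equal(nrow(km$at_risk), 2 * length(seq(0, 10, by = 5)))

  # identical groups: no separation at all
  km0 <- km_logrank(rep(c(0, 1), each = 10), rep(1:10, 2), rep(1, 20))
  expect_equal(glance(km0)$statistic, 0, tolerance = 1e-12)
  expect_equal(glance(km0)$p_value, 1)

  # single patient per group
  km1 <- km_logrank(c(0, 1), c(4, 9), c(1, 1))
  expect_equal(sort(unname(km1$medians)), c(4, 9))

  # one group only: medians still computed, p undefined
  km2 <- km_logrank(rep(1, 5), 1:5, rep(1, 5))
  expect_true(is.na(glance(km2)$p_value))
})

test_that("the DC-vs-PD comparison is powered for cohort-sized duration shifts", {
  set.seed(403)
  hits <- replicate(500, {
    dc <- rnorm(18, 26.7, 15)
    pd <- rnorm(12, 9.8, 15)
    r <- ttest_response(c(dc, pd), rep(c("DC", "PD"), c(18, 12)))
    r$effect > 0 && r$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("t-test handles degenerate and NE-contaminated input", {
  expect_equal(ttest_response(rep(3, 10), rep(c("DC", "PD"), 5))$effect, 0)
  expect_equal(ttest_response(rep(3, 10), rep(c("DC", "PD"), 5))$p_value, 1)
  expect_equal(ttest_response(rnorm(5), c("DC", rep("PD", 4)))$status,
               "skipped_sparse")
  # NA groups (NE patients) are dropped, not counted
  r <- ttest_response(c(rnorm(8), 99, 99),
                      c(rep(c("DC", "PD"), 4), NA, NA))
  expect_equal(r$n_used, 8)
})

test_that("t-test p agrees with its permutation-null counterpart", {
  set.seed(404)
  x <- rnorm(30)
  labels <- rep(c("DC", "PD"), c(18, 12))
  obs <- ttest_response(x, labels)
  perm <- replicate(500, ttest_response(x, sample(labels))$p_value)
  emp <- mean(perm <= obs$p_value)
  mc_se <- sqrt(obs$p_value * (1 - obs$p_value) / 500)
  expect_lt(abs(emp - obs$p_value), 4 * mc_se + 0.02)
})

test_that("DOT correlation behaves at its boundary cases", {
  dot <- runif(20, 0.5, 24)
  expect_equal(pearson_dot(dot, dot)$effect, 1)
  expect_equal(pearson_dot(-dot, dot)$effect, -1)
  expect_equal(pearson_dot(rep(1, 20), dot)$status, "skipped_constant")
  set.seed(405)
  r <- pearson_dot(rnorm(1000), rexp(1000, 0.3))
  expect_lt(abs(r$effect), 0.08)
  rs <- pearson_dot(dot^3, dot, method = "spearman")
  expect_equal(rs$effect_kind, "spearman_rho")
  expect_equal(rs$effect, 1)
})

test_that("Cox and log-rank agree on rejection for occurrence splits", {
  set.seed(406)
  agree <- replicate(200, {
    n <- 60
    x <- rbinom(n, 1, 0.5)
    hr <- sample(c(1, 0.6, 1.6), 1)
    time <- rexp(n, 0.2 * hr^x)
    event <- as.integer(time < quantile(time, 0.9))
    pc <- cox_univariate(x, time, event)$p_value
    pl <- glance(km_logrank(x, time, event))$p_value
    (pc < 0.05) == (pl < 0.05)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("run_discovery emits exactly 96 ordered rows per scope", {
  sim <- simulate_cohort(sim_config(n_patients = 30, seed = 407))
  bm <- suppressWarnings(derive_matrix(sim$cohort, "overall", landmark_day = 30))
  expect_message(res <- suppressWarnings(run_discovery(bm, sim$clinical)), "30 patients")
  expect_equal(nrow(res), 96)
  expect_equal(as.character(unique(res$scope_name)), "overall")
  # deterministic: same call, same table
  res2 <- suppressMessages(suppressWarnings(run_discovery(bm, sim$clinical)))
  expect_equal(tidy(res), tidy(res2))
  # canonical ordering: stratum blocks of 16, outcome cycles of 4
  expect_equal(as.character(res$outcome[1:4]),
               c("PFS", "OS", "DC_vs_PD", "DOT"))
  expect_equal(as.character(unique(res$stratum)), stratum_levels_for_test())
  pv <- attr(res, "provenance")
  expect_equal(pv$landmark_day, 30)
  expect_equal(pv$n_scopes, 1)
})

test_that("sparse scopes are skipped wholesale but still reported", {
  # single affected patient < default floor of 3
  ev <- tibble::tibble(
    patient_id = "P01", term = "Rare AE", category = "X",
    onset_day = 5L, resolution_day = 9L, grade = 2L,
    attribution = "possible")
  coh <- ae_cohort(ev, patients = sprintf("P%02d", 1:20))
  clin <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    pfs_months = rexp(20, 0.2), pfs_event = 1L,
    os_months = rexp(20, 0.1), os_event = 1L,
    best_response = rep(c("SD", "PD"), 10), dot_months = rexp(20, 0.3))
  bm <- derive_matrix(coh, "term")
  res <- suppressMessages(run_discovery(bm, clin))
  expect_equal(nrow(res), 96)
  expect_true(all(res$status == "skipped_sparse"))
  expect_true(all(is.na(res$effect)))
})

test_that("significant-row summaries annotate direction and keep BH aside", {
  # planted protective occurrence effect
  cfg <- sim_config(
    n_patients = 300,
    effect_links = effect_link("low_grade", "occurrence", "PFS", log(0.4)),
    seed = 408)
  sim <- simulate_cohort(cfg)
  bm <- suppressWarnings(derive_matrix(sim$cohort, "overall", landmark_day = 30))
  res <- suppressMessages(suppressWarnings(run_discovery(bm, sim$clinical)))
  sig <- summarize_significant(res)
  planted <- sig[sig$stratum == "low_grade" &
                   sig$measurement == "occurrence" & sig$outcome == "PFS", ]
  expect_equal(nrow(planted), 1)
  expect_lt(planted$effect, 1)
  expect_equal(planted$direction, "improved survival")
  expect_true(all(c("p_adj", "direction") %in% names(sig)))
  expect_true(all(sig$p_value < 0.05))

  # empty in, empty out
  empty <- summarize_significant(res[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("discovery glance tallies statuses coherently", {
  sim <- simulate_cohort(sim_config(n_patients = 25, seed = 409))
  bm <- suppressWarnings(derive_matrix(sim$cohort, "category", landmark_day = 30))
  res <- suppressMessages(suppressWarnings(run_discovery(bm, sim$clinical)))
  g <- glance(res)
  expect_equal(g$n_rows, nrow(res))
  expect_equal(g$n_ok + g$n_skipped_sparse + g$n_skipped_constant,
               g$n_rows)
  expect_equal(g$n_rows, 96 * g$n_scopes)
})

test_that("disjoint patient universes are a hard error", {
  sim <- simulate_cohort(sim_config(n_patients = 10, seed = 410))
  bm <- suppressWarnings(derive_matrix(sim$cohort, "overall"))
  clin <- sim$clinical
  clin$patient_id <- paste0("OTHER-", clin$patient_id)
  expect_error(suppressMessages(run_discovery(bm, clin)), "no patients")
})
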