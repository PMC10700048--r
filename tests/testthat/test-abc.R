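test_that("direct approach equals brute-force nearest-neighbour counting", {
  set.seed(81)
  for (setup in list(c(n = 30, k = 10), c(n = 200, k = 50),
                     c(n = 1000, k = 500))) {
    n <- setup[["n"]]; k <- setup[["k"]]
    stats <- matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("S", 1:6)))
    scen <- sample(1:4, n, replace = TRUE)
    ref <- make_toy_ref(stats, scen)
    obs <- setNames(rnorm(6), paste0("S", 1:6))
    got <- direct_pp(ref, obs, k = k)
    expect_equal(got$pp, direct_pp_oracle(ref, obs, k))
    expect_equal(sum(got$pp), 1, tolerance = 1e-9)
    expect_true(all(got$ci_lower <= got$pp & got$pp <= got$ci_upper))
  }
})

test_that("direct approach: degenerate and symmetric configurations", {
  set.seed(82)
  # all k nearest from one scenario
  stats <- matrix(c(rnorm(40, 0), rnorm(40, 50)), ncol = 1)
  ref <- make_toy_ref(cbind(S1 = stats[, 1], S2 = rnorm(80)),
                      rep(c(2, 1), each = 40))
  got <- direct_pp(ref, c(S1 = 0, S2 = 0), k = 20)
  expect_equal(got$pp[got$scenario == 2], 1)
  # iid rows across 8 scenarios: each PP near 1/8
  stats <- matrix(rnorm(4000 * 3), ncol = 3,
                  dimnames = list(NULL, paste0("S", 1:3)))
  ref <- make_toy_ref(stats, rep(1:8, 500))
  got <- direct_pp(ref, setNames(rnorm(3), paste0("S", 1:3)), k = 800)
  expect_true(all(abs(got$pp - 1 / 8) < 4 * sqrt(0.125 * 0.875 / 800)))
})

test_that("model choice is invariant to row duplication and affine scaling", {
  set.seed(83)
  stats <- matrix(rnorm(300 * 4), 300, 4,
                  dimnames = list(NULL, paste0("S", 1:4)))
  scen <- rep(1:3, each = 100)
  ref <- make_toy_ref(stats, scen)
  obs <- setNames(rnorm(4), paste0("S", 1:4))
  base <- direct_pp(ref, obs, k = 60)
  dup <- make_toy_ref(rbind(stats, stats), c(scen, scen))
  both <- direct_pp(dup, obs, k = 120)
  expect_equal(both$pp, base$pp)
  expect_true(all(both$ci_upper - both$ci_lower <=
                    base$ci_upper - base$ci_lower + 1e-12))
  # affine rescaling of a statistic column (applied to table and observed)
  scaled <- ref
  scaled$stats[, 2] <- 1000 * scaled$stats[, 2] + 7
  obs2 <- obs
  obs2[2] <- 1000 * obs2[2] + 7
  expect_equal(direct_pp(scaled, obs2, k = 60)$pp, base$pp)
  lg1 <- logistic_pp(ref, obs, fraction = 0.4)
  lg2 <- logistic_pp(scaled, obs2, fraction = 0.4)
  expect_equal(lg1$pp, lg2$pp, tolerance = 1e-6)
})

test_that("logistic approach separates clean clouds and flags degenerate subsets", {
  set.seed(84)
  stats <- rbind(matrix(rnorm(200 * 2, 0), ncol = 2),
                 matrix(rnorm(200 * 2, 4), ncol = 2))
  colnames(stats) <- c("S1", "S2")
  ref <- make_toy_ref(stats, rep(1:2, each = 200))
  got <- logistic_pp(ref, c(S1 = 0.2, S2 = -0.1), fraction = 0.6)
  expect_gt(got$pp[got$scenario == 1], 0.99)
  expect_equal(sum(got$pp), 1, tolerance = 1e-9)
  # tiny fraction selects a single scenario: warning and PP = 1
  expect_warning(one <- logistic_pp(ref, c(S1 = 0, S2 = 0),
                                    fraction = 0.02),
                 "single scenario")
  expect_equal(one$pp[one$scenario == 1], 1)
})

test_that("regression adjustment beats raw counting on a mean-shift problem", {
  # two scenarios differ by a 2-SD shift of one statistic; pods from
  # scenario 1 should earn a higher average PP under the logistic
  # approach than under the direct approach
  set.seed(85)
  n <- 1500
  stats <- cbind(S1 = c(rnorm(n, 0), rnorm(n, 2)),
                 S2 = rnorm(2 * n))
  ref <- make_toy_ref(stats, rep(1:2, each = n))
  pods <- 100
  pp_d <- pp_l <- numeric(pods)
  for (i in seq_len(pods)) {
    obs <- c(S1 = rnorm(1, 0), S2 = rnorm(1))
    pp_d[i] <- direct_pp(ref, obs, k = 100)$pp[1]
    pp_l[i] <- suppressWarnings(logistic_pp(ref, obs,
                                            fraction = 0.05))$pp[1]
  }
  expect_gt(mean(pp_l), mean(pp_d))
})

test_that("prior error rate reflects scenario distinguishability", {
  # two scenarios identical by construction: error rate near 1/2
  base <- two_deme_scenario()
  twin <- base; twin$id <- 2
  pr <- prior_spec(n_bounds = c(50, 500), t_bounds = c(20, 400))
  gr <- group_config(c(A = 5, B = 5))
  ref <- build_reference_table(list(base, twin), pr, gr, n_loci = 40,
                               n_per_scenario = 120, seed = 86,
                               trios = list())
  pe <- prior_error_rate(ref, true_scenario = 98, n_pods = 40,
                         method = "direct", k = 40, seed = 87)
  se3 <- 3 * sqrt(0.25 / 40)
  expect_lt(abs(pe$error_rate - 0.5), se3 + 0.05)
  # near-disjoint summary-statistic supports: errors become rare.  The
  # competitor's rows are simulated under huge sizes and shallow splits
  # (no drift), the true scenario under strong drift.
  slow <- base; slow$id <- 2
  refA <- build_reference_table(list(base),
                                prior_spec(n_bounds = c(20, 200),
                                           t_bounds = c(200, 400)),
                                gr, 40, 120, seed = 88, trios = list())
  refB <- build_reference_table(list(slow),
                                prior_spec(n_bounds = c(5e4, 6e5),
                                           t_bounds = c(20, 60)),
                                gr, 40, 120, seed = 89, trios = list())
  refAB <- combine_reference_tables(refA, refB)
  refAB$meta$scenarios <- list(base, slow)
  refAB$meta$priors <- prior_spec(n_bounds = c(20, 200),
                                  t_bounds = c(200, 400))
  pe2 <- prior_error_rate(refAB, true_scenario = 98, n_pods = 25,
                          method = "direct", k = 20, seed = 90)
  expect_lt(pe2$error_rate, 0.2)
})

test_that("ties in the winning probability count as errors", {
  # a reference table whose two scenarios are mirror-identical rows forces
  # frequent exact ties at small k
  stats <- matrix(rep(rnorm(40), 2), ncol = 1)
  colnames(stats) <- "S1"
  ref <- make_toy_ref(cbind(stats, S2 = rep(rnorm(40), 2)),
                      rep(1:2, each = 40))
  got <- direct_pp(ref, c(S1 = 0, S2 = 0), k = 10)
  expect_equal(sum(got$pp), 1)
})

test_that("posterior estimation: degenerate acceptance returns the row itself", {
  set.seed(91)
  sc <- builtin_scenarios()[[1]]
  pr <- estimation_priors()
  draws <- sample_prior(sc, pr, n = 60)
  stats <- cbind(S1 = draws[, "t4"] / 100 + rnorm(60, 0, 0.01),
                 S2 = log(draws[, "NA"]) + rnorm(60, 0, 0.01))
  ref <- make_toy_ref(stats, rep(1, 60), priors = pr)
  ref$params[, colnames(draws)] <- draws
  obs <- stats[17, ]
  post <- estimate_parameters(ref, obs, 1, fraction = 1 / 60, min_rows = 1)
  expect_equal(post$summary$mean[post$summary$parameter == "t4"],
               unname(draws[17, "t4"]), tolerance = 1e-6)
  expect_equal(post$summary$mean[post$summary$parameter == "NA"],
               unname(draws[17, "NA"]), tolerance = 1e-4)
})

test_that("uninformative statistics leave the posterior equal to the prior", {
  set.seed(92)
  sc <- builtin_scenarios()[[1]]
  pr <- estimation_priors()
  n <- 1200
  draws <- sample_prior(sc, pr, n = n)
  stats <- matrix(rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("S", 1:5)))
  ref <- make_toy_ref(stats, rep(1, n), priors = pr)
  ref$params[, colnames(draws)] <- draws
  obs <- setNames(rnorm(5), paste0("S", 1:5))
  post <- estimate_parameters(ref, obs, 1, fraction = 0.25)
  prior_sample <- sample_prior(sc, pr, n = 5000)
  for (p in c("N2", "t3")) {
    ks <- suppressWarnings(stats::ks.test(post$draws[, p],
                                          prior_sample[, p]))
    expect_gt(ks$p.value, 0.001)
  }
  # quantiles are monotone and within prior bounds
  s <- post$summary
  expect_true(all(s$q025 <= s$q05 & s$q05 <= s$q50 & s$q50 <= s$q95 &
                    s$q95 <= s$q975))
  for (i in seq_len(nrow(s))) {
    b <- prior_bounds_for(pr, s$parameter[i])
    expect_gte(s$q025[i], b[1])
    expect_lte(s$q975[i], b[2])
  }
})

test_that("insufficient acceptance raises instead of degrading silently", {
  stats <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("S1", "S2")))
  ref <- make_toy_ref(stats, rep(1, 100))
  expect_error(estimate_parameters(ref, c(S1 = 0, S2 = 0), 1,
                                   fraction = 0.01),
               "insufficient acceptance")
})

test_that("time recalibration is exact arithmetic on means and quantiles", {
  expect_equal(recalibrate_time(1.26e3),
               c(years = 10080, years_low = 7560, years_high = 12600))
  expect_equal(unname(recalibrate_time(0)), c(0, 0, 0))
  expect_error(recalibrate_time(-5), "non-negative")
  m <- recalibrate_time(c(100, 200))
  expect_equal(unname(m[, "years"]), c(800, 1600))
})

test_that("model checking locates the observed point and flags misfit", {
  set.seed(93)
  sc2 <- two_deme_scenario()
  gr <- group_config(c(A = 6, B = 6))
  pr <- prior_spec(n_bounds = c(50, 800), t_bounds = c(20, 400))
  ref <- build_reference_table(list(sc2), pr, gr, n_loci = 60,
                               n_per_scenario = 150, seed = 94,
                               trios = list())
  truth <- c(N1 = 200, N2 = 200, t1 = 100, "NA" = 400)
  g_obs <- simulate_dataset(sc2, truth, gr, 60)
  s_obs <- compute_sumstats(g_obs, trios = list())
  post <- estimate_parameters(ref, s_obs, 98, fraction = 0.4)
  chk <- model_check(ref, post, s_obs, n_posterior_sims = 60)
  expect_equal(sum(chk$var_prop), 1, tolerance = 1e-9)
  # observed well inside the posterior-predictive cloud on PC1/PC2
  expect_gte(chk$observed_score[1], min(chk$posterior_scores[, 1]))
  expect_lte(chk$observed_score[1], max(chk$posterior_scores[, 1]))
  expect_gt(min(chk$tail_probs), 0)
  # an observation from a wildly different history fails the check
  g_far <- simulate_dataset(sc2, c(N1 = 8, N2 = 8, t1 = 390, "NA" = 50),
                            gr, 60)
  s_far <- compute_sumstats(g_far, trios = list())
  chk2 <- model_check(ref, post, s_far, n_posterior_sims = 60)
  expect_lt(min(chk2$tail_probs), 0.01)
  # statistic subsetting restricts the check
  sub <- estimation_stats(colnames(ref$stats))
  chk3 <- model_check(ref, post, s_obs, n_posterior_sims = 20,
                      stat_subset = sub)
  expect_true(all(chk3$stats_used %in% sub))
  expect_error(model_check(ref, post, s_obs, stat_subset = "NOPE"),
               "empty statistic subset")
})

test_that("reference tables persist with metadata and combine cleanly", {
  sc2 <- two_deme_scenario()
  gr <- group_config(c(A = 3, B = 3))
  pr <- prior_spec(n_bounds = c(50, 500), t_bounds = c(20, 300))
  r1 <- build_reference_table(list(sc2), pr, gr, 20, 15, seed = 95,
                              trios = list())
  r2 <- build_reference_table(list(sc2), pr, gr, 20, 10, seed = 96,
                              trios = list())
  rc <- combine_reference_tables(r1, r2)
  expect_equal(nrow(rc$stats), 25)
  path <- tempfile(fileext = ".tsv")
  write_reference_table(rc, path)
  back <- read_reference_table(path)
  expect_equal(back$stats, rc$stats, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$scenario, rc$scenario)
  expect_equal(back$meta$priors$n_bounds, pr$n_bounds)
  expect_equal(as.integer(back$meta$groups), as.integer(gr))
  # a query runs identically against the restored table
  obs <- setNames(colMeans(rc$stats), colnames(rc$stats))
  expect_equal(direct_pp(back, obs, k = 5)$pp,
               direct_pp(rc, obs, k = 5)$pp)
  unlink(c(path, paste0(path, ".meta.json")))
  # same build seed gives a bit-identical table
  r1b <- build_reference_table(list(sc2), pr, gr, 20, 15, seed = 95,
                               trios = list())
  expect_identical(r1$stats, r1b$stats)
  expect_identical(r1$params, r1b$params)
})
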