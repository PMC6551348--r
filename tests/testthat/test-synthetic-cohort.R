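test_that("paper-scale demographics reproduce the study design and are deterministic", {
  cfg <- sim_config(n_vertices = 10, n_regions = 2, seed = 3)
  demo <- simulate_demographics(cfg)

  expect_equal(nrow(demo), 527)
  expect_equal(sum(demo$group == "TD"), 206)
  expect_equal(sum(demo$group == "ASD"), 321)
  expect_equal(sum(demo$group == "TD" & demo$sex == "male"), 127)
  expect_equal(sum(demo$group == "ASD" & demo$sex == "male"), 232)
  tab <- table(demo$group, demo$schedule)
  expect_equal(unname(tab["ASD", c("A", "B", "C", "D")]),
               c(125, 112, 64, 20))
  expect_equal(unname(tab["TD", c("A", "B", "C")]), c(84, 70, 52))
  expect_false("D" %in% demo$schedule[demo$group == "TD"])

  expect_false(anyDuplicated(demo$subject_id) > 0)
  # schedule D is exactly the IQ < 70 stratum
  expect_true(all(demo$iq[demo$schedule == "D"] < 70))
  expect_true(all(demo$iq[demo$schedule != "D"] >= 70, na.rm = TRUE))
  expect_equal(sum(is.na(demo$iq)), cfg$n_missing_iq)
  # ages inside each schedule window
  for (s in names(cfg$age_windows)) {
    a <- demo$age[demo$schedule == s]
    expect_true(all(a >= cfg$age_windows[[s]][1] &
                      a <= cfg$age_windows[[s]][2]))
  }
  # TD symptom columns stay missing
  expect_true(all(is.na(demo$ados_rrb[demo$group == "TD"])))

  demo2 <- simulate_demographics(sim_config(n_vertices = 10, n_regions = 2,
                                            seed = 3))
  expect_identical(demo, demo2)
  demo3 <- simulate_demographics(sim_config(n_vertices = 10, n_regions = 2,
                                            seed = 4))
  expect_false(identical(demo$age, demo3$age))
})

test_that("a TD-free cohort simulates but the normative fit refuses it", {
  cfg <- small_config(n_vertices = 5, n_regions = 1, n_td = 0, n_asd = 30,
                      deviation_extent = 1)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$cohort), 30)
  expect_true(all(sim$cohort$group == "ASD"))
  expect_error(normative_model(sim$cohort, sim$measures, folds = 2),
               "TD subjects")
})

test_that("the noise-free limit reproduces the trajectory polynomial exactly", {
  cfg <- small_config(n_vertices = 12, n_regions = 3, seed = 5,
                      n_td = 30, n_asd = 20,
                      noise_sd_range = c(1e-9, 1e-9),
                      deviation_prevalence = 0)
  sim <- simulate_cohort(cfg)
  tr <- cfg$trajectories
  male <- as.numeric(sim$cohort$sex == "male")
  expected <- cbind(1, sim$cohort$age, sim$cohort$age^2, male) %*%
    t(cbind(tr$intercept, tr$linear, tr$quadratic, tr$sex_offset))
  expect_lt(max(abs(sim$measures$values - expected)), 1e-6)
})

test_that("TD age slopes recover the configured linear coefficients", {
  cfg <- small_config(n_vertices = 30, n_regions = 6, seed = 11,
                      frac_inverted_u = 0)
  sim <- simulate_cohort(cfg)
  td <- sim$cohort$group == "TD"
  covered <- vapply(seq_len(30), function(v) {
    fit <- summary(stats::lm(sim$measures$values[td, v] ~
                               sim$cohort$age[td] +
                               I(sim$cohort$sex[td] == "male")))
    est <- fit$coefficients[2, 1]
    se <- fit$coefficients[2, 2]
    abs(est - cfg$trajectories$linear[v]) <= 2 * se
  }, logical(1))
  expect_gte(sum(covered), 26)   # ~95% nominal coverage over 30 vertices
})

test_that("inverted-U vertices peak between the age extremes", {
  cfg <- small_config(n_vertices = 50, n_regions = 10, seed = 2,
                      frac_inverted_u = 0.4)
  tr <- cfg$trajectories
  u <- which(tr$inverted_u)
  expect_gt(length(u), 0)
  traj <- function(v, a) tr$intercept[v] + tr$linear[v] * a +
    tr$quadratic[v] * a^2
  for (v in u) {
    mid <- -tr$linear[v] / (2 * tr$quadratic[v])
    expect_gt(mid, 6)
    expect_lt(mid, 31)
    expect_gt(traj(v, mid), traj(v, 6))
    expect_gt(traj(v, mid), traj(v, 31))
  }
})

test_that("deviations are planted as an exact carrier count with schedule-dependent signs", {
  cfg <- small_config(seed = 9)
  sim <- simulate_cohort(cfg)
  truth <- sim$truth
  expect_equal(sum(truth$subject$carrier), round(0.4 * 321))
  # no TD row carries a deviation
  td_rows <- which(sim$cohort$group == "TD")
  expect_true(all(truth$mask[td_rows, ] == 0))
  # sign law: children (C) negative, A/B/D positive under the default map
  sched <- sim$cohort$schedule[match(truth$planted$subject_id,
                                     sim$cohort$subject_id)]
  expect_true(all(truth$planted$sign[sched == "C"] == -1L))
  expect_true(all(truth$planted$sign[sched != "C"] == 1L))
  # deviations occupy whole parcels
  reg_sizes <- table(sim$parcellation$region)
  for (k in head(seq_len(nrow(truth$planted)), 10)) {
    i <- match(truth$planted$subject_id[k], sim$cohort$subject_id)
    vs <- sim$parcellation$vertex[sim$parcellation$region ==
                                    truth$planted$region[k]] + 1L
    expect_true(all(truth$mask[i, vs] == truth$planted$sign[k]))
  }
})

test_that("prevalence zero embeds a true null: ASD and TD share one generative law", {
  cfg <- small_config(n_vertices = 30, n_regions = 6, seed = 13,
                      deviation_prevalence = 0)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$mask == 0))
  # residuals around the trajectory have matching spread in both groups
  tr <- cfg$trajectories
  male <- as.numeric(sim$cohort$sex == "male")
  mu <- cbind(1, sim$cohort$age, sim$cohort$age^2, male) %*%
    t(cbind(tr$intercept, tr$linear, tr$quadratic, tr$sex_offset))
  res <- sim$measures$values - mu
  sd_td <- sd(res[sim$cohort$group == "TD", ])
  sd_asd <- sd(res[sim$cohort$group == "ASD", ])
  expect_lt(abs(sd_td - sd_asd) / sd_td, 0.1)
})

test_that("symptom links hit their configured rank correlations", {
  # null link: correlation near zero
  st0 <- default_symptom_targets()
  st0$link <- 0
  cfg0 <- small_config(n_vertices = 20, n_regions = 4, seed = 17,
                       symptom_targets = st0)
  sim0 <- simulate_cohort(cfg0)
  asd <- sim0$cohort$group == "ASD"
  mag <- sim0$truth$subject$magnitude[match(sim0$cohort$subject_id[asd],
                                            sim0$truth$subject$subject_id)]
  rho0 <- cor(mag, sim0$cohort$ados_rrb[asd], method = "spearman",
              use = "complete.obs")
  expect_lt(abs(rho0), 0.1)

  # strong link: mean recovered correlation within the tolerance band
  st5 <- default_symptom_targets()
  st5$link[st5$score == "ados_rrb"] <- -0.5
  rhos <- vapply(1:15, function(s) {
    cfg <- small_config(n_vertices = 20, n_regions = 4, seed = 100 + s,
                        symptom_targets = st5)
    sim <- simulate_cohort(cfg)
    asd <- sim$cohort$group == "ASD"
    mag <- sim$truth$subject$magnitude[match(sim$cohort$subject_id[asd],
                                             sim$truth$subject$subject_id)]
    cor(mag, sim$cohort$ados_rrb[asd], method = "spearman",
        use = "complete.obs")
  }, numeric(1))
  expect_gt(mean(rhos), -0.65)
  expect_lt(mean(rhos), -0.35)
})

test_that("symptom score moments and missingness match their targets", {
  cfg <- small_config(n_vertices = 10, n_regions = 2, seed = 23)
  sim <- simulate_cohort(cfg)
  asd <- sim$cohort$group == "ASD"
  x <- sim$cohort$adi_rrb[asd]
  expect_equal(sum(!is.na(x)), 321 - cfg$n_missing_adi)
  expect_lt(abs(mean(x, na.rm = TRUE) - 4.32) / 4.32, 0.1)
  expect_lt(abs(sd(x, na.rm = TRUE) - 2.69) / 2.69, 0.1)
  expect_equal(sum(!is.na(sim$cohort$ados_rrb[asd])),
               321 - cfg$n_missing_ados)
})

test_that("identical configurations yield bit-identical cohorts", {
  a <- simulate_cohort(small_config(seed = 31))
  b <- simulate_cohort(small_config(seed = 31))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$measures$values, b$measures$values)
  expect_identical(a$truth$mask, b$truth$mask)
})
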