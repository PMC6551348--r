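test_that("overlap counts equal brute-force tallies", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(10:40, 1)
      V <- sample(5:30, 1)
      mask <- matrix(sample(c(-1L, 0L, 1L), n * V, replace = TRUE,
                            prob = c(0.1, 0.8, 0.1)), n, V)
      group <- sample(c("TD", "ASD"), n, replace = TRUE)
      if (length(unique(group)) < 2) group[1:2] <- c("TD", "ASD")
      ov <- overlap_map(mask, group = group)
      for (g in unique(group)) {
        rows <- which(group == g)
        for (sgn in c(1L, -1L)) {
          want <- vapply(seq_len(V), function(v) {
            sum(mask[rows, v] == sgn)
          }, numeric(1))
          got <- ov$counts$count[ov$counts$group == g &
                                   ov$counts$sign ==
                                     ifelse(sgn == 1, "positive",
                                            "negative")]
          expect_equal(got, want)
        }
      }
    }
  })
})

test_that("overlap maps are empty for empty masks and invariant to subject order", {
  mask <- matrix(0L, 10, 6)
  group <- rep(c("TD", "ASD"), 5)
  ov <- overlap_map(mask, group = group)
  expect_true(all(ov$counts$count == 0))
  expect_true(all(ov$contributors$proportion == 0))

  withr::with_seed(5, {
    mask <- matrix(sample(c(-1L, 0L, 1L), 120, replace = TRUE), 20, 6)
    group <- rep(c("TD", "ASD"), 10)
    sched <- sample(c("A", "B"), 20, replace = TRUE)
    perm <- sample(20)
    a <- overlap_map(mask, group = group, schedule = sched)
    b <- overlap_map(mask[perm, ], group = group[perm],
                     schedule = sched[perm])
    key <- function(x) dplyr::arrange(x$counts, .data$group,
                                      .data$schedule, .data$sign,
                                      .data$vertex)
    expect_equal(key(a), key(b))
  })
  expect_error(overlap_map(mask, group = group[1:5]), "match")
})

test_that("the per-vertex OLS t statistic matches lm on a toy design", {
  cohort <- tibble::tibble(
    subject_id = paste0("s", 1:6),
    group = c("TD", "TD", "TD", "ASD", "ASD", "ASD"),
    sex = c("male", "female", "male", "female", "male", "female"),
    age = c(8, 12, 20, 9, 14, 22),
    schedule = "A")
  Y <- matrix(c(2.9, 2.7, 2.4, 3.0, 2.8, 2.5,
                2.5, 2.6, 2.2, 2.4, 2.3, 2.1), 6, 2)
  rownames(Y) <- cohort$subject_id
  res <- glm_case_control(Y, cohort, age_powers = 1, include_sex = FALSE)
  for (v in 1:2) {
    fit <- summary(stats::lm(Y[, v] ~ I(cohort$group != "TD") +
                               I(cohort$age - mean(cohort$age))))
    expect_equal(res$estimate[v], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(res$t[v], fit$coefficients[2, 3], tolerance = 1e-10)
    expect_equal(res$p[v], fit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("diagnosis coefficient equals the adjusted group-mean difference", {
  withr::with_seed(17, {
    n <- 60
    cohort <- tibble::tibble(
      subject_id = paste0("s", 1:n),
      group = rep(c("TD", "ASD"), each = n / 2),
      sex = rep(c("male", "female"), n / 2),
      age = rep(runif(n / 2, 6, 31), 2),  # identical age distribution
      schedule = "A")
    Y <- matrix(rnorm(n, 2.5, 0.2) + 0.3 * (cohort$group == "ASD"), n, 1)
    rownames(Y) <- cohort$subject_id
    res <- glm_case_control(Y, cohort, include_sex = FALSE)
    # balanced ages make the adjusted difference the raw difference
    raw <- mean(Y[cohort$group == "ASD", 1]) -
      mean(Y[cohort$group == "TD", 1])
    expect_equal(res$estimate[1], raw, tolerance = 1e-10)
  })
})

test_that("null group contrasts rarely survive FDR", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(600 + s, {
      n <- 200
      cohort <- tibble::tibble(
        subject_id = paste0("s", 1:n),
        group = sample(rep(c("TD", "ASD"), n / 2)),
        sex = sample(c("male", "female"), n, replace = TRUE),
        age = runif(n, 6, 31),
        schedule = "A")
      Y <- matrix(2.8 - 0.02 * cohort$age + rnorm(n * 100, 0, 0.2),
                  n, 100)
      rownames(Y) <- cohort$subject_id
      sum(glm_case_control(Y, cohort)$significant)
    })
  }, numeric(1))
  expect_gte(sum(hits == 0), 9)
})

test_that("a common planted shift is fully recovered with FDR-consistent false hits", {
  res <- vapply(1:5, function(s) {
    withr::with_seed(700 + s, {
      n <- 527
      cohort <- tibble::tibble(
        subject_id = paste0("s", 1:n),
        group = rep(c("TD", "ASD"), c(206, 321)),
        sex = sample(c("male", "female"), n, replace = TRUE),
        age = runif(n, 6, 31),
        schedule = "A")
      V <- 100
      Y <- matrix(2.8 - 0.02 * cohort$age + rnorm(n * V, 0, 0.2), n, V)
      Y[cohort$group == "ASD", 1:10] <- Y[cohort$group == "ASD", 1:10] + 0.3
      rownames(Y) <- cohort$subject_id
      res <- glm_case_control(Y, cohort)
      c(power = all(res$significant[1:10]),
        false = sum(res$significant[-(1:10)]))
    })
  }, numeric(2))
  # effect/SE ~ 17: every planted vertex recovered in every seed
  expect_true(all(res["power", ] == 1))
  # false vertices limited to what BH at q = .05 admits alongside 10 hits
  expect_lte(mean(res["false", ]), 1)
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  cohort <- tibble::tibble(
    subject_id = paste0("s", 1:20),
    group = rep(c("TD", "ASD"), 10),
    sex = rep(c("male", "female"), 10),
    age = 12,                          # constant: centered age term is zero
    schedule = "A")
  Y <- matrix(rnorm(20), 20, 1)
  rownames(Y) <- cohort$subject_id
  expect_error(glm_case_control(Y, cohort), "age1")
})

test_that("interaction and stratified variants run and label their output", {
  withr::with_seed(23, {
    n <- 80
    cohort <- tibble::tibble(
      subject_id = paste0("s", 1:n),
      group = rep(c("TD", "ASD"), n / 2),
      sex = sample(c("male", "female"), n, replace = TRUE),
      age = runif(n, 6, 31),
      schedule = "A")
    Y <- matrix(rnorm(n * 5, 2.5, 0.2), n, 5)
    rownames(Y) <- cohort$subject_id
    ri <- glm_case_control(Y, cohort, age_powers = c(1, 2),
                           interaction = TRUE)
    expect_equal(nrow(ri), 5)
    rs <- glm_case_control(Y, cohort, stratify_by_sex = TRUE)
    expect_setequal(unique(rs$stratum), c("male", "female"))
    expect_equal(nrow(rs), 10)
  })
})
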