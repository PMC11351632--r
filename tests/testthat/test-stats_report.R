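test_that("summarize pools agents and computes SEM across replicates", {
  r <- fake_result(reached_per_rep = c(91L))
  s <- summarize_runs(r)
  expect_equal(s$pct_reached, 91)
  expect_equal(s$n_agents, 100L)
  # identical replicates give SEM 0; all reached gives 100%
  s2 <- summarize_runs(fake_result(reached_per_rep = c(100L, 100L, 100L)))
  expect_equal(s2$pct_reached, 100)
  expect_equal(s2$sem, 0)
  # pooled percentage is the (weighted) mean of replicate percentages
  s3 <- summarize_runs(fake_result(reached_per_rep = c(80L, 60L)))
  expect_equal(s3$pct_reached, mean(c(80, 60)))
  expect_equal(sort(s3$replicate_pct), c(60, 80))
  expect_equal(s3$sem, stats::sd(c(80, 60)) / sqrt(2))
})

test_that("summarize is permutation-invariant and rejects mixed conditions", {
  r <- fake_result(reached_per_rep = c(70L, 90L))
  r_shuf <- r
  set.seed(42)
  r_shuf$agents <- r_shuf$agents[sample(nrow(r_shuf$agents)), ]
  expect_equal(summarize_runs(r_shuf)$pct_reached,
               summarize_runs(r)$pct_reached)
  expect_equal(summarize_runs(r_shuf)$sem, summarize_runs(r)$sem)
  r40 <- fake_result(age = "40s", reached_per_rep = 50L)
  expect_error(summarize_runs(list(r, r40)), "condition")
})

test_that("per-lesion stuck counts are collected and bounded", {
  r <- fake_result(reached_per_rep = 90L)
  idx <- which(r$agents$status == "stuck")
  r$agents$stuck_at[idx[1:6]] <- c("lesion_1", "lesion_2", "lesion_2",
                                   "lesion_3", "lesion_3", "lesion_3")
  s <- summarize_runs(r)
  expect_equal(unname(s$per_lesion_stuck),
               c(1L, 2L, 3L))
  expect_lte(sum(s$per_lesion_stuck), s$n_agents)
})

test_that("reduction rate follows (normal - endo) / normal x 100", {
  mk <- function(pct, endo) summarize_runs(
    fake_result(reached_per_rep = as.integer(pct), endo = endo))
  expect_equal(reduction_rate(mk(60, FALSE), mk(60, TRUE))$rate, 0)
  expect_equal(reduction_rate(mk(60, FALSE), mk(40, TRUE))$rate, 100 / 3,
               tolerance = 1e-9)
  expect_equal(reduction_rate(mk(75, FALSE), mk(0, TRUE))$rate, 100)
  # invariant to common scaling of both percentages
  r1 <- reduction_rate(mk(80, FALSE), mk(40, TRUE))$rate
  r2 <- reduction_rate(mk(40, FALSE), mk(20, TRUE))$rate
  expect_equal(r1, r2)
  expect_error(reduction_rate(mk(0, FALSE), mk(0, TRUE)), "undefined")
})

test_that("SEM shrinks like 1/sqrt(n_replicates) on resampled outcomes", {
  set.seed(7)
  reps_small <- as.integer(rbinom(8, 100, 0.9))
  reps_large <- as.integer(rbinom(128, 100, 0.9))
  sem_small <- summarize_runs(fake_result(reached_per_rep = reps_small))$sem
  sem_large <- summarize_runs(fake_result(reached_per_rep = reps_large))$sem
  expect_lt(sem_large, sem_small)
  expect_equal(sem_large / sem_small, sqrt(8 / 128), tolerance = 0.5)
})

test_that("report writes tables and figures for the full grid", {
  summ <- list()
  for (kd in c("sperm", "oocyte")) for (a in c("20s", "30s", "40s"))
    for (e in c(FALSE, TRUE)) {
      key <- paste(kd, a, if (e) "endo" else "normal", sep = "_")
      summ[[key]] <- summarize_runs(
        fake_result(kind = kd, age = a, endo = e,
                    reached_per_rep = c(85L, 80L)))
    }
  out <- tempfile("report")
  paths <- report(summ, out)
  files <- list.files(out)
  expect_length(grep("outcomes\\.csv$", files), 2L)
  expect_length(grep("reduction_rates\\.csv$", files), 2L)
  expect_length(grep("\\.png$", files), 4L)
  tab <- utils::read.csv(file.path(out, "oocyte_reduction_rates.csv"))
  expect_equal(nrow(tab), 3L)
  unlink(out, recursive = TRUE)
})

test_that("report on an incomplete grid writes partial output then errors", {
  summ <- list(sperm_20s_normal = summarize_runs(
    fake_result(kind = "sperm", reached_per_rep = 80L)))
  out <- tempfile("partial")
  expect_error(report(summ, out), "missing conditions")
  expect_true(file.exists(file.path(out, "sperm_outcomes.csv")))
  expect_error(report(list(), tempfile()), "missing conditions.*oocyte_40s_normal")
  unlink(out, recursive = TRUE)
})
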