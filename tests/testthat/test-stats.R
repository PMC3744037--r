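test_that("paired t on symmetric differences gives t = 0, p = 1", {
  x <- c(1, 2, 3, 4); y <- x - c(1, -1, 1, -1)
  r <- lymph_t_test(x, y, paired = TRUE, tails = 2)
  expect_equal(r$t_statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  expect_equal(r$degrees_of_freedom, 3)
})

test_that("degenerate zero-variance cases follow the conventions", {
  x <- c(5, 6, 7, 8)
  r <- lymph_t_test(x + 2, x, paired = TRUE, tails = 2)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  expect_error(lymph_t_test(x, x, paired = TRUE, tails = 2),
               "zero variance with zero effect")
  expect_error(lymph_t_test(rep(1, 4), rep(1, 4), paired = FALSE),
               "zero variance with zero effect")
})

test_that("paired t equals the one-sample t of the differences", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    r <- lymph_t_test(x, y, paired = TRUE, tails = 2)
    ref <- stats::t.test(x - y)
    expect_equal(r$t_statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("unpaired default is Welch; pooled variance on request", {
  set.seed(8)
  x <- rnorm(6); y <- rnorm(9, sd = 3)
  r <- lymph_t_test(x, y)
  ref <- stats::t.test(x, y)
  expect_equal(r$degrees_of_freedom, unname(ref$parameter),
               tolerance = 1e-9)
  r2 <- lymph_t_test(x, y, var_equal = TRUE)
  expect_equal(r2$degrees_of_freedom, 13)
})

test_that("one-tailed direction conventions are honoured", {
  x <- c(10, 11, 12, 13); y <- c(1, 2, 3, 4)
  up <- lymph_t_test(x, y, paired = TRUE, tails = 1, direction = "greater")
  down <- lymph_t_test(x, y, paired = TRUE, tails = 1, direction = "less")
  expect_lt(up$p_value, 0.001)
  expect_gt(down$p_value, 0.999)
})

test_that("missing pairs are dropped with a recorded count", {
  r <- lymph_t_test(c(1, 2, NA, 4, 5), c(0, 1, 2, NA, 3), paired = TRUE)
  expect_equal(r$n, 3)
  expect_equal(r$n_dropped, 2)
})

test_that("bonferroni adjusts, caps, and validates", {
  expect_equal(bonferroni(0.012, 3), 0.036)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(0.1, 0), "m must be")
  # monotone in both arguments
  p <- seq(0, 0.3, 0.05)
  expect_true(all(diff(bonferroni(p, 3)) >= 0))
  expect_true(all(bonferroni(p, 4) >= bonferroni(p, 2)))
})

make_vessel_table <- function(n = 4, effect = 1) {
  rows <- list()
  for (a in seq_len(n)) {
    for (role in c("dominant", "non_dominant")) {
      e <- if (role == "dominant") effect else 0
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = paste0("a", a), week = 0, group = "treatment",
        role = role,
        metric = rep(c("transport_time", "packet_frequency",
                       "packet_velocity"), each = 2),
        segment = rep(c("arrival", "steady_state"), 3),
        value = c(80 - 10 * e, 80 - 10 * e, 5 + e, 4 + e, 2 + e / 2,
                  1.5 + e / 2) + stats::rnorm(6, 0, 0.05))
    }
  }
  do.call(rbind, rows)
}

test_that("vessel_paired design runs one family of six comparisons", {
  set.seed(21)
  tab <- make_vessel_table()
  res <- compare_design(tab, "vessel_paired")
  expect_equal(nrow(res), 6)
  expect_true(all(res$m_comparisons == 6))
  expect_equal(res$p_adjusted, pmin(1, 6 * res$p_raw))
  expect_true(all(res$significant))
})

test_that("timecourse design tests decline one-tailed against week 0", {
  set.seed(22)
  base <- make_vessel_table(effect = 0)
  fup <- base; fup$week <- 1
  # decline: transport up, frequency and velocity down
  fup$value <- ifelse(fup$metric == "transport_time", fup$value + 30,
                      fup$value * 0.5)
  tab <- rbind(base, fup)
  tab$baseline <- NA_real_
  for (i in which(tab$week == 1)) {
    j <- tab$week == 0 & tab$animal_id == tab$animal_id[i] &
      tab$role == tab$role[i] & tab$metric == tab$metric[i] &
      tab$segment == tab$segment[i]
    tab$baseline[i] <- tab$value[j]
  }
  res <- compare_design(tab, "timecourse_one_tail")
  expect_equal(nrow(res), 12)   # 6 combos x 2 roles
  expect_true(all(res$m_comparisons == 1))
  expect_true(all(res$significant))
  # an improvement in function is not significant under the decline tails
  fup2 <- base; fup2$week <- 1
  fup2$value <- ifelse(fup2$metric == "transport_time", fup2$value - 30,
                       fup2$value * 2)
  tab2 <- rbind(base, fup2)
  tab2$baseline <- NA_real_
  for (i in which(tab2$week == 1)) {
    j <- tab2$week == 0 & tab2$animal_id == tab2$animal_id[i] &
      tab2$role == tab2$role[i] & tab2$metric == tab2$metric[i] &
      tab2$segment == tab2$segment[i]
    tab2$baseline[i] <- tab2$value[j]
  }
  res2 <- compare_design(tab2, "timecourse_one_tail")
  expect_false(any(res2$significant))
})

test_that("group_unpaired compares two groups per role and metric", {
  set.seed(23)
  g1 <- make_vessel_table(effect = 0); g1$group <- "healthy"
  g2 <- make_vessel_table(effect = 0); g2$group <- "gtno"
  g2$value <- g2$value + ifelse(g2$metric == "transport_time", 100, -1)
  res <- compare_design(rbind(g1, g2), "group_unpaired")
  expect_equal(nrow(res), 12)
  expect_true(all(res$significant))
  expect_error(compare_design(g1, "group_unpaired"), "two groups")
})

test_that("identical groups stay null under the family-wise control", {
  set.seed(24)
  rejections <- vapply(1:300, function(i) {
    tab <- make_vessel_table(effect = 0)
    tab$value <- tab$value + stats::rnorm(nrow(tab))
    any(compare_design(tab, "vessel_paired")$significant)
  }, logical(1))
  expect_lte(mean(rejections), 0.05 + 2.6 * sqrt(0.05 * 0.95 / 300))
})
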