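#' t-test with the package's missing-data and degeneracy conventions
#'
#' Classical t statistic with p from the t distribution, wrapping
#' [stats::t.test()]. Paired tests require equal-length samples and drop
#' incomplete pairs (with a recorded count); unpaired tests use Welch
#' degrees of freedom by default (`var_equal = TRUE` switches to the pooled
#' variance). Degenerate inputs follow fixed conventions: zero variance
#' with zero effect is an undefined test (error, never `p = 1`); zero
#' variance with a nonzero effect returns a `p = 0` sentinel flagged
#' `degenerate`.
#'
#' @param x,y Numeric samples (`y` of equal length for paired tests).
#' @param paired Paired test?
#' @param tails 1 or 2.
#' @param direction For one-tailed tests: `"greater"` or `"less"`, the
#'   alternative for `mean(x) - mean(y)` (or `mean(x)` of the differences).
#' @param var_equal Unpaired only: pooled-variance instead of Welch.
#' @return List of class `lymph_t_test`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `n`, `n_dropped`, `estimate`,
#'   `degenerate`.
#' @export
lymph_t_test <- function(x, y, paired = FALSE, tails = 2,
                         direction = c("greater", "less"),
                         var_equal = FALSE) {
  stopifnot(tails %in% c(1, 2))
  if (tails == 1) direction <- match.arg(direction)
  alternative <- if (tails == 2) "two.sided" else direction
  x <- as.numeric(x); y <- as.numeric(y)
  n_dropped <- 0L
  if (paired) {
    if (length(x) != length(y))
      stop("paired samples must have equal length", call. = FALSE)
    ok <- is.finite(x) & is.finite(y)
    n_dropped <- sum(!ok)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) stop("fewer than 2 usable pairs", call. = FALSE)
    d <- x - y
    if (stats::sd(d) == 0) {
      if (mean(d) == 0)
        stop("undefined test: zero variance with zero effect", call. = FALSE)
      res <- list(t_statistic = sign(mean(d)) * Inf,
                  degrees_of_freedom = length(d) - 1,
                  p_value = if (alternative == "two.sided" ||
                                (alternative == "greater" && mean(d) > 0) ||
                                (alternative == "less" && mean(d) < 0))
                    0 else 1,
                  n = length(d), n_dropped = n_dropped,
                  estimate = mean(d), degenerate = TRUE)
      class(res) <- "lymph_t_test"
      return(res)
    }
    tt <- stats::t.test(d, alternative = alternative)
    est <- mean(d)
    n <- length(d)
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2)
      stop("each sample needs >= 2 usable values", call. = FALSE)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y))
        stop("undefined test: zero variance with zero effect", call. = FALSE)
      res <- list(t_statistic = sign(mean(x) - mean(y)) * Inf,
                  degrees_of_freedom = length(x) + length(y) - 2,
                  p_value = if (alternative == "two.sided" ||
                                (alternative == "greater" &&
                                   mean(x) > mean(y)) ||
                                (alternative == "less" && mean(x) < mean(y)))
                    0 else 1,
                  n = min(length(x), length(y)), n_dropped = n_dropped,
                  estimate = mean(x) - mean(y), degenerate = TRUE)
      class(res) <- "lymph_t_test"
      return(res)
    }
    tt <- stats::t.test(x, y, alternative = alternative,
                        var.equal = var_equal)
    est <- mean(x) - mean(y)
    n <- min(length(x), length(y))
  }
  res <- list(t_statistic = unname(tt$statistic),
              degrees_of_freedom = unname(tt$parameter),
              p_value = tt$p.value, n = n, n_dropped = n_dropped,
              estimate = est, degenerate = FALSE)
  class(res) <- "lymph_t_test"
  res
}

#' @export
print.lymph_t_test <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.2f, p = %.4g (n = %d%s)%s\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$n,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, m * p_raw)` for a family of `m` comparisons.
#'
#' @param p_raw Raw p-value(s) in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Adjusted p-value(s), capped at 1.
#' @export
#' @examples
#' bonferroni(0.012, 3)  # 0.036
bonferroni <- function(p_raw, m) {
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("p_raw must be in [0, 1]", call. = FALSE)
  pmin(1, m * p_raw)
}

#' Run a standard family of comparisons on a time-course table
#'
#' The three analysis designs applied to a [compile_timecourse()] table:
#'
#' * `vessel_paired` — within-session dominant vs. non-dominant, paired
#'   two-tail per metric-segment family (Bonferroni across the family).
#' * `group_unpaired` — two groups compared per vessel role and
#'   metric-segment, unpaired two-tail (Welch), Bonferroni across the
#'   family.
#' * `timecourse_one_tail` — each follow-up week vs. week 0 per vessel
#'   role and metric-segment, paired one-tail in the direction of
#'   functional decline (transport time increases; packet frequency and
#'   velocity decrease); uncorrected by default (`m = 1`), matching the
#'   standard protocol, but `m` is configurable.
#'
#' Node-area rows (`metric == "node_area"`) are only used by
#' `group_unpaired`. Missing values are dropped pairwise with counts in
#' the result. Both raw and adjusted p-values are reported since family
#' sizes are a convention.
#'
#' @param table A [compile_timecourse()]-style data frame.
#' @param design One of `"vessel_paired"`, `"group_unpaired"`,
#'   `"timecourse_one_tail"`.
#' @param m Bonferroni family size; default: the number of comparisons in
#'   the family for the two-tail designs, 1 for the one-tail time course.
#' @param alpha Significance level (default 0.05).
#' @param groups For `group_unpaired`: the two group labels to compare
#'   (default: the two groups present, first vs. second).
#' @return Data frame of class `test_table`: one row per comparison with
#'   `comparison`, `n`, `t_statistic`, `degrees_of_freedom`, `p_raw`,
#'   `m_comparisons`, `p_adjusted`, `alpha`, `significant`, `degenerate`.
#' @export
compare_design <- function(table,
                           design = c("vessel_paired", "group_unpaired",
                                      "timecourse_one_tail"),
                           m = NULL, alpha = 0.05, groups = NULL) {
  design <- match.arg(design)
  req <- c("animal_id", "week", "group", "role", "metric", "segment",
           "value")
  if (!all(req %in% names(table)))
    stop("table is missing columns: ",
         paste(setdiff(req, names(table)), collapse = ", "), call. = FALSE)
  tab <- as.data.frame(table)

  run_one <- function(label, f) {
    r <- tryCatch(f(), error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(comparison = label, n = r$n, t_statistic = r$t_statistic,
               degrees_of_freedom = r$degrees_of_freedom,
               p_raw = r$p_value, degenerate = r$degenerate,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  if (design == "vessel_paired") {
    sub <- tab[tab$metric != "node_area", ]
    combos <- unique(sub[, c("metric", "segment", "week")])
    for (i in seq_len(nrow(combos))) {
      cm <- combos[i, ]
      s <- sub[sub$metric == cm$metric & sub$segment == cm$segment &
                 sub$week == cm$week, ]
      wd <- stats::reshape(s[, c("animal_id", "role", "value")],
                           direction = "wide", idvar = "animal_id",
                           timevar = "role")
      if (!all(c("value.dominant", "value.non_dominant") %in% names(wd)))
        next
      rows[[length(rows) + 1]] <- run_one(
        sprintf("%s/%s wk%s: dominant vs non-dominant",
                cm$metric, cm$segment, cm$week),
        function() lymph_t_test(wd$value.dominant, wd$value.non_dominant,
                                paired = TRUE, tails = 2))
    }
  } else if (design == "group_unpaired") {
    if (is.null(groups)) {
      groups <- unique(tab$group)
      if (length(groups) != 2)
        stop("group_unpaired needs exactly two groups", call. = FALSE)
    }
    combos <- unique(tab[, c("metric", "segment", "role", "week")])
    for (i in seq_len(nrow(combos))) {
      cm <- combos[i, ]
      s <- tab[tab$metric == cm$metric & tab$segment == cm$segment &
                 tab$role == cm$role & tab$week == cm$week, ]
      g1 <- s$value[s$group == groups[1]]
      g2 <- s$value[s$group == groups[2]]
      rows[[length(rows) + 1]] <- run_one(
        sprintf("%s/%s/%s wk%s: %s vs %s", cm$metric, cm$segment, cm$role,
                cm$week, groups[1], groups[2]),
        function() lymph_t_test(g1, g2, paired = FALSE, tails = 2))
    }
  } else {                                   # timecourse_one_tail
    sub <- tab[tab$metric != "node_area" & tab$week > 0 &
                 !is.na(tab$baseline), ]
    combos <- unique(sub[, c("metric", "segment", "role", "week")])
    for (i in seq_len(nrow(combos))) {
      cm <- combos[i, ]
      s <- sub[sub$metric == cm$metric & sub$segment == cm$segment &
                 sub$role == cm$role & sub$week == cm$week, ]
      # decline in function: transport time rises, frequency/velocity fall
      dir <- if (cm$metric == "transport_time") "greater" else "less"
      rows[[length(rows) + 1]] <- run_one(
        sprintf("%s/%s/%s: wk%s vs wk0", cm$metric, cm$segment, cm$role,
                cm$week),
        function() lymph_t_test(s$value, s$baseline, paired = TRUE,
                                tails = 1, direction = dir))
    }
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    stop("no testable comparisons in the table", call. = FALSE)
  out <- do.call(rbind, rows)
  m_eff <- if (is.null(m)) {
    if (design == "timecourse_one_tail") 1L else nrow(out)
  } else m
  out$m_comparisons <- m_eff
  out$p_adjusted <- bonferroni(out$p_raw, m_eff)
  out$alpha <- alpha
  out$significant <- out$p_adjusted < alpha
  class(out) <- c("test_table", "data.frame")
  out
}
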