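# Group summaries, Student's t, ANOVA + Bonferroni post-hoc, table rendering.

test_that("summaries report mean, SEM and n over usable cells", {
  res <- data.frame(
    construct = "a", cell_id = paste0("c", 1:3),
    qc_included = TRUE, qc_reason = "ok", converged = TRUE,
    v_half_act = c(1, 2, 3), slope_act = 8, v_rev = 65,
    v_half_inact = NA_real_, slope_inact = NA_real_,
    plateau_pct = NA_real_, ssi_converged = NA,
    stringsAsFactors = FALSE)
  s <- summarize_groups(res, params = "v_half_act")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(s$n, 3)

  res$v_half_act <- 5  # identical values: SEM 0
  s2 <- summarize_groups(res, params = "v_half_act")
  expect_equal(s2$mean, 5)
  expect_equal(s2$sem, 0)
})

test_that("summaries drop QC-excluded and non-converged cells", {
  res <- data.frame(
    construct = "a", cell_id = paste0("c", 1:4),
    qc_included = c(TRUE, TRUE, FALSE, TRUE),
    qc_reason = c("ok", "ok", "too small", "ok"),
    converged = c(TRUE, TRUE, TRUE, FALSE),
    v_half_act = c(-10, -12, -99, -99),
    stringsAsFactors = FALSE)
  s <- summarize_groups(res, params = "v_half_act")
  expect_equal(s$n, 2)
  expect_equal(s$mean, -11)
  expect_error(summarize_groups(res[res$qc_included & res$converged, ][1, ],
                                params = "v_half_act"),
               "fewer than 2")
})

test_that("the two-group comparison is an equal-variance Student's t", {
  # closed form: pooled SD = 1, t = -3/sqrt(2/3), df = 4
  r <- compare_two(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(r$p, 0.0213, tolerance = 1e-2)

  same <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(compare_two(c(1, 1, 1), c(1, 1, 1)), "zero pooled variance")

  # separation limit: tiny variance, large mean gap
  sep <- compare_two(c(0, 1e-8, -1e-8, 0), c(1, 1 + 1e-8, 1 - 1e-8, 1))
  expect_lt(sep$p, 1e-10)
})

test_that("with two groups the ANOVA F equals t squared", {
  set.seed(31)
  a <- rnorm(8)
  b <- rnorm(9, 1)
  t_res <- compare_two(a, b)
  an <- stats::anova(stats::aov(c(a, b) ~ factor(rep(1:2, c(8, 9)))))
  expect_equal(an[["F value"]][1], t_res$t^2, tolerance = 1e-10)
  expect_equal(an[["Pr(>F)"]][1], t_res$p, tolerance = 1e-10)
})

test_that("compare_many needs three groups and adjusts vs reference", {
  vals <- c(1, 2, 3, 4)
  expect_error(compare_many(vals, rep(c("a", "b"), 2)), ">= 3 groups")

  set.seed(5)
  d <- data.frame(
    v = c(rnorm(8, 0), rnorm(8, 0), rnorm(8, 2)),
    g = rep(c("ref", "g1", "g2"), each = 8))
  r <- compare_many(d$v, d$g, reference = "ref")
  expect_equal(nrow(r$pairwise), 2)
  expect_true(all(r$pairwise$reference == "ref"))
  # Bonferroni: adjusted = raw * 2 here, clipped at 1
  expect_equal(r$pairwise$p_adj,
               pmin(1, r$pairwise$p_raw * 2), tolerance = 1e-12)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
  expect_true(all(r$pairwise$p_adj <= 1))
  # all-pairs multiplicity is 3
  r2 <- compare_many(d$v, d$g, reference = "ref", comparisons = "allpairs")
  expect_equal(nrow(r2$pairwise), 3)
  expect_equal(r2$pairwise$p_adj,
               pmin(1, r2$pairwise$p_raw * 3), tolerance = 1e-12)
})

test_that("Bonferroni arithmetic: 3 comparisons at raw p 0.02 give 0.06", {
  expect_equal(min(1, 0.02 * 3), 0.06)
  # and the implementation reproduces it through compare_many on data
  # engineered to have a known raw p is covered above; here the clip:
  expect_equal(min(1, 0.6 * 3), 1)
})

test_that("ANOVA p agrees with a permutation null on small groups", {
  set.seed(77)
  g <- rep(c("a", "b", "c"), each = 5)
  vals <- c(rnorm(5, 0), rnorm(5, 0.8), rnorm(5, 1.6))
  r <- compare_many(vals, g)
  f_obs <- r$f
  n_perm <- 10000
  f_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    vp <- sample(vals)
    m <- tapply(vp, g, mean)
    ssb <- 5 * sum((m - mean(vp))^2)
    ssw <- sum((vp - m[g])^2)
    f_perm[i] <- (ssb / 2) / (ssw / 12)
  }
  p_perm <- mean(f_perm >= f_obs)
  expect_lt(abs(p_perm - r$p), 0.01)
})

test_that("the vs-reference family rejects at ~5% under the null", {
  set.seed(123)
  n_rep <- 1000
  rejected <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    vals <- rnorm(24)
    g <- rep(c("ref", "g1", "g2"), each = 8)
    r <- compare_many(vals, g, reference = "ref")
    rejected[i] <- any(r$pairwise$p_adj < 0.05)
  }
  expect_gt(mean(rejected), 0.035)
  expect_lt(mean(rejected), 0.065)
})

test_that("star thresholds follow the 0.05/0.01/0.001 convention", {
  expect_equal(p_stars(c(0.0005, 0.005, 0.04, 0.2, NA)),
               c("***", "**", "*", "", ""))
})

test_that("rendered tables carry stars and round-trip numerically", {
  res <- data.frame(
    construct = rep(c("wt", "mut"), each = 4),
    cell_id = paste0("c", 1:8),
    qc_included = TRUE, qc_reason = "ok", converged = TRUE,
    v_half_act = c(-10.2, -10.4, -9.9, -10.1, -25.3, -25.6, -25.2, -25.8),
    slope_act = rep(c(8.5, 7.6), each = 4) + rep(c(0, .1, -.1, .05), 2),
    v_rev = rep(c(65.7, 58.3), each = 4) + rep(c(0, .2, -.2, .1), 2),
    stringsAsFactors = FALSE)
  s <- summarize_groups(res)
  cmp <- compare_constructs(res, "v_half_act", reference = "wt")
  expect_equal(cmp$stars, "***")
  tab <- render_group_table(s, cmp, layout = "gating")
  expect_equal(tab$construct, c("wt", "mut"))
  expect_match(tab$v_half_act[tab$construct == "mut"], "\\*\\*\\*$")
  # empty comparison set: no stars anywhere
  tab0 <- render_group_table(s, NULL, layout = "gating")
  expect_false(any(grepl("\\*", unlist(tab0))))
  # round-trip at printed precision
  parsed <- parse_mean_sem(tab$v_half_act)
  expect_equal(parsed$mean,
               round(s$mean[s$parameter == "v_half_act"], 2))
  expect_equal(parsed$sem,
               round(s$sem[s$parameter == "v_half_act"], 2))
})
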