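# Cohort aggregation and hypothesis testing: mean +/- SEM summaries,
# unpaired Student's t-tests, one-way ANOVA with Bonferroni-adjusted
# vs-reference (or all-pairs) post-hoc comparisons, and formatted tables.

.gating_params <- c("v_half_act", "slope_act", "v_rev",
                    "v_half_inact", "slope_inact", "plateau_pct")
.kinetic_params <- paste0("r", c(50, 100, 250, 500, 1000, 5000))

# drop QC-excluded and non-converged cells before any statistics;
# parameter-specific convergence (IV/GV vs SSI) is respected
included_values <- function(results, param) {
  keep <- !is.na(results[[param]])
  if (param %in% c("v_half_act", "slope_act", "v_rev", "g_max",
                   "peak_pa", "norm_pa_pf")) {
    keep <- keep & results$qc_included %in% TRUE & results$converged %in% TRUE
  } else if (param %in% c("v_half_inact", "slope_inact", "plateau_pct")) {
    keep <- keep & results$ssi_converged %in% TRUE
    if (!all(is.na(results$qc_included))) {
      keep <- keep & !(results$qc_included %in% FALSE)
    }
  } else if (param %in% .kinetic_params) {
    if (!all(is.na(results$qc_included))) {
      keep <- keep & !(results$qc_included %in% FALSE)
    }
  }
  keep
}

#' Group mean / SEM / n summary
#'
#' Summarizes a per-cell results table (from [analyze_cohort()]) per
#' construct and parameter, excluding QC-failed and non-converged cells.
#' All values are reported as mean and SEM (`SD/sqrt(n)`).
#'
#' @param results Per-cell results data.frame.
#' @param params Parameter columns to summarize; defaults to all gating and
#'   kinetic parameters present.
#' @param group_key Grouping column, normally `"construct"`.
#' @return A `group_summary` data.frame with columns `group`, `parameter`,
#'   `mean`, `sem`, `n`.
#' @export
summarize_groups <- function(results, params = NULL,
                             group_key = "construct") {
  stopifnot(group_key %in% names(results))
  if (is.null(params)) {
    params <- intersect(c(.gating_params, .kinetic_params), names(results))
    params <- params[vapply(params,
                            function(p) any(!is.na(results[[p]])),
                            logical(1))]
  }
  groups <- unique(results[[group_key]])
  rows <- list()
  for (g in groups) {
    sub <- results[results[[group_key]] == g, , drop = FALSE]
    for (p in params) {
      x <- sub[[p]][included_values(sub, p)]
      if (length(x) < 2L) {
        stop("group '", g, "' has fewer than 2 usable cells for ", p)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, parameter = p, mean = mean(x),
        sem = stats::sd(x) / sqrt(length(x)), n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Unpaired Student's t-test between two groups
#'
#' Two-sided, equal-variance t-test with `df = nA + nB - 2`.
#'
#' @param a,b Numeric vectors of per-cell values (each length >= 2).
#' @return List with `t`, `df`, `p`.
#' @export
compare_two <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) + stats::var(b) == 0 && mean(a) == mean(b)) {
    stop("zero pooled variance: groups are constant and identical")
  }
  tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                 error = function(e) stop("t-test failed: ",
                                          conditionMessage(e)))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Significance stars
#'
#' @param p (Adjusted) p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `""`.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' One-way ANOVA with Bonferroni post-hoc comparisons
#'
#' For three or more groups: a one-way ANOVA followed by pairwise
#' pooled-variance t-tests (pooled SD across all groups, ANOVA residual
#' degrees of freedom) whose raw p-values are Bonferroni-multiplied by the
#' number of comparisons performed and clipped at 1. By default each
#' non-reference group is compared against the reference construct only;
#' `comparisons = "allpairs"` tests every pair.
#'
#' @param values Numeric vector of per-cell values.
#' @param groups Factor/character vector of group labels, same length.
#' @param reference Reference group label (default: first level).
#' @param comparisons `"reference"` or `"allpairs"`.
#' @return List with `f`, `df` (length 2), `p` (ANOVA) and `pairwise`, a
#'   data.frame `reference`/`test`/`p_raw`/`p_adj`/`stars`.
#' @export
compare_many <- function(values, groups, reference = NULL,
                         comparisons = c("reference", "allpairs")) {
  comparisons <- match.arg(comparisons)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  lv <- unique(groups)
  if (length(lv) < 3L) {
    stop("compare_many() needs >= 3 groups; use compare_two() for two")
  }
  if (is.null(reference)) reference <- lv[1]
  stopifnot(reference %in% lv)

  fg <- factor(groups, levels = lv)
  fit <- stats::aov(values ~ fg)
  an <- stats::anova(fit)
  f <- an[["F value"]][1]
  df <- c(an[["Df"]][1], an[["Df"]][2])
  p_anova <- an[["Pr(>F)"]][1]

  pw <- stats::pairwise.t.test(values, fg, pool.sd = TRUE,
                               p.adjust.method = "none")$p.value
  get_p <- function(a, b) {
    if (a %in% rownames(pw) && b %in% colnames(pw) && !is.na(pw[a, b])) {
      return(pw[a, b])
    }
    if (b %in% rownames(pw) && a %in% colnames(pw) && !is.na(pw[b, a])) {
      return(pw[b, a])
    }
    stop("no pairwise p-value for ", a, " vs ", b)
  }
  pairs <- if (comparisons == "reference") {
    lapply(setdiff(lv, reference), function(g) c(reference, g))
  } else {
    utils::combn(lv, 2, simplify = FALSE)
  }
  m <- length(pairs)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    p_raw <- get_p(pr[1], pr[2])
    data.frame(reference = pr[1], test = pr[2], p_raw = p_raw,
               p_adj = min(1, p_raw * m), stringsAsFactors = FALSE)
  }))
  pairwise$stars <- p_stars(pairwise$p_adj)
  list(f = f, df = df, p = p_anova, pairwise = pairwise)
}

#' Compare a parameter across constructs of a results table
#'
#' Convenience wrapper that extracts usable per-cell values of `param` for
#' each construct and runs [compare_two()] (two groups) or [compare_many()]
#' (three or more).
#'
#' @param results Per-cell results table ([analyze_cohort()]).
#' @param param Parameter column name.
#' @param reference Reference construct.
#' @param comparisons See [compare_many()].
#' @return A data.frame, one row per comparison: `parameter`, `reference`,
#'   `test`, `p_raw`, `p_adj`, `stars`.
#' @export
compare_constructs <- function(results, param, reference = NULL,
                               comparisons = c("reference", "allpairs")) {
  comparisons <- match.arg(comparisons)
  keep <- included_values(results, param)
  vals <- results[[param]][keep]
  grp <- results$construct[keep]
  lv <- unique(grp)
  if (is.null(reference)) reference <- lv[1]
  if (length(lv) == 2L) {
    other <- setdiff(lv, reference)
    res <- compare_two(vals[grp == reference], vals[grp == other])
    data.frame(parameter = param, reference = reference, test = other,
               p_raw = res$p, p_adj = res$p, stars = p_stars(res$p),
               stringsAsFactors = FALSE)
  } else {
    res <- compare_many(vals, grp, reference = reference,
                        comparisons = comparisons)
    cbind(parameter = param, res$pairwise)
  }
}

#' Render a publication-style gating or kinetics table
#'
#' Formats a [summarize_groups()] summary as one row per construct with
#' "mean +/- SEM" entries, star annotations from `comparisons`, and the
#' per-block n.
#'
#' @param summary A `group_summary`.
#' @param comparisons Optional data.frame from [compare_constructs()]
#'   (stacked over parameters) used for star annotations on the test
#'   groups.
#' @param layout `"gating"` (activation + inactivation columns) or
#'   `"kinetics"` (r-value columns).
#' @param digits Decimal places.
#' @return A character data.frame, one row per construct.
#' @export
render_group_table <- function(summary, comparisons = NULL,
                               layout = c("gating", "kinetics"),
                               digits = 2) {
  layout <- match.arg(layout)
  params <- if (layout == "gating") .gating_params else .kinetic_params
  params <- intersect(params, unique(summary$parameter))
  groups <- unique(summary$group)
  star_for <- function(g, p) {
    if (is.null(comparisons)) return("")
    hit <- comparisons$test == g & comparisons$parameter == p
    if (any(hit)) comparisons$stars[hit][1] else ""
  }
  fmt <- paste0("%.", digits, "f ± %.", digits, "f%s")
  rows <- lapply(groups, function(g) {
    row <- list(construct = g)
    for (p in params) {
      s <- summary[summary$group == g & summary$parameter == p, ]
      row[[p]] <- if (nrow(s) == 1L) {
        sprintf(fmt, s$mean, s$sem, star_for(g, p))
      } else {
        ""
      }
      row[[paste0("n_", p)]] <- if (nrow(s) == 1L) s$n else NA_integer_
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # keep one n column per block rather than per parameter
  if (layout == "gating") {
    act_n <- out$n_v_half_act
    inact_n <- out$n_v_half_inact
    out <- out[, !grepl("^n_", names(out)), drop = FALSE]
    out$n_act <- act_n
    out$n_inact <- inact_n
  } else {
    n <- out$n_r50
    out <- out[, !grepl("^n_", names(out)), drop = FALSE]
    out$n <- n
  }
  out
}

#' Parse a rendered "mean +/- SEM" entry back to numbers
#'
#' Inverse of the formatting used by [render_group_table()] (stars are
#' ignored); round-trips at the table's printed precision.
#'
#' @param x Character vector like `"-10.21 ± 0.62**"`.
#' @return data.frame with `mean` and `sem`.
#' @export
parse_mean_sem <- function(x) {
  m <- regmatches(x, regexec("^(-?[0-9.]+) ± ([0-9.]+)", x))
  data.frame(mean = vapply(m, function(g) as.numeric(g[2]), numeric(1)),
             sem = vapply(m, function(g) as.numeric(g[3]), numeric(1)))
}
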