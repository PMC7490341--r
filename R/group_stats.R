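#' Pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance, `df = n_a + n_b - 2`. The cage is
#' the statistical unit for activity/RDI comparisons, so inputs are
#' per-cage weekly values.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  ht <- t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Mean pairwise correlation among repeated weekly outcomes
#'
#' Estimates the mean correlation r-bar used by the D/AP correction: the
#' average of all upper-triangle pairwise Pearson correlations between
#' week columns, computed across cages of both groups pooled (rows with
#' missing weeks dropped), clipped to \[0, 1\].
#'
#' @param weekly_matrix Numeric matrix, cages x weeks.
#' @return Scalar r-bar in \[0, 1\].
#' @export
estimate_rbar <- function(weekly_matrix) {
  m <- weekly_matrix[stats::complete.cases(weekly_matrix), , drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 week columns")
  if (nrow(m) < 3) stop("need at least 3 cages with complete rows")
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("zero-variance week column(s) skipped in r-bar estimation")
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2) return(0)
  }
  cm <- cor(m)
  rb <- mean(cm[upper.tri(cm)])
  min(max(rb, 0), 1)
}

#' D/AP-adjusted significance level
#'
#' The D/AP multiplicity correction shrinks the effective number of tests
#' according to the mean correlation among the `k` repeated outcomes:
#' `k_eff = k^(1 - r_bar)` and `alpha_adj = 1 - (1 - alpha)^(1 / k_eff)`.
#' With perfectly correlated outcomes (`r_bar = 1`) this is no correction;
#' with independent outcomes (`r_bar = 0`) it reduces to the Sidak form
#' `1 - (1 - alpha)^(1/k)` (approximately Bonferroni's `alpha / k`).
#'
#' @param alpha Family significance level.
#' @param k Number of correlated tests.
#' @param r_bar Mean pairwise correlation among the outcomes, in \[0, 1\].
#' @return Adjusted per-test level.
#' @export
dap_adjust <- function(alpha = 0.05, k, r_bar) {
  stopifnot(alpha > 0, alpha < 1, k >= 1, r_bar >= 0, r_bar <= 1)
  k_eff <- k^(1 - r_bar)
  1 - (1 - alpha)^(1 / k_eff)
}

#' Per-week group comparisons with three correction schemes
#'
#' Runs a pooled two-sample t-test per week between the two groups and
#' flags significance with no correction, classical Bonferroni
#' (`alpha / k`) and the D/AP correction. Testing is restricted to weeks at
#' or below `max_week` (after which cages may be missing) and to weeks at
#' which every cage has a value; other weeks are dropped with a reason.
#'
#' @param weekly Weekly values of one metric (as from [weekly_aggregate()]
#'   or [weekly_rdi()], single metric).
#' @param meta `cage_metadata` (provides the genotype of each cage).
#' @param group_col Metadata column holding the two group labels.
#' @param max_week Last week of age tested.
#' @param alpha Family significance level.
#' @param r_bar Mean outcome correlation; `NULL` estimates it from the
#'   pooled cage x week matrix via [estimate_rbar()].
#' @return `data.frame` of class `posthoc_table`: `week`, `t`, `df`,
#'   `p_raw`, `sig_none`, `sig_bonferroni`, `sig_dap`; attributes `alpha`,
#'   `alpha_adj`, `r_bar`, `k`, `groups`, `dropped_weeks`.
#' @export
posthoc_weeks <- function(weekly, meta, group_col = "genotype",
                          max_week = 20L, alpha = 0.05, r_bar = NULL) {
  if (length(unique(weekly$metric)) > 1)
    stop("posthoc_weeks expects a single metric")
  grp <- meta[[group_col]][match(weekly$cage_id, meta$cage_id)]
  levs <- sort(unique(grp))
  if (length(levs) != 2) stop("need exactly 2 groups")
  w <- weekly[weekly$week <= max_week & !is.na(weekly$value), ]
  grp <- grp[weekly$week <= max_week & !is.na(weekly$value)]
  cages <- sort(unique(weekly$cage_id))
  weeks_all <- sort(unique(w$week))
  mat <- matrix(NA_real_, length(cages), length(weeks_all),
                dimnames = list(cages, weeks_all))
  mat[cbind(match(w$cage_id, cages), match(w$week, weeks_all))] <- w$value
  complete_wk <- colSums(!is.na(mat)) == length(cages)
  dropped <- weeks_all[!complete_wk]
  weeks <- weeks_all[complete_wk]
  k <- length(weeks)
  if (k == 0) stop("no week has values for every cage")
  if (is.null(r_bar))
    r_bar <- if (k >= 2) estimate_rbar(mat[, complete_wk, drop = FALSE]) else 1
  a_dap <- dap_adjust(alpha, k, r_bar)
  cage_grp <- meta[[group_col]][match(cages, meta$cage_id)]
  rows <- lapply(weeks, function(wk) {
    v <- mat[, as.character(wk)]
    tt <- pooled_t_test(v[cage_grp == levs[1]], v[cage_grp == levs[2]])
    data.frame(week = wk, t = tt$t, df = tt$df, p_raw = tt$p,
               sig_none = tt$p < alpha,
               sig_bonferroni = tt$p < alpha / k,
               sig_dap = tt$p < a_dap)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("posthoc_table", "data.frame"),
            alpha = alpha, alpha_adj = a_dap, r_bar = r_bar, k = k,
            groups = levs, dropped_weeks = dropped)
}

#' Onset week of a group difference
#'
#' The onset of an RDI (or activity) difference is the earliest tested
#' week at which the groups differ significantly under the D/AP-corrected
#' post-hoc test.
#'
#' @param posthoc A `posthoc_table` from [posthoc_weeks()].
#' @return Integer week, or `NA` if no week is significant.
#' @export
detect_onset <- function(posthoc) {
  hit <- posthoc$week[posthoc$sig_dap]
  if (length(hit)) as.integer(min(hit)) else NA_integer_
}
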