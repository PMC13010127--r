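# Cohort statistics layer: normality-gated two-group comparisons, one-way
# ANOVA, Spearman correlation matrix, stratified summaries.

#' Summary of one sample: n, mean, standard error of the mean
#'
#' Non-finite values are dropped; SEM is `sd(x)/sqrt(n)`.
#'
#' @param x numeric vector.
#' @return list with `n`, `mean`, `sem`.
#' @export
group_summary <- function(x) {
  n <- sum(is.finite(x))
  x <- x[is.finite(x)]
  list(n = n, mean = if (n > 0) mean(x) else NA_real_,
       sem = if (n > 1) sd(x) / sqrt(n) else NA_real_)
}

#' Two-group comparison with a normality gate
#'
#' Both samples are tested with Shapiro-Wilk at `alpha_normality`; if both
#' pass, an unpaired two-sample t test is used (pooled variance by default,
#' Welch by flag), otherwise a two-sided Mann-Whitney U test (exact for
#' small samples without ties, normal approximation otherwise). A
#' zero-variance sample bypasses the gate directly to the nonparametric
#' branch with a warning. Group summaries are mean, SEM and n.
#'
#' @param x,y numeric samples (n >= 3 each for the gate).
#' @param alpha_normality normality test level (default 0.05).
#' @param metric label carried into the result.
#' @param welch use Welch's t test instead of pooled variance.
#' @param force_test `"auto"` (gated), `"t"` or `"mann_whitney"`.
#' @return object of class `group_comparison`: `metric`, `test`
#'   (`"t_unpaired"` or `"mann_whitney_u"`), `statistic`, `p_value`,
#'   `normality_p`, `alpha_normality`, `summaries`.
#' @export
compare_two_groups <- function(x, y, alpha_normality = 0.05,
                               metric = "metric", welch = FALSE,
                               force_test = c("auto", "t", "mann_whitney")) {
  force_test <- match.arg(force_test)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop2("each sample needs n >= 3 for the normality gate")
  zero_var <- sd(x) == 0 || sd(y) == 0
  norm_p <- c(NA_real_, NA_real_)
  if (force_test == "auto") {
    if (zero_var) {
      warning("zero-variance sample: normality gate bypassed to the nonparametric branch")
      use_t <- FALSE
    } else {
      norm_p <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
      use_t <- all(norm_p > alpha_normality)
    }
  } else use_t <- force_test == "t"
  if (use_t) {
    ht <- t.test(x, y, var.equal = !welch)
    test <- "t_unpaired"; stat <- unname(ht$statistic)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, exact = NULL,
                                       correct = TRUE))
    test <- "mann_whitney_u"; stat <- unname(ht$statistic)
  }
  structure(list(metric = metric, test = test, statistic = stat,
                 p_value = ht$p.value, normality_p = norm_p,
                 alpha_normality = alpha_normality,
                 variance_assumption = if (use_t && !welch) "pooled"
                 else if (use_t) "welch" else NA_character_,
                 summaries = list(x = group_summary(x),
                                  y = group_summary(y))),
            class = "group_comparison")
}

#' One-way ANOVA across three or more groups
#'
#' @param groups named list of numeric samples; >= 3 groups, each n >= 2.
#' @param metric label carried into the result.
#' @return object of class `group_comparison` with `test = "anova"`,
#'   `statistic` (F), `df`, `p_value` and per-group summaries.
#' @export
anova_oneway <- function(groups, metric = "metric") {
  if (length(groups) == 2L)
    stop2("two groups: use compare_two_groups()")
  if (length(groups) < 3L) stop2("need >= 3 groups")
  ns <- vapply(groups, function(g) sum(is.finite(g)), 0L)
  if (any(ns < 2L)) stop2("every group needs n >= 2")
  vals <- unlist(lapply(groups, function(g) g[is.finite(g)]))
  fac <- factor(rep(seq_along(groups), ns))
  ht <- oneway.test(vals ~ fac, var.equal = TRUE)
  structure(list(metric = metric, test = "anova",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value,
                 summaries = lapply(groups, group_summary)),
            class = "group_comparison")
}

#' Spearman correlation matrix
#'
#' Pairwise-complete Spearman rank correlations with average ranks for
#' ties; symmetric with unit diagonal. Cells with fewer than 3 complete
#' pairs, and rows/columns of constant variables, carry `NA`.
#'
#' @param table data.frame or matrix of numeric columns.
#' @return numeric matrix of rs values.
#' @export
spearman_matrix <- function(table) {
  m <- as.matrix(as.data.frame(table))
  storage.mode(m) <- "double"
  p <- ncol(m)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) for (j in i:p) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    if (sum(ok) < 3L) next
    if (sd(m[ok, i]) == 0 || sd(m[ok, j]) == 0) next
    out[i, j] <- out[j, i] <- cor(m[ok, i], m[ok, j], method = "spearman")
  }
  for (i in seq_len(p)) {
    ok <- is.finite(m[, i])
    if (sum(ok) >= 3L && sd(m[ok, i]) > 0) out[i, i] <- 1
  }
  out
}

#' Per-stratum summaries of subject metrics
#'
#' Stratifies subject records by disease severity (VC bins), NIV status or
#' group label, and reports n, mean and SEM for each numeric metric. Strata
#' ordering is fixed: group + severity gives HV, mild, moderate, severe;
#' group + NIV gives HV, non-NIV, with_NIV. Empty strata are reported with
#' n = 0; single-record strata have no SEM.
#'
#' @param records data.frame from [read_subject_table()].
#' @param stratifier `"severity"`, `"niv"` or `"group"`.
#' @param metrics character vector of metric columns (default: all numeric
#'   columns except the spirometry inputs when stratifying by them).
#' @return data.frame with columns stratum, metric, n, mean, sem.
#' @export
subgroup_summary <- function(records, stratifier = c("severity", "niv",
                                                     "group"),
                             metrics = NULL) {
  stratifier <- match.arg(stratifier)
  if (stratifier == "severity") {
    if (!"vc_percent" %in% names(records))
      stop2("severity stratification needs vc_percent")
    strat <- ifelse(records$group == "HV", "HV",
                    as.character(stratify_by_vc(records$vc_percent)))
    levels <- c("HV", "mild", "moderate", "severe")
  } else if (stratifier == "niv") {
    if (!"niv" %in% names(records)) stop2("niv stratification needs niv")
    strat <- ifelse(records$group == "HV", "HV",
                    ifelse(records$niv, "with_NIV", "non_NIV"))
    levels <- c("HV", "non_NIV", "with_NIV")
  } else {
    strat <- records$group
    levels <- unique(c("HV", sort(unique(records$group))))
  }
  if (is.null(metrics)) {
    num <- names(records)[vapply(records, is.numeric, TRUE)]
    drop <- if (stratifier == "severity")
      c("vc_percent", "fvc_percent", "fev1_percent", "pef_percent")
    else character(0)
    metrics <- setdiff(num, drop)
  }
  rows <- list()
  for (lv in levels) {
    sel <- strat == lv
    for (mt in metrics) {
      s <- group_summary(if (any(sel)) records[[mt]][sel] else numeric(0))
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = lv, metric = mt, n = s$n,
                   mean = s$mean, sem = s$sem)
    }
  }
  out <- do.call(rbind, rows)
  out$stratum <- factor(out$stratum, levels = levels)
  out
}

#' Tidy table of two-group comparisons across metrics
#'
#' Runs [compare_two_groups()] for every metric column between two groups
#' and returns a tidy data.frame with raw p values plus clearly labelled
#' optional Holm and Benjamini-Hochberg adjusted columns (no silent
#' adjustment).
#'
#' @param records subject data.frame.
#' @param metrics metric column names (default: all numeric).
#' @param group_col grouping column (two levels).
#' @param alpha_normality normality gate level.
#' @param adjust add `p_holm` / `p_bh` columns (default TRUE).
#' @return data.frame, one row per metric.
#' @export
compare_groups_table <- function(records, metrics = NULL,
                                 group_col = "group",
                                 alpha_normality = 0.05, adjust = TRUE) {
  g <- records[[group_col]]
  lv <- sort(unique(g))
  if (length(lv) != 2L) stop2("group column must have exactly two levels")
  if (is.null(metrics))
    metrics <- names(records)[vapply(records, is.numeric, TRUE)]
  rows <- lapply(metrics, function(mt) {
    cmp <- compare_two_groups(records[[mt]][g == lv[1]],
                              records[[mt]][g == lv[2]],
                              alpha_normality = alpha_normality,
                              metric = mt)
    data.frame(metric = mt, test = cmp$test, statistic = cmp$statistic,
               p_value = cmp$p_value,
               mean_1 = cmp$summaries$x$mean, sem_1 = cmp$summaries$x$sem,
               n_1 = cmp$summaries$x$n,
               mean_2 = cmp$summaries$y$mean, sem_2 = cmp$summaries$y$sem,
               n_2 = cmp$summaries$y$n,
               alpha_normality = alpha_normality)
  })
  out <- do.call(rbind, rows)
  names(out) <- sub("_1$", paste0("_", lv[1]), names(out))
  names(out) <- sub("_2$", paste0("_", lv[2]), names(out))
  if (adjust) {
    out$p_holm <- p.adjust(out$p_value, "holm")
    out$p_bh <- p.adjust(out$p_value, "BH")
  }
  out
}
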