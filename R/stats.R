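#' Wilcoxon rank-sum group comparison
#'
#' Two-sided rank-sum test wrapping the standard implementation: exact
#' enumeration when the pooled sample size is at most 20 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.  If every value in both samples is identical the test is
#' degenerate and `p = 1` is returned with a flag.
#'
#' @param x,y numeric samples (each `n >= 2`).
#' @return list with `statistic` (Mann-Whitney U for `x`), `p`
#'   (two-sided), `exact` (logical), `degenerate` (logical).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                exact = FALSE, degenerate = TRUE))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       exact = use_exact, degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a family of p-values; a hypothesis is rejected
#' when its adjusted p-value is at most `q`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param q acceptable false discovery rate (default 0.05).
#' @return list with `p_adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value list")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  padj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = padj, rejected = padj <= q)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank ties; the p-value uses the exact
#' distribution for small tie-free samples and the t-approximation
#' otherwise (the standard implementation's switch).  Constant input
#' yields `NA` with `defined = FALSE`.
#'
#' @param x,y numeric samples (`n >= 3`).
#' @return list with `rho`, `p`, `defined`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("samples must have equal length")
  if (length(x) < 3) stop("n >= 3 required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' Run the full group-comparison battery
#'
#' Executes the study's statistical families on a tidy metric table:
#'
#' * family `"resting_global"`: patient-vs-control rank-sum tests on the
#'   global resting metrics (burst amplitude, non-burst amplitude, total
#'   burst time), BH-corrected across the three.
#' * family `"task"`: the 12-test movement battery (left/right cortex x
#'   left/right press x \{rebound probability, rebound amplitude,
#'   modulation\}), BH-corrected across the twelve.
#' * family `"connectivity"`: single rank-sum test on global mean
#'   connectivity (uncorrected).
#' * family `"symptoms"`: Spearman correlations of symptom severity with
#'   each metric in the table flagged for correlation, run separately
#'   within patients only and across the combined group.  Combined-group
#'   results carry a note that a significant correlation is likely driven
#'   by a group difference, and support rather than establish an
#'   individual-level relationship.
#'
#' Missing family members are skipped with a message.
#'
#' @param metrics data frame with columns `subject`, `group`, `metric`,
#'   `value` (one row per subject x metric).
#' @param symptom_scores optional named numeric vector (names = subject
#'   ids) for the symptom family.
#' @param families character vector of family names to run.
#' @param q false discovery rate (default 0.05).
#' @param task_metrics metric-name prefix set treated as the task family
#'   (default the 12 canonical names, see Details).
#' @return data frame with columns `family`, `test`, `statistic`, `rho`,
#'   `p_raw`, `p_adjusted`, `rejected`, `note`.
#' @export
run_group_battery <- function(metrics, symptom_scores = NULL,
                              families = c("resting_global", "task",
                                           "connectivity", "symptoms"),
                              q = 0.05, task_metrics = NULL) {
  stopifnot(all(c("subject", "group", "metric", "value") %in%
                  names(metrics)))
  res <- list()
  add <- function(family, test, statistic = NA_real_, rho = NA_real_,
                  p = NA_real_, note = "") {
    res[[length(res) + 1L]] <<- data.frame(
      family = family, test = test, statistic = statistic, rho = rho,
      p_raw = p, p_adjusted = NA_real_, rejected = NA, note = note,
      stringsAsFactors = FALSE)
  }
  two_group <- function(metric_name) {
    d <- metrics[metrics$metric == metric_name, ]
    x <- d$value[d$group == "patient"]
    y <- d$value[d$group == "control"]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    wilcoxon_rank_sum(x, y)
  }
  run_family <- function(family, metric_names) {
    ran <- character(0)
    for (m in metric_names) {
      w <- two_group(m)
      if (is.null(w)) {
        message("family ", family, ": metric ", m, " missing; skipped")
        next
      }
      add(family, m, statistic = w$statistic, p = w$p,
          note = if (w$degenerate) "degenerate" else "")
      ran <- c(ran, m)
    }
    ran
  }

  if ("resting_global" %in% families)
    run_family("resting_global",
               c("burst_amplitude", "nonburst_amplitude",
                 "total_burst_time"))
  if ("task" %in% families) {
    if (is.null(task_metrics))
      task_metrics <- as.vector(outer(
        c("pmbr_probability", "pmbr_amplitude", "modulation"),
        as.vector(outer(c("left_cortex", "right_cortex"),
                        c("left_press", "right_press"), paste, sep = ".")),
        function(a, b) paste(b, a, sep = ".")))
    run_family("task", task_metrics)
  }
  if ("connectivity" %in% families)
    run_family("connectivity", "global_connectivity")
  if ("symptoms" %in% families && !is.null(symptom_scores)) {
    corr_metrics <- intersect(unique(metrics$metric),
                              c("burst_amplitude", "global_connectivity",
                                "selected_connectivity"))
    for (m in corr_metrics) {
      d <- metrics[metrics$metric == m, ]
      sc <- symptom_scores[d$subject]
      pat <- d$group == "patient"
      if (sum(pat) >= 3) {
        s <- spearman(sc[pat], d$value[pat])
        add("symptoms", paste0(m, ".patients"), rho = s$rho, p = s$p)
      }
      if (nrow(d) >= 3) {
        s <- spearman(sc, d$value)
        add("symptoms", paste0(m, ".combined"), rho = s$rho, p = s$p,
            note = paste("combined-group correlation: a significant",
                         "result is likely driven by the group",
                         "difference"))
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no tests could be run")
  ## BH within each corrected family; single tests pass through
  for (fam in unique(out$family)) {
    i <- out$family == fam
    if (fam %in% c("resting_global", "task", "symptoms")) {
      f <- bh_fdr(out$p_raw[i], q)
      out$p_adjusted[i] <- f$p_adjusted
      out$rejected[i] <- f$rejected
    } else {
      out$p_adjusted[i] <- out$p_raw[i]
      out$rejected[i] <- out$p_raw[i] <= q
    }
  }
  out
}

#' Two-sided t-test convenience wrapper for demographic tables
#'
#' @param x,y numeric samples.
#' @return list with `statistic`, `p`.
#' @export
demographic_t_test <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}
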