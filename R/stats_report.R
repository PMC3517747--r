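# Descriptive summaries and paired/unpaired comparisons over kinematics
# record tables, mirroring the study's reporting: per-condition mean +/- SD
# cells and Student t-tests (pooled-variance by default, Welch optional),
# two-sided, significance at p < 0.05, no multiplicity correction.

KIN_PARAMETERS <- c("ap_medial", "ap_lateral", "ap_central", "rotation",
                    "height", "pf_angle", "tilt", "shift")

#' Per-cell summary of a kinematics table
#'
#' Sample mean, sample SD (n - 1 denominator) and n for every group x
#' condition x parameter cell.
#'
#' @param records data.frame of kinematics records (one row per subject x
#'   condition) with the columns of [measure_scene()] output.
#' @param parameters character vector of parameter columns to summarize.
#' @return long data.frame of class `kin_summary` with columns `group`,
#'   `flexion`, `muscle`, `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_kinematics <- function(records, parameters = intersect(KIN_PARAMETERS,
                                                                 names(records))) {
  if (!nrow(records)) stop("no records to summarize", call. = FALSE)
  cells <- unique(records[c("group", "flexion", "muscle")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- records$group == cells$group[i] &
      records$flexion == cells$flexion[i] & records$muscle == cells$muscle[i]
    if (sum(sel) < 2L)
      stop("summary cell with fewer than 2 records: ",
           paste(cells[i, ], collapse = "/"), call. = FALSE)
    for (p in parameters) {
      x <- records[[p]][sel]
      out[[length(out) + 1L]] <- data.frame(
        group = cells$group[i], flexion = cells$flexion[i],
        muscle = cells$muscle[i], parameter = p,
        mean = mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("kin_summary", class(res))
  res
}

#' Format a summary as a study-style table
#'
#' One row per parameter, one column per condition, cells formatted
#' `mean +/- sd` to one decimal.
#'
#' @param summary a `kin_summary` (from [summarize_kinematics()]).
#' @param group which group to tabulate.
#' @return character matrix (parameters x conditions).
#' @export
kinematics_table <- function(summary, group) {
  s <- summary[summary$group == group, ]
  conds <- unique(s[c("flexion", "muscle")])
  conds <- conds[order(conds$flexion, conds$muscle == "active"), ]
  pars <- unique(s$parameter)
  tab <- matrix("", length(pars), nrow(conds),
                dimnames = list(pars, sprintf("%d%s", conds$flexion,
                                              ifelse(conds$muscle == "active",
                                                     " flex.", ""))))
  for (i in seq_along(pars)) for (j in seq_len(nrow(conds))) {
    r <- s[s$parameter == pars[i] & s$flexion == conds$flexion[j] &
             s$muscle == conds$muscle[j], ]
    if (nrow(r) == 1L) tab[i, j] <- sprintf("%.1f ± %.1f", r$mean, r$sd)
  }
  tab
}

# shared result constructor
kin_test_result <- function(type, parameter, t, df, p, estimate, n,
                            degenerate = FALSE) {
  structure(list(type = type, parameter = parameter, t = t, df = df, p = p,
                 estimate = estimate, n = n, degenerate = degenerate,
                 significant = isTRUE(p < 0.05)),
            class = "kin_test")
}

#' @export
print.kin_test <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("%s t-test [%s]: degenerate (zero variance), estimate %.3f, n = %d\n",
                x$type, x$parameter, x$estimate, x$n))
  else
    cat(sprintf("%s t-test [%s]: t = %.3f, df = %.1f, p = %.4g%s (n = %d)\n",
                x$type, x$parameter, x$t, x$df, x$p,
                if (x$significant) " *" else "", x$n))
  invisible(x)
}

#' Paired comparison of two conditions
#'
#' Student's paired t-test on within-subject differences between two
#' conditions (df = n - 1, two-sided). Zero-variance differences are
#' reported as a degenerate result rather than an error.
#'
#' @param records kinematics records containing both conditions.
#' @param condition_a,condition_b lists with `flexion` and `muscle`.
#' @param parameter parameter column to compare.
#' @param group optional group filter (required if records hold both groups).
#' @return a `kin_test` result (`t`, `df`, `p`, `estimate` = mean
#'   difference b - a, `degenerate` flag).
#' @export
paired_compare <- function(records, condition_a, condition_b, parameter,
                           group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, ]
  pick <- function(cond) {
    r <- records[records$flexion == cond$flexion & records$muscle == cond$muscle, ]
    r[order(r$subject), ]
  }
  a <- pick(condition_a); b <- pick(condition_b)
  if (!identical(a$subject, b$subject) || nrow(a) == 0L)
    stop("unmatched subjects between the two conditions", call. = FALSE)
  d <- b[[parameter]] - a[[parameter]]
  n <- length(d)
  if (stats::sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12)   # identical conditions: a clean null
      return(kin_test_result("paired", parameter, 0, n - 1, 1, 0, n))
    return(kin_test_result("paired", parameter, NA_real_, n - 1, NA_real_,
                           mean(d), n, degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  kin_test_result("paired", parameter, unname(tt$statistic),
                  unname(tt$parameter), tt$p.value, mean(d), n)
}

#' Unpaired comparison of two groups at one condition
#'
#' Two-sample Student t-test between groups at a fixed condition;
#' pooled-variance by default, Welch with `var_equal = FALSE`.
#'
#' @param records kinematics records for both groups.
#' @param group_a,group_b group labels.
#' @param condition list with `flexion` and `muscle`.
#' @param parameter parameter column to compare.
#' @param var_equal use the pooled-variance statistic (default TRUE).
#' @return a `kin_test` result (`estimate` = mean a - mean b).
#' @export
unpaired_compare <- function(records, group_a, group_b, condition, parameter,
                             var_equal = TRUE) {
  sel <- records$flexion == condition$flexion & records$muscle == condition$muscle
  x <- records[[parameter]][sel & records$group == group_a]
  y <- records[[parameter]][sel & records$group == group_b]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs n >= 2 records at the condition", call. = FALSE)
  if (stats::sd(c(x - mean(x), y - mean(y))) < 1e-12)
    return(kin_test_result("unpaired", parameter, NA_real_,
                           length(x) + length(y) - 2, NA_real_,
                           mean(x) - mean(y), length(x) + length(y),
                           degenerate = TRUE))
  tt <- stats::t.test(x, y, var.equal = var_equal)
  kin_test_result("unpaired", parameter, unname(tt$statistic),
                  unname(tt$parameter), tt$p.value, mean(x) - mean(y),
                  length(x) + length(y))
}

#' All study-style comparisons over a record table
#'
#' Runs, for every parameter: paired flexion-step comparisons (0 vs 30,
#' 30 vs 90) and muscle-effect comparisons per flexion angle within each
#' group, and unpaired group comparisons per condition.
#'
#' @param records kinematics records for one or two groups.
#' @param parameters parameter columns to test.
#' @param var_equal pooled-variance (TRUE) or Welch unpaired tests.
#' @return data.frame with one row per test: `type`, `group`, `parameter`,
#'   `comparison`, `t`, `df`, `p`, `significant`.
#' @export
compare_all <- function(records, parameters = intersect(KIN_PARAMETERS,
                                                        names(records)),
                        var_equal = TRUE) {
  rows <- list()
  add <- function(res, group, comparison) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = res$type, group = group, parameter = res$parameter,
      comparison = comparison, t = res$t, df = res$df, p = res$p,
      significant = res$significant)
  }
  groups <- unique(records$group)
  muscles <- intersect(c("relaxed", "active"), unique(records$muscle))
  flexions <- sort(unique(records$flexion))
  for (g in groups) for (p in parameters) {
    for (mu in muscles) for (k in seq_len(length(flexions) - 1L)) {
      ca <- list(flexion = flexions[k], muscle = mu)
      cb <- list(flexion = flexions[k + 1L], muscle = mu)
      add(paired_compare(records, ca, cb, p, group = g), g,
          sprintf("%d->%d deg (%s)", flexions[k], flexions[k + 1L], mu))
    }
    if (length(muscles) == 2L) for (fx in flexions)
      add(paired_compare(records, list(flexion = fx, muscle = "relaxed"),
                         list(flexion = fx, muscle = "active"), p, group = g),
          g, sprintf("muscle effect at %d deg", fx))
  }
  if (length(groups) == 2L) for (p in parameters)
    for (fx in flexions) for (mu in muscles)
      add(unpaired_compare(records, groups[1], groups[2],
                           list(flexion = fx, muscle = mu), p,
                           var_equal = var_equal),
          paste(groups, collapse = " vs "),
          sprintf("groups at %d deg (%s)", fx, mu))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
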