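# Group-comparison layer: mean +/- SEM summaries, the unpaired
# two-tailed Student's t-test, and mixed-design (group x time)
# repeated-measures ANOVA with Bonferroni post tests.

#' Per-group mean and SEM of one metric
#'
#' Summarizes a long study table as mean +/- SEM (sd / sqrt(n)) per
#' (group, timepoint) cell for one metric.
#'
#' @param table long data.frame with columns `animal`, `group`,
#'   `timepoint`, `metric`, `value`.
#' @param metric metric name to summarize.
#' @return data.frame with `group`, `timepoint`, `n`, `mean`, `sem`,
#'   ordered by group then timepoint (factor order preserved).
#' @export
summarize_metric <- function(table, metric) {
  tab <- check_study_table(table)
  tab <- tab[tab$metric == metric, , drop = FALSE]
  stop_if(nrow(tab) == 0, "metric '%s' not present in the table", metric)
  cells <- split(tab$value,
                 list(group = tab$group, timepoint = tab$timepoint),
                 drop = TRUE, sep = "\r")
  keys <- do.call(rbind, strsplit(names(cells), "\r", fixed = TRUE))
  out <- data.frame(
    group = keys[, 1],
    timepoint = keys[, 2],
    n = vapply(cells, length, integer(1)),
    mean = vapply(cells, mean, numeric(1)),
    sem = vapply(cells, function(v) {
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    row.names = NULL)
  lev_g <- unique(as.character(tab$group))
  lev_t <- unique(as.character(tab$timepoint))
  out[order(match(out$group, lev_g), match(out$timepoint, lev_t)), ,
      drop = FALSE]
}

#' Two-tailed unpaired Student's t-test
#'
#' Classical pooled-variance (equal-variance) form, not Welch's. The
#' statistic is symmetric: swapping the samples negates t and leaves p
#' unchanged.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @examples
#' unpaired_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
unpaired_t_test <- function(a, b) {
  stop_if(!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b),
          "samples must be numeric with no missing values")
  stop_if(length(a) < 2 || length(b) < 2,
          "each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate but well-defined: identical constant samples
    return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Repeated-measures two-way ANOVA with Bonferroni post tests
#'
#' Mixed-design analysis of one metric over the post-intervention
#' timepoints: one between-subjects factor (group) and one
#' within-subjects factor (time), classical sums of squares with
#' subject as the error stratum for the group effect (no sphericity
#' correction). Post hoc, the groups are compared at each timepoint
#' with the pooled-variance t-test and the raw p-values are multiplied
#' by the number of timepoints (Bonferroni), capped at 1.
#'
#' Animals missing any included timepoint are dropped complete-case,
#' with a warning naming them.
#'
#' @param table long study table (see [summarize_metric()]).
#' @param metric metric name.
#' @param timepoints character vector of timepoints to include
#'   (default: every non-baseline timepoint present).
#' @return list with `anova` (data.frame: effect, df, df_error, F, p)
#'   and `posthoc` (data.frame: timepoint, t, df, p_raw, p_adj).
#' @export
rm_anova_bonferroni <- function(table, metric, timepoints = NULL) {
  tab <- check_study_table(table)
  tab <- tab[tab$metric == metric, , drop = FALSE]
  stop_if(nrow(tab) == 0, "metric '%s' not present in the table", metric)
  if (is.null(timepoints)) {
    timepoints <- setdiff(unique(as.character(tab$timepoint)), "baseline")
  }
  stop_if(length(timepoints) < 2, "need >= 2 timepoints for the within factor")
  tab <- tab[tab$timepoint %in% timepoints, , drop = FALSE]
  # complete-case: drop animals not observed at every included timepoint
  counts <- base::table(tab$animal)
  incomplete <- names(counts)[counts < length(timepoints)]
  if (length(incomplete)) {
    warning(sprintf("dropping incomplete animals (complete-case): %s",
                    paste(incomplete, collapse = ", ")), call. = FALSE)
    tab <- tab[!(tab$animal %in% incomplete), , drop = FALSE]
  }
  stop_if(length(unique(tab$group[!duplicated(tab$animal)])) < 2 ||
            min(base::table(tab$group[!duplicated(tab$animal)])) < 2,
          "need >= 2 complete animals in each of >= 2 groups")
  dat <- data.frame(
    value = tab$value,
    group = factor(tab$group),
    time = factor(tab$timepoint, levels = timepoints),
    animal = factor(tab$animal))
  fit <- stats::aov(value ~ group * time + Error(animal), data = dat)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: animal"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  pick <- function(stratum, name) {
    i <- trimws(rownames(stratum)) == name
    stop_if(!any(i), "effect '%s' missing from the ANOVA table", name)
    err <- trimws(rownames(stratum)) == "Residuals"
    data.frame(effect = name,
               df = stratum$Df[i],
               df_error = stratum$Df[err],
               F = stratum$`F value`[i],
               p = stratum$`Pr(>F)`[i])
  }
  anova_tab <- rbind(pick(between, "group"),
                     pick(within, "time"),
                     pick(within, "group:time"))
  lev <- levels(dat$group)
  posthoc <- do.call(rbind, lapply(timepoints, function(tp) {
    a <- dat$value[dat$time == tp & dat$group == lev[1]]
    b <- dat$value[dat$time == tp & dat$group == lev[2]]
    tt <- unpaired_t_test(a, b)
    data.frame(timepoint = tp, t = tt$t, df = tt$df, p_raw = tt$p,
               p_adj = min(1, tt$p * length(timepoints)))
  }))
  list(anova = anova_tab, posthoc = posthoc)
}

check_study_table <- function(table) {
  stop_if(!is.data.frame(table), "table must be a data.frame")
  need <- c("animal", "group", "timepoint", "metric", "value")
  missing_cols <- setdiff(need, names(table))
  stop_if(length(missing_cols) > 0, "table lacks columns: %s",
          paste(missing_cols, collapse = ", "))
  key <- paste(table$animal, table$timepoint, table$metric)
  dup <- duplicated(key)
  stop_if(any(dup), "duplicate (animal, timepoint, metric) row: %s",
          key[dup][1])
  stop_if(!is.numeric(table$value) || anyNA(table$value),
          "value column must be numeric with no missing values")
  table
}
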