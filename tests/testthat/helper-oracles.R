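# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately written by a different route than the
# package implementation it checks.

# Polygon centroid by brute-force fan triangulation from vertex 1:
# signed-area-weighted mean of triangle centroids.
centroid_bruteforce <- function(p) {
  n <- nrow(p)
  acc <- c(0, 0); area <- 0
  for (k in 2:(n - 1)) {
    a <- p[1, ]; b <- p[k, ]; d <- p[k + 1, ]
    tri_area <- ((b[1] - a[1]) * (d[2] - a[2]) -
                   (b[2] - a[2]) * (d[1] - a[1])) / 2
    acc <- acc + tri_area * (a + b + d) / 3
    area <- area + tri_area
  }
  acc / area
}

# Pooled-variance two-sample t-test from the closed-form definition.
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Classical mixed-design ANOVA sums of squares for a *balanced*
# two-group x T-timepoint complete design, straight from the textbook
# decomposition (between-subject stratum: group vs subject-within-group;
# within stratum: time, group:time, residual).
mixed_anova_oracle <- function(value, group, time, subject) {
  stopifnot(length(unique(table(subject))) == 1)
  grand <- mean(value)
  Tn <- length(unique(time))
  subj_means <- tapply(value, subject, mean)
  subj_group <- tapply(group, subject, function(g) g[1])
  group_means <- tapply(value, group, mean)
  time_means <- tapply(value, time, mean)
  cell_means <- tapply(value, list(group, time), mean)
  n_g <- table(subj_group)

  ss_group <- Tn * sum(n_g * (group_means[names(n_g)] - grand)^2)
  ss_subj <- Tn * sum((subj_means - group_means[as.character(subj_group)])^2)
  n_subj_total <- length(unique(subject))
  ss_time <- n_subj_total * sum((time_means - grand)^2)
  ss_int <- 0
  for (g in rownames(cell_means)) for (tt in colnames(cell_means)) {
    ss_int <- ss_int + n_g[[g]] *
      (cell_means[g, tt] - group_means[[g]] - time_means[[tt]] + grand)^2
  }
  ss_total <- sum((value - grand)^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_time - ss_int

  df_group <- length(n_g) - 1
  df_subj <- n_subj_total - length(n_g)
  df_time <- Tn - 1
  df_int <- df_group * df_time
  df_err <- df_subj * df_time

  f_group <- (ss_group / df_group) / (ss_subj / df_subj)
  f_time <- (ss_time / df_time) / (ss_err / df_err)
  f_int <- (ss_int / df_int) / (ss_err / df_err)
  list(
    group = list(F = f_group, p = pf(f_group, df_group, df_subj, lower.tail = FALSE)),
    time = list(F = f_time, p = pf(f_time, df_time, df_err, lower.tail = FALSE)),
    interaction = list(F = f_int, p = pf(f_int, df_int, df_err, lower.tail = FALSE)))
}

# Regular polygon (circle discretization) fixture.
circle_poly <- function(r, n = 96, center = c(0, 0), phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# A long study table drawn from N(mu, sd) per (group, timepoint) cell.
random_study_table <- function(n_per_group = c(a = 4, b = 4),
                               timepoints = c("d2", "d7", "d14", "d28"),
                               mu = 0, sd = 1, metric = "m",
                               subject_sd = 0) {
  rows <- list()
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      id <- sprintf("%s%02d", g, i)
      subj_shift <- rnorm(1, 0, subject_sd)
      for (tp in timepoints) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal = id, group = g, timepoint = tp, metric = metric,
          value = rnorm(1, mu + subj_shift, sd))
      }
    }
  }
  do.call(rbind, rows)
}
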