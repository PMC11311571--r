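#' Normality-routed two-group comparison
#'
#' Implements the study's test-routing protocol on per-volume biomarker
#' medians. A Shapiro-Wilk test at alpha = 0.05 on the pooled values of the
#' feature decides between parametric and nonparametric branches:
#' * paired, parametric: t-test on the paired differences (the paired form
#'   of Welch's t-test: with a single difference sample the unequal-variance
#'   correction reduces to the one-sample t);
#' * paired, nonparametric: Wilcoxon signed-rank (the paired analogue of
#'   the rank-sum test);
#' * unpaired, parametric: Welch's two-sample t-test;
#' * unpaired, nonparametric: Mann-Whitney U (Wilcoxon rank-sum).
#'
#' Missing values are dropped pairwise for paired designs. Degenerate paired
#' data with all differences zero return `p = 1`.
#'
#' @param x,y numeric value vectors for the two groups (equal length and
#'   pairwise ordered when `design = "paired"`).
#' @param design `"paired"` or `"unpaired"`.
#' @param alpha normality-routing significance level (default 0.05).
#' @return a list: `test` (name), `p.value`, `statistic`, `parametric`
#'   (logical), `shapiro_p`.
#' @export
route_test <- function(x, y, design = c("paired", "unpaired"), alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(x) != length(y)) stop("paired design needs equal-length groups")
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
  } else {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
  }
  if (length(x) < 3L || length(y) < 3L)
    stop("need at least 3 values per group")
  pooled <- c(x, y)
  shapiro_p <- if (stats::sd(pooled) == 0) 0 else stats::shapiro.test(pooled)$p.value
  parametric <- shapiro_p >= alpha
  if (design == "paired") {
    d <- x - y
    if (all(d == 0))
      return(list(test = "degenerate (all paired differences zero)",
                  p.value = 1, statistic = 0, parametric = parametric,
                  shapiro_p = shapiro_p))
    ht <- if (parametric) stats::t.test(x, y, paired = TRUE)
          else suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    nm <- if (parametric) "paired t-test" else "Wilcoxon signed-rank"
  } else {
    ht <- if (parametric) stats::t.test(x, y)
          else suppressWarnings(stats::wilcox.test(x, y))
    nm <- if (parametric) "Welch two-sample t-test" else "Mann-Whitney U"
  }
  list(test = nm, p.value = ht$p.value, statistic = unname(ht$statistic),
       parametric = parametric, shapiro_p = shapiro_p)
}

#' Contralateral normalization of lesion medians
#'
#' Subtracts each patient's median contralateral measurement from the median
#' lesion measurement, per biomarker. Patients without a matched lesion and
#' contralateral row are excluded (reported via a message).
#'
#' @param table a study table (`data.frame`) with columns `patient`, `role`
#'   (`"lesion"` / `"contralateral"`) and the biomarker columns.
#' @param biomarkers columns to normalize (default: the seven summary
#'   medians present in the table).
#' @return a `data.frame` with one row per matched patient: `patient` and
#'   lesion-minus-contralateral deltas per biomarker.
#' @export
normalize_to_contralateral <- function(table, biomarkers = NULL) {
  stopifnot(all(c("patient", "role") %in% names(table)))
  if (is.null(biomarkers))
    biomarkers <- intersect(
      c("depth_um", "loss_pct", "mu_overall", "mu_epi", "mu_stroma",
        "es_strat", "ie_strat"), names(table))
  les <- table[table$role == "lesion", , drop = FALSE]
  con <- table[table$role == "contralateral", , drop = FALSE]
  matched <- intersect(les$patient, con$patient)
  dropped <- setdiff(unique(table$patient), matched)
  if (length(dropped))
    message("excluded (no matched lesion/contralateral): ",
            paste(dropped, collapse = ", "))
  if (!length(matched)) return(data.frame(patient = character(0)))
  out <- data.frame(patient = matched, stringsAsFactors = FALSE)
  for (b in biomarkers)
    out[[b]] <- les[[b]][match(matched, les$patient)] -
                con[[b]][match(matched, con$patient)]
  out
}

#' Auxiliary association, variance, and outlier tests
#'
#' The protocol's supporting tests, reported without correction for multiple
#' comparisons: Spearman's rank correlation of each biomarker against age,
#' Levene's test of variance homogeneity across a grouping factor, and a
#' two-sided Grubbs test (alpha = 0.05) for a single outlier per biomarker.
#'
#' @param table study table with an `age` column, optionally a `group`
#'   column, and biomarker columns.
#' @param biomarkers biomarker columns to test (default as in
#'   [normalize_to_contralateral()]).
#' @return a `data.frame` of report rows: `biomarker`, `test`, `statistic`,
#'   `p.value`, `note`.
#' @export
auxiliary_tests <- function(table, biomarkers = NULL) {
  if (is.null(biomarkers))
    biomarkers <- intersect(
      c("depth_um", "loss_pct", "mu_overall", "mu_epi", "mu_stroma",
        "es_strat", "ie_strat"), names(table))
  rows <- list()
  for (b in biomarkers) {
    v <- table[[b]]
    if ("age" %in% names(table)) {
      keep <- !is.na(v) & !is.na(table$age)
      if (sum(keep) >= 3 && stats::sd(v[keep]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(table$age[keep], v[keep], method = "spearman"))
        rows[[length(rows) + 1L]] <- data.frame(
          biomarker = b, test = "Spearman rho (age)",
          statistic = unname(ct$estimate), p.value = ct$p.value, note = "")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          biomarker = b, test = "Spearman rho (age)", statistic = NA_real_,
          p.value = NA_real_, note = "degenerate input")
      }
    }
    if ("group" %in% names(table)) {
      keep <- !is.na(v) & !is.na(table$group)
      if (length(unique(table$group[keep])) >= 2) {
        lev <- car::leveneTest(v[keep], factor(table$group[keep]))
        rows[[length(rows) + 1L]] <- data.frame(
          biomarker = b, test = "Levene", statistic = lev$`F value`[1],
          p.value = lev$`Pr(>F)`[1], note = "")
      }
    }
    g <- grubbs_test(v[!is.na(v)])
    rows[[length(rows) + 1L]] <- data.frame(
      biomarker = b, test = "Grubbs", statistic = g$G, p.value = g$p.value,
      note = if (g$outlier_flagged) sprintf("outlier: %g", g$outlier) else "")
  }
  do.call(rbind, rows)
}

#' Two-sided Grubbs test for a single outlier
#'
#' Tests the observation farthest from the sample mean against the
#' closed-form critical value
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`; the p-value inverts the same relation.
#'
#' @param x numeric vector (n >= 3, non-constant).
#' @param alpha significance level (default 0.05).
#' @return list: `G`, `G_crit`, `p.value`, `outlier`, `outlier_flagged`.
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("Grubbs test needs at least 3 values")
  if (stats::sd(x) == 0)
    return(list(G = 0, G_crit = NA_real_, p.value = 1,
                outlier = NA_real_, outlier_flagged = FALSE))
  dev <- abs(x - mean(x))
  G <- max(dev) / stats::sd(x)
  tcrit <- stats::qt(1 - alpha / (2 * n), n - 2)
  G_crit <- (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  # invert G -> t -> p; q >= 1 means G is at the attainable maximum (n-1)/sqrt(n)
  q <- n * G^2 / (n - 1)^2
  p <- if (q >= 1) 0
       else if (q <= 0) 1
       else min(1, 2 * n * stats::pt(sqrt((n - 2) * q / (1 - q)), n - 2,
                                     lower.tail = FALSE))
  list(G = G, G_crit = G_crit, p.value = p, outlier = x[which.max(dev)],
       outlier_flagged = G > G_crit)
}

#' Group summary tables and bar-chart figures
#'
#' For each biomarker and group: the mean of the per-volume medians, their
#' standard deviation, and the group size; bar charts (mean +/- SD) with
#' significance annotations for routed-test p-values below 0.05.
#'
#' @param table study table with `group`, `role`, and biomarker columns.
#' @param dir output directory for `group_summary.csv`, `comparisons.csv`
#'   and `biomarkers_report.png`; `NULL` skips writing.
#' @param design comparison design between roles within groups
#'   (see [route_test()]).
#' @return invisibly, a list with `summary` and `comparisons` data frames.
#' @export
report_biomarkers <- function(table, dir = NULL, design = "unpaired") {
  stopifnot(all(c("group", "role") %in% names(table)))
  biomarkers <- intersect(
    c("depth_um", "loss_pct", "mu_overall", "mu_epi", "mu_stroma",
      "es_strat", "ie_strat"), names(table))
  cells <- expand.grid(group = unique(table$group), role = unique(table$role),
                       biomarker = biomarkers, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    v <- table[[cells$biomarker[i]]][table$group == cells$group[i] &
                                     table$role == cells$role[i]]
    v <- v[!is.na(v)]
    data.frame(cells[i, ], n = length(v),
               mean_of_medians = if (length(v)) mean(v) else NA_real_,
               sd_of_medians = if (length(v) > 1) stats::sd(v) else 0)
  }))
  groups <- unique(table$group)
  comps <- list()
  for (b in biomarkers) for (g in groups) {
    x <- table[[b]][table$group == g & table$role == "lesion"]
    y <- table[[b]][table$group == g & table$role == "contralateral"]
    if (sum(!is.na(x)) >= 3 && sum(!is.na(y)) >= 3) {
      rt <- tryCatch(route_test(x[!is.na(x)], y[!is.na(y)], "unpaired"),
                     error = function(e) NULL)
      if (!is.null(rt))
        comps[[length(comps) + 1L]] <- data.frame(
          biomarker = b, group = g, test = rt$test, p.value = rt$p.value,
          significant = rt$p.value < 0.05)
    }
  }
  comps <- if (length(comps)) do.call(rbind, comps)
           else data.frame(biomarker = character(0), group = character(0),
                           test = character(0), p.value = numeric(0),
                           significant = logical(0))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(summ, file.path(dir, "group_summary.csv"), row.names = FALSE)
    utils::write.csv(comps, file.path(dir, "comparisons.csv"), row.names = FALSE)
    p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$group,
                                            y = .data$mean_of_medians,
                                            fill = .data$role)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_of_medians - .data$sd_of_medians,
                                          ymax = .data$mean_of_medians + .data$sd_of_medians),
                             position = ggplot2::position_dodge(width = 0.9),
                             width = 0.25) +
      ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                         position = ggplot2::position_dodge(width = 0.9),
                         vjust = -0.5, size = 2.5) +
      ggplot2::facet_wrap(~biomarker, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "mean of per-volume medians") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "biomarkers_report.png"), p,
                    width = 9, height = 6, dpi = 120)
  }
  invisible(list(summary = summ, comparisons = comps))
}
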