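PARAM_COLS <- c("area", "perimeter", "feret_x", "feret_y", "feret",
                "pf_ratio", "solidity", "mgv", "cmgv", "mean_thickness")

#' Aggregate measurements to the analysis unit
#'
#' The default analysis unit is the patient: each patient's value for a
#' parameter is the mean over that patient's non-empty fields. `"field"` and
#' `"roi"` pass the table through at that granularity (hand a per-ROI table
#' in for `level = "roi"`). Empty fields (`n_roi == 0`) and patients with no
#' non-empty fields are excluded with a warning.
#'
#' @param table a per-field (or per-ROI) `data.frame` carrying `sample_id`,
#'   `group_label`, optionally `subgroup` and `n_roi`, plus numeric
#'   parameter columns.
#' @param level `"patient"` (default), `"field"`, or `"roi"`.
#' @return A `data.frame` with one row per analysis unit.
#' @export
aggregate_units <- function(table, level = c("patient", "field", "roi")) {
  level <- match.arg(level)
  stopifnot(all(c("sample_id", "group_label") %in% names(table)))
  if (!is.null(table$n_roi)) {
    empty <- table$n_roi == 0
    if (any(empty)) {
      warning(sprintf("excluding %d empty field(s)", sum(empty)),
              call. = FALSE)
      table <- table[!empty, , drop = FALSE]
    }
  }
  if (nrow(table) == 0L) {
    warning("no non-empty units to aggregate", call. = FALSE)
    return(table)
  }
  if (level != "patient") {
    out <- table
    out$unit <- level
    return(out)
  }
  params <- intersect(PARAM_COLS, names(table))
  ids <- unique(table$sample_id)
  rows <- lapply(ids, function(s) {
    sub <- table[table$sample_id == s, , drop = FALSE]
    means <- lapply(sub[params], mean)
    cbind(data.frame(sample_id = s,
                     group_label = sub$group_label[1],
                     subgroup = (sub$subgroup %||% "none")[1],
                     n_fields = nrow(sub)),
          as.data.frame(means))
  })
  out <- do.call(rbind, rows)
  out$unit <- "patient"
  out
}

pooled_descriptives <- function(x) {
  n <- length(x)
  c(mean = mean(x), sd = if (n >= 2) stats::sd(x) else NA_real_, n = n)
}

#' Two-group comparison of morphometric parameters
#'
#' Descriptives (sample mean and SD, n-1 denominator) per group and a
#' two-sided Student's t-test per parameter. The pooled-variance test is the
#' default; `var_equal = FALSE` gives the Welch variant. Groups with fewer
#' than two units get descriptives only (test columns `NA`, with a warning);
#' perfectly separated groups with zero within-group variance are reported
#' with `t = +/-Inf` and the smallest representable positive p, with a
#' degeneracy warning. No multiple-testing correction is applied by default
#' (pass `p_adjust = "holm"` to add adjusted p-values).
#'
#' @param table output of [aggregate_units()] (or any data frame with
#'   `group_label` plus numeric parameter columns).
#' @param parameters parameter columns to compare; defaults to all known
#'   parameter columns present.
#' @param var_equal pooled-variance Student's test if `TRUE` (default);
#'   Welch if `FALSE`.
#' @param p_adjust optional p-value adjustment method (see
#'   [stats::p.adjust()]); `"none"` (default) matches an uncorrected design.
#' @return A `group_comparison` data frame: one row per parameter with group
#'   descriptives, `t_statistic`, `df`, `p_value`, and the aggregation level.
#' @export
compare_groups <- function(table, parameters = NULL, var_equal = TRUE,
                           p_adjust = "none") {
  stopifnot("group_label" %in% names(table))
  groups <- intersect(c("disease", "control"), unique(table$group_label))
  if (length(groups) < 2) groups <- sort(unique(table$group_label))
  if (length(groups) != 2L)
    stop_validation("exactly two groups required, found: %s",
                    paste(unique(table$group_label), collapse = ", "))
  parameters <- parameters %||% intersect(PARAM_COLS, names(table))
  level <- (table$unit %||% "patient")[1]
  rows <- lapply(parameters, function(p) {
    xa <- table[[p]][table$group_label == groups[1]]
    xb <- table[[p]][table$group_label == groups[2]]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    da <- pooled_descriptives(xa); db <- pooled_descriptives(xb)
    tt <- list(statistic = NA_real_, parameter = NA_real_,
               p.value = NA_real_)
    if (length(xa) >= 2 && length(xb) >= 2) {
      tt <- tryCatch(
        stats::t.test(xa, xb, var.equal = var_equal),
        error = function(e) {
          warning(sprintf("%s: degenerate comparison (%s); reporting t = Inf, p -> 0",
                          p, conditionMessage(e)), call. = FALSE)
          list(statistic = sign(mean(xa) - mean(xb)) * Inf,
               parameter = length(xa) + length(xb) - 2,
               p.value = .Machine$double.xmin)
        })
    } else {
      warning(sprintf("%s: a group has fewer than 2 units; descriptives only",
                      p), call. = FALSE)
    }
    data.frame(parameter_name = p,
               group_a = groups[1], group_a_mean = da["mean"],
               group_a_sd = da["sd"], group_a_n = da["n"],
               group_b = groups[2], group_b_mean = db["mean"],
               group_b_sd = db["sd"], group_b_n = db["n"],
               t_statistic = unname(tt$statistic),
               df = unname(tt$parameter),
               p_value = unname(tt$p.value),
               aggregation_level = level,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none"))
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  class(out) <- c("group_comparison", class(out))
  out
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Two-group comparison (%s level): %s (n=%d) vs %s (n=%d)\n",
              x$aggregation_level[1], x$group_a[1], as.integer(x$group_a_n[1]),
              x$group_b[1], as.integer(x$group_b_n[1])))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-14s %8.3f \u00b1 %-8.3f vs %8.3f \u00b1 %-8.3f  t=%6.2f  p=%.3g\n",
                x$parameter_name[i], x$group_a_mean[i], x$group_a_sd[i],
                x$group_b_mean[i], x$group_b_sd[i],
                x$t_statistic[i], x$p_value[i]))
  }
  invisible(x)
}

#' Subgroup descriptives (no tests)
#'
#' Mean and SD per clinical subgroup within each group, plus the group total
#' — descriptives only, since subgroup sizes in this design are too small
#' for inference. A subgroup of one unit gets its mean with `SD = NA`.
#'
#' @param table output of [aggregate_units()] with a `subgroup` column.
#' @param parameters parameter columns; defaults to all present.
#' @return Long-format `data.frame`: `parameter_name`, `group_label`,
#'   `subgroup` (including `"total"`), `n`, `mean`, `sd`.
#' @export
subgroup_table <- function(table, parameters = NULL) {
  stopifnot("group_label" %in% names(table))
  if (is.null(table$subgroup)) table$subgroup <- "none"
  parameters <- parameters %||% intersect(PARAM_COLS, names(table))
  rows <- list()
  for (g in unique(table$group_label)) {
    sub <- table[table$group_label == g, , drop = FALSE]
    cells <- c("total", sort(unique(sub$subgroup)))
    for (s in cells) {
      xs <- if (s == "total") sub else sub[sub$subgroup == s, , drop = FALSE]
      if (nrow(xs) == 0L) next
      for (p in parameters) {
        d <- pooled_descriptives(xs[[p]][!is.na(xs[[p]])])
        rows[[length(rows) + 1L]] <-
          data.frame(parameter_name = p, group_label = g, subgroup = s,
                     n = unname(d["n"]), mean = unname(d["mean"]),
                     sd = unname(d["sd"]))
      }
    }
  }
  do.call(rbind, rows)
}

#' Pivot subgroup descriptives to the wide report layout
#'
#' One row per parameter; one `mean +/- sd` column per (group, subgroup)
#' cell, total first, with the two-group p-value appended when a
#' `group_comparison` is supplied.
#'
#' @param sub_tab output of [subgroup_table()].
#' @param comparison optional [compare_groups()] result.
#' @return A character-matrix-like `data.frame` ready for CSV export.
#' @export
format_report_table <- function(sub_tab, comparison = NULL) {
  fmt <- function(m, s) {
    ifelse(is.na(m), "",
           ifelse(is.na(s), sprintf("%.3g", m),
                  sprintf("%.3g \u00b1 %.3g", m, s)))
  }
  params <- unique(sub_tab$parameter_name)
  cells <- unique(sub_tab[, c("group_label", "subgroup")])
  out <- data.frame(parameter = params)
  for (i in seq_len(nrow(cells))) {
    g <- cells$group_label[i]; s <- cells$subgroup[i]
    col <- paste(g, s, sep = "_")
    v <- vapply(params, function(p) {
      row <- sub_tab[sub_tab$parameter_name == p &
                       sub_tab$group_label == g & sub_tab$subgroup == s, ]
      if (nrow(row) == 0) "" else fmt(row$mean, row$sd)
    }, character(1))
    out[[col]] <- unname(v)
  }
  if (!is.null(comparison)) {
    out$p_value <- vapply(params, function(p) {
      pv <- comparison$p_value[comparison$parameter_name == p]
      if (length(pv) == 0 || is.na(pv[1])) "" else sprintf("%.3g", pv[1])
    }, character(1))
  }
  out
}
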