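#' Delta-delta-CT relative quantification
#'
#' Classical qPCR quantification with amplification efficiency fixed at
#' 2: per sample, `delta_ct = ct_target - ct_reference` (cycles);
#' `delta_delta_ct = delta_ct - mean(control delta_ct)`; relative
#' quantity `rq = 2^(-delta_delta_ct)`. Technical replicates (duplicate
#' `sample_id` rows) are averaged per sample before the computation.
#' Groups are compared by Welch's t-test on the rq values.
#'
#' @param plate Data.frame with columns `sample_id`, `group`,
#'   `ct_target`, `ct_reference`.
#' @param control_group Group label used as the calibrator.
#' @return An object of class `ddct_result`: list with `samples`
#'   (per-sample `delta_ct`, `delta_delta_ct`, `rq`), `groups`
#'   (per-group `n`, `mean_rq`, `sem_rq`) and `welch` (t, df, p for
#'   case vs control rq; `NULL` if only one group).
#' @export
#' @examples
#' plate <- simulate_qpcr_plate(5, group_delta_ct = 1, noise_sd = 0, seed = 1)
#' ddct_quantify(plate)$groups
ddct_quantify <- function(plate, control_group = "control") {
  required <- c("sample_id", "group", "ct_target", "ct_reference")
  missing_cols <- setdiff(required, names(plate))
  if (length(missing_cols) > 0) {
    stop("plate is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(plate$ct_target)) || any(!is.finite(plate$ct_reference))) {
    bad <- plate$sample_id[!is.finite(plate$ct_target) |
                             !is.finite(plate$ct_reference)]
    stop("missing or non-finite CT for sample(s): ",
         paste(unique(bad), collapse = ", "))
  }
  # average technical replicates per sample
  agg <- stats::aggregate(plate[, c("ct_target", "ct_reference")],
                          by = list(sample_id = plate$sample_id), FUN = mean)
  agg$group <- plate$group[match(agg$sample_id, plate$sample_id)]
  if (!control_group %in% agg$group) {
    stop(sprintf("control group '%s' has no samples", control_group))
  }
  agg$delta_ct <- agg$ct_target - agg$ct_reference
  ctrl_mean <- mean(agg$delta_ct[agg$group == control_group])
  agg$delta_delta_ct <- agg$delta_ct - ctrl_mean
  agg$rq <- 2^(-agg$delta_delta_ct)
  groups <- do.call(rbind, lapply(split(agg, agg$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean_rq = mean(g$rq),
               sem_rq = stats::sd(g$rq) / sqrt(nrow(g)),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  other <- setdiff(unique(agg$group), control_group)
  welch <- NULL
  if (length(other) == 1 && sum(agg$group == other) >= 2 &&
      sum(agg$group == control_group) >= 2) {
    welch <- tryCatch(
      welch_t(agg$rq[agg$group == other], agg$rq[agg$group == control_group]),
      error = function(e) NULL
    )
  }
  structure(
    list(samples = agg[, c("sample_id", "group", "delta_ct",
                           "delta_delta_ct", "rq")],
         groups = groups, welch = welch, control_group = control_group),
    class = "ddct_result"
  )
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("ddct_result (control =", x$control_group, ")\n")
  print(x$groups)
  if (!is.null(x$welch)) {
    cat(sprintf("Welch t = %.3f, df = %.2f, p = %.4g\n", x$welch$t,
                x$welch$df, x$welch$p))
  }
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unpaired t-test with Welch's correction (Welch-Satterthwaite degrees
#' of freedom), two-sided.
#'
#' @param a,b Numeric vectors of >= 2 values each; at least one with
#'   non-zero variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("at least one group needs non-zero variance")
  }
  ht <- stats::t.test(a, b)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Student's pooled-variance two-sample t-test
#'
#' @inheritParams welch_t
#' @return List with `t`, `df` (`n_a + n_b - 2`), `p` (two-sided).
#' @export
student_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("at least one group needs non-zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Chi-square test on a 2 x k count table
#'
#' Pearson chi-square without continuity correction by default (Yates
#' available via `correct = TRUE`); for tables with small or empty cells
#' Fisher's exact test is available via `exact = TRUE`.
#'
#' @param table Non-negative 2 x k count matrix with positive margins.
#' @param correct Apply Yates continuity correction (2 x 2 only).
#' @param exact Use Fisher's exact test instead.
#' @return List with `statistic` (NA for exact), `df`, `p`.
#' @export
#' @examples
#' chi2_test(rbind(c(13, 17), c(0, 30)))
chi2_test <- function(table, correct = FALSE, exact = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margins: every row and column needs a positive sum")
  }
  if (exact) {
    ht <- stats::fisher.test(table)
    return(list(statistic = NA_real_, df = NA_real_, p = ht$p.value))
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

.fmt_mean_se <- function(x) {
  sprintf("%.1f ± %.1f", mean(x), stats::sd(x) / sqrt(length(x)))
}

.fmt_count_pct <- function(count, n) {
  sprintf("%d (%.1f)", count, round(100 * count / n, 1))
}

#' Clinical characteristics table summary
#'
#' Summarizes a per-subject data.frame the way clinical baseline tables
#' are printed: continuous variables as `mean +/- SE` per group with a
#' Student t-test p-value; categorical variables as `count (%)` per group
#' and level with a chi-square p-value (`percent = 100 * count / n`,
#' one decimal; SE = sd / sqrt(n)).
#'
#' @param data Data.frame of subjects; one row per subject.
#' @param group_col Name of the two-level grouping column.
#' @param exact Use Fisher's exact test for the categorical comparisons.
#' @return A data.frame with columns `variable`, `level`, one formatted
#'   column per group, `p_value`, `test`.
#' @export
summarize_clinical <- function(data, group_col = "group", exact = FALSE) {
  stopifnot(group_col %in% names(data))
  g <- as.character(data[[group_col]])
  levels_g <- unique(g)
  if (length(levels_g) != 2) stop("grouping column must have two levels")
  n_g <- table(factor(g, levels = levels_g))
  if (any(n_g == 0)) stop("both groups need at least one subject")
  vars <- setdiff(names(data), group_col)
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      vals <- split(x, factor(g, levels = levels_g))
      p <- tryCatch(student_t(vals[[1]], vals[[2]])$p,
                    error = function(e) NA_real_)
      row <- data.frame(variable = v, level = "", stringsAsFactors = FALSE)
      for (lv in levels_g) row[[lv]] <- .fmt_mean_se(vals[[lv]])
      row$p_value <- p
      row$test <- "student_t"
      rows[[length(rows) + 1]] <- row
    } else {
      x <- as.character(x)
      lv_x <- unique(x)
      tab <- table(factor(g, levels = levels_g), factor(x, levels = lv_x))
      p <- tryCatch(chi2_test(tab, exact = exact)$p,
                    error = function(e) NA_real_)
      for (i in seq_along(lv_x)) {
        row <- data.frame(variable = v, level = lv_x[i],
                          stringsAsFactors = FALSE)
        for (lv in levels_g) {
          row[[lv]] <- .fmt_count_pct(tab[lv, lv_x[i]], n_g[[lv]])
        }
        row$p_value <- if (i == 1) p else NA_real_
        row$test <- if (i == 1) {
          if (exact) "fisher_exact" else "chi2"
        } else {
          ""
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
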