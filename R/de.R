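#' Configuration of the permutation DE test
#'
#' @param n_permutations Number of random label permutations (default
#'   300).
#' @param seed Integer seed for the permutation draws.
#' @param alpha_combined Threshold on the Stouffer-combined p-value.
#' @param alpha_t Threshold on the empirical t-statistic p-value.
#' @param fc_cutoff Positive absolute log2 fold-change cutoff (default
#'   0.58, i.e. 1.5-fold), or the string `"adaptive"` to derive it from
#'   the permutation null via [adaptive_fc_cutoff()].
#' @param percentile_pair Percentile pair for the adaptive cutoff; must
#'   be symmetric about 50 (e.g. `c(10, 90)` or `c(2.5, 97.5)`).
#' @param var_method `"pooled"` (Student) or `"welch"` per-gene variance.
#' @param sd_floor_quantile Per-gene standard errors are floored at this
#'   quantile of all gene-level standard errors so no t-statistic is
#'   infinite; `0` disables the floor.
#'
#' @return An object of class `de_config`.
#' @export
de_config <- function(n_permutations = 300, seed = 1L, alpha_combined = 0.05,
                      alpha_t = 0.05, fc_cutoff = 0.58,
                      percentile_pair = c(10, 90),
                      var_method = c("pooled", "welch"),
                      sd_floor_quantile = 0.01) {
  var_method <- match.arg(var_method)
  stopifnot(
    n_permutations >= 1,
    alpha_combined > 0, alpha_combined < 1,
    alpha_t > 0, alpha_t < 1,
    length(percentile_pair) == 2,
    sd_floor_quantile >= 0, sd_floor_quantile < 1
  )
  if (abs(sum(percentile_pair) - 100) > 1e-8) {
    stop("percentile_pair must be symmetric about 50")
  }
  adaptive <- identical(fc_cutoff, "adaptive")
  if (!adaptive && (!is.numeric(fc_cutoff) || fc_cutoff <= 0)) {
    stop("fc_cutoff must be a positive number or \"adaptive\"")
  }
  structure(
    list(
      n_permutations = as.integer(n_permutations), seed = as.integer(seed),
      alpha_combined = alpha_combined, alpha_t = alpha_t,
      fc_cutoff = fc_cutoff, percentile_pair = as.numeric(percentile_pair),
      var_method = var_method, sd_floor_quantile = sd_floor_quantile
    ),
    class = "de_config"
  )
}

.group_indices <- function(m, groups) {
  groups <- groups[colnames(m)]
  case <- which(groups == "case")
  ctrl <- which(groups == "control")
  if (length(case) < 2 || length(ctrl) < 2) {
    stop("each group needs at least two samples")
  }
  list(case = case, ctrl = ctrl)
}

# Column-wise means/variances over an assignment indicator matrix.
# m: genes x samples; a: samples x P 0/1 indicator with colSums n1.
.perm_stats <- function(m, a, n1, n2, var_method, sd_floor_quantile) {
  s1 <- m %*% a
  s2 <- m %*% (1 - a)
  q1 <- (m * m) %*% a
  q2 <- (m * m) %*% (1 - a)
  m1 <- s1 / n1
  m2 <- s2 / n2
  v1 <- pmax((q1 - n1 * m1^2) / (n1 - 1), 0)
  v2 <- pmax((q2 - n2 * m2^2) / (n2 - 1), 0)
  fc <- m1 - m2
  se <- if (var_method == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    sqrt(v1 / n1 + v2 / n2)
  }
  if (sd_floor_quantile > 0) {
    floors <- apply(se, 2, stats::quantile, probs = sd_floor_quantile)
    se <- pmax(se, rep(floors, each = nrow(se)))
  }
  t_stat <- fc / se
  t_stat[fc == 0 & se == 0] <- 0
  list(t = t_stat, fc = fc)
}

#' Per-gene t-statistic and log2 fold-change
#'
#' On the normalized log2 matrix, `log2fc = mean(case) - mean(control)`
#' and `t` is the two-sample t-statistic (Student pooled-variance by
#' default, Welch optionally). Per-gene standard errors are floored at
#' the `sd_floor_quantile` quantile of all standard errors so every t is
#' finite.
#'
#' @param m Normalized log2 matrix, genes x samples.
#' @param groups Named `"case"`/`"control"` vector; each group >= 2
#'   samples.
#' @inheritParams de_config
#'
#' @return A data.frame with columns `gene_id`, `log2fc`, `t_stat`.
#' @export
#' @examples
#' m <- rbind(g1 = c(2, 4, 6, 1, 2, 3))
#' colnames(m) <- c(paste0("c", 1:3), paste0("k", 1:3))
#' groups <- setNames(rep(c("case", "control"), each = 3), colnames(m))
#' gene_statistics(m, groups)
gene_statistics <- function(m, groups, var_method = c("pooled", "welch"),
                            sd_floor_quantile = 0.01) {
  var_method <- match.arg(var_method)
  idx <- .group_indices(m, groups)
  a <- matrix(0, ncol(m), 1)
  a[idx$case, 1] <- 1
  st <- .perm_stats(m, a, length(idx$case), length(idx$ctrl), var_method,
                    sd_floor_quantile)
  data.frame(gene_id = rownames(m), log2fc = st$fc[, 1], t_stat = st$t[, 1],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Permutation empirical null distributions
#'
#' Recomputes the per-gene t-statistic and log2 fold-change under random
#' reassignments of the group labels (group sizes preserved; assignments
#' drawn uniformly, with replacement across permutations). When the
#' number of distinct label assignments is below `cfg$n_permutations` a
#' warning notes that sampling with replacement is forced. With
#' `exhaustive = TRUE` all `choose(n, n_case)` assignments are enumerated
#' instead.
#'
#' The per-gene draws are pooled across genes into `pooled_t` and
#' `pooled_fc`; empirical p-values and adaptive cutoffs are computed from
#' these pooled vectors (gene-specific nulls at a few hundred
#' permutations are too coarse for p < 0.05).
#'
#' @inheritParams gene_statistics
#' @param cfg A [de_config()].
#' @param exhaustive Enumerate all distinct assignments instead of
#'   sampling.
#'
#' @return An object of class `null_distributions`: list with `null_t`,
#'   `null_fc` (genes x permutations matrices) and `pooled_t`,
#'   `pooled_fc` (flattened vectors).
#' @export
permutation_null <- function(m, groups, cfg = de_config(),
                             exhaustive = FALSE) {
  idx <- .group_indices(m, groups)
  n <- ncol(m)
  n1 <- length(idx$case)
  if (exhaustive) {
    idx_mat <- utils::combn(n, n1)
  } else {
    n_distinct <- choose(n, n1)
    if (n_distinct < cfg$n_permutations) {
      warning(sprintf(
        "requested %d permutations but only %d distinct label assignments exist; sampling with replacement",
        cfg$n_permutations, n_distinct
      ))
    }
    set.seed(cfg$seed)
    idx_mat <- replicate(cfg$n_permutations, sample.int(n, n1))
  }
  p <- ncol(idx_mat)
  a <- matrix(0, n, p)
  a[cbind(as.vector(idx_mat), rep(seq_len(p), each = n1))] <- 1
  st <- .perm_stats(m, a, n1, n - n1, cfg$var_method, cfg$sd_floor_quantile)
  dimnames(st$t) <- dimnames(st$fc) <- list(rownames(m), NULL)
  structure(
    list(null_t = st$t, null_fc = st$fc,
         pooled_t = as.vector(st$t), pooled_fc = as.vector(st$fc),
         n_genes = nrow(m), n_permutations = p),
    class = "null_distributions"
  )
}

#' @export
print.null_distributions <- function(x, ...) {
  cat(sprintf("null_distributions: %d genes x %d permutations (pooled n = %d)\n",
              x$n_genes, x$n_permutations, length(x$pooled_t)))
  invisible(x)
}

#' Two-tailed empirical p-value against a pooled null
#'
#' `p = (#\{|null| >= |stat|\} + 1) / (N + 1)`, so p is always in
#' `(0, 1]`. Vectorized over `stat`.
#'
#' @param stat Observed statistic(s); must be finite.
#' @param pooled_null Non-empty numeric vector of null draws.
#' @return Empirical p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' empirical_pvalue(2.5, rnorm(599))
empirical_pvalue <- function(stat, pooled_null) {
  if (length(pooled_null) == 0) stop("pooled null must be non-empty")
  if (any(!is.finite(stat))) stop("stat must be finite")
  sorted <- sort(abs(pooled_null))
  n <- length(sorted)
  ge <- n - findInterval(abs(stat), sorted, left.open = TRUE)
  (ge + 1) / (n + 1)
}

#' Stouffer combination of two p-values
#'
#' `z_i = qnorm(1 - p_i)`, `z = (z_t + z_fc) / sqrt(2)`,
#' `p = 1 - pnorm(z)`. Inputs are clipped to `[1e-15, 1 - 1e-15]` first
#' (a message reports how many values were clipped). Vectorized.
#'
#' @param p_t,p_fc p-values in `(0, 1]`.
#' @return Combined p-value(s) in `(0, 1)`.
#' @export
#' @examples
#' stouffer_combine(0.05, 0.05)
stouffer_combine <- function(p_t, p_fc) {
  check <- c(p_t, p_fc)
  if (any(!is.finite(check)) || any(check <= 0) || any(check > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  eps <- 1e-15
  n_clip <- sum(p_t < eps | p_t > 1 - eps) + sum(p_fc < eps | p_fc > 1 - eps)
  if (n_clip > 0) {
    message(sprintf("stouffer_combine: clipped %d p-value(s) to [1e-15, 1 - 1e-15]", n_clip))
  }
  p_t <- pmin(pmax(p_t, eps), 1 - eps)
  p_fc <- pmin(pmax(p_fc, eps), 1 - eps)
  z <- (stats::qnorm(p_t, lower.tail = FALSE) +
          stats::qnorm(p_fc, lower.tail = FALSE)) / sqrt(2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Percentile-derived adaptive fold-change cutoff
#'
#' For datasets whose log2 fold-change spread differs from the cohort the
#' fixed 0.58 cutoff was tuned on, the cutoff is taken from the
#' permutation null itself: the mean of the absolute values of a
#' symmetric percentile pair of the pooled null log2 fold-changes.
#'
#' @param pooled_null_fc Non-empty pooled null log2 fold-change vector.
#' @param percentile_pair Symmetric percentile pair, e.g. `c(10, 90)`.
#' @return Non-negative cutoff.
#' @export
adaptive_fc_cutoff <- function(pooled_null_fc, percentile_pair = c(10, 90)) {
  if (length(pooled_null_fc) == 0) stop("pooled null must be non-empty")
  q <- stats::quantile(pooled_null_fc, percentile_pair / 100, names = FALSE)
  mean(abs(q))
}

#' Three-criterion DEG call
#'
#' A gene is a DEG iff its combined p-value, empirical t p-value and
#' absolute log2 fold-change all pass; direction follows the sign of the
#' fold-change.
#'
#' @param records Data.frame with columns `gene_id`, `log2fc`,
#'   `p_combined`, `p_t_adj`.
#' @param alpha_combined,alpha_t Significance thresholds.
#' @param fc_cutoff Numeric absolute log2 fold-change cutoff.
#' @return `records` with `is_deg` (logical) and `direction`
#'   (`"up"`/`"down"`/`"none"`) columns added.
#' @export
call_degs <- function(records, alpha_combined = 0.05, alpha_t = 0.05,
                      fc_cutoff = 0.58) {
  stopifnot(is.numeric(fc_cutoff), fc_cutoff >= 0)
  records$is_deg <- records$p_combined < alpha_combined &
    records$p_t_adj < alpha_t &
    abs(records$log2fc) > fc_cutoff
  records$direction <- ifelse(!records$is_deg, "none",
                              ifelse(records$log2fc > 0, "up", "down"))
  records
}

#' Run the full permutation DE test
#'
#' Observed statistics, permutation null, empirical p-values for both
#' statistics, Stouffer combination, fold-change cutoff resolution
#' (fixed or adaptive) and the three-criterion DEG call.
#'
#' @inheritParams gene_statistics
#' @param cfg A [de_config()].
#' @return An object of class `de_result`: list with `records` (one row
#'   per gene: `gene_id`, `log2fc`, `t_stat`, `p_t_adj`, `p_fc_adj`,
#'   `p_combined`, `is_deg`, `direction`), `nulls`, `fc_cutoff` (numeric
#'   value used) and `config`.
#' @export
run_de <- function(m, groups, cfg = de_config()) {
  obs <- gene_statistics(m, groups, var_method = cfg$var_method,
                         sd_floor_quantile = cfg$sd_floor_quantile)
  nulls <- permutation_null(m, groups, cfg)
  obs$p_t_adj <- empirical_pvalue(obs$t_stat, nulls$pooled_t)
  obs$p_fc_adj <- empirical_pvalue(obs$log2fc, nulls$pooled_fc)
  obs$p_combined <- stouffer_combine(obs$p_t_adj, obs$p_fc_adj)
  cutoff <- if (identical(cfg$fc_cutoff, "adaptive")) {
    adaptive_fc_cutoff(nulls$pooled_fc, cfg$percentile_pair)
  } else {
    cfg$fc_cutoff
  }
  records <- call_degs(obs, cfg$alpha_combined, cfg$alpha_t, cutoff)
  records <- records[, c("gene_id", "log2fc", "t_stat", "p_t_adj", "p_fc_adj",
                         "p_combined", "is_deg", "direction")]
  structure(list(records = records, nulls = nulls, fc_cutoff = cutoff,
                 config = cfg),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  n_up <- sum(x$records$direction == "up")
  n_dn <- sum(x$records$direction == "down")
  cat(sprintf(
    "de_result: %d genes, %d permutations, |log2FC| cutoff %.3f; %d DEGs (%d up, %d down)\n",
    nrow(x$records), x$nulls$n_permutations, x$fc_cutoff,
    n_up + n_dn, n_up, n_dn
  ))
  invisible(x)
}

#' Up/down DEG gene lists from a DE result
#'
#' @param de A `de_result` from [run_de()], or a records data.frame with
#'   `gene_id` and `direction` columns.
#' @return List with sorted character vectors `up` and `down`.
#' @export
deg_lists <- function(de) {
  records <- if (inherits(de, "de_result")) de$records else de
  list(up = sort(records$gene_id[records$direction == "up"]),
       down = sort(records$gene_id[records$direction == "down"]))
}
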