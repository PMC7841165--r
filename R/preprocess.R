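#' Expressed-gene filter on FPKM
#'
#' A gene is kept when (a) it has non-zero FPKM in at least
#' `min_nonzero_fraction` of the samples of the case group OR of the
#' control group (with a 5v5 design and the default fraction this is the
#' "n >= 3 in either group" rule), and (b) the maximum of its non-zero
#' FPKM values exceeds `max_fpkm_cutoff`. Row order is preserved.
#'
#' @param fpkm Numeric matrix, genes x samples, gene-id rownames.
#' @param groups Named character vector (`"case"`/`"control"`) for the
#'   columns of `fpkm`.
#' @param min_nonzero_fraction Required fraction of non-zero samples
#'   within a group (rounded up).
#' @param max_fpkm_cutoff Threshold the per-gene maximum non-zero FPKM
#'   must exceed (strictly).
#'
#' @return Character vector of kept gene ids, in input order.
#' @export
filter_expressed <- function(fpkm, groups, min_nonzero_fraction = 0.5,
                             max_fpkm_cutoff = 1) {
  groups <- groups[colnames(fpkm)]
  case <- which(groups == "case")
  ctrl <- which(groups == "control")
  if (length(case) == 0 || length(ctrl) == 0) {
    stop("both groups must be non-empty")
  }
  nz <- fpkm > 0
  enough_case <- rowSums(nz[, case, drop = FALSE]) >=
    ceiling(min_nonzero_fraction * length(case))
  enough_ctrl <- rowSums(nz[, ctrl, drop = FALSE]) >=
    ceiling(min_nonzero_fraction * length(ctrl))
  # all values are >= 0, so the overall row maximum equals the maximum
  # over non-zero entries whenever any entry is non-zero
  max_nonzero <- apply(fpkm, 1, max)
  keep <- (enough_case | enough_ctrl) & (max_nonzero > max_fpkm_cutoff)
  rownames(fpkm)[keep]
}

# Weighted trimmed mean of M-values for one sample against the reference.
# M = log2 ratio of library-scaled proportions, A = average log2
# abundance; genes with a zero in either sample are excluded, both tails
# of M and A are trimmed, and the surviving M-values are averaged with
# inverse asymptotic-variance (delta-method binomial) weights.
.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]
  ref <- ref[pos]
  log_r <- log2((obs / n_obs) / (ref / n_ref))
  abs_e <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  n <- length(log_r)
  if (n == 0 || max(abs(log_r)) < 1e-6) return(1)
  lo_l <- floor(n * trim_m) + 1
  hi_l <- n + 1 - lo_l
  lo_s <- floor(n * trim_a) + 1
  hi_s <- n + 1 - lo_s
  r_l <- rank(log_r)
  r_s <- rank(abs_e)
  keep <- r_l >= lo_l & r_l <= hi_l & r_s >= lo_s & r_s <= hi_s
  if (!any(keep)) return(1)
  2^(sum(log_r[keep] / v[keep]) / sum(1 / v[keep]))
}

#' TMM scaling factors
#'
#' Trimmed mean of M-values between-sample scaling. For each sample vs a
#' reference, per-gene log-ratios of library-scaled proportions (M) and
#' average log-abundances (A) are computed over genes non-zero in both;
#' the upper and lower `trim_m` tails of M and `trim_a` tails of A are
#' discarded; the remaining M-values are averaged with inverse
#' asymptotic-variance weights; factors are rescaled to geometric mean 1.
#' The reference is the sample whose upper-quartile count (scaled by
#' library size) is closest to the mean upper-quartile.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param trim_m Two-sided trim fraction on M-values.
#' @param trim_a Two-sided trim fraction on A-values.
#' @param ref_sample Optional reference column name or index; default
#'   picks the upper-quartile-closest-to-mean sample.
#'
#' @return A data.frame of class `norm_factors` with columns `sample_id`,
#'   `library_size`, `tmm_factor`, `effective_size`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        ref_sample = NULL) {
  stopifnot(ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- if (is.null(ref_sample)) {
    which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    match(ref_sample, colnames(counts))
  } else {
    as.integer(ref_sample)
  }
  if (is.na(ref) || ref < 1 || ref > ncol(counts)) {
    stop("invalid reference sample")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(
    data.frame(
      sample_id = colnames(counts),
      library_size = unname(lib),
      tmm_factor = unname(f),
      effective_size = unname(lib * f),
      stringsAsFactors = FALSE
    ),
    class = c("norm_factors", "data.frame"),
    reference = colnames(counts)[ref]
  )
}

#' Scaled log2 transform of counts
#'
#' Divides each sample's counts by its TMM factor and applies
#' `log2(. + 1)`. Residual depth differences are removed by the
#' subsequent [quantile_normalize()] step.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors A `norm_factors` table from [tmm_factors()] covering
#'   exactly the samples of `counts`.
#'
#' @return Numeric matrix of log2-scale values.
#' @export
log_transform <- function(counts, factors) {
  if (!setequal(colnames(counts), factors$sample_id)) {
    stop("factors do not match the samples of the count matrix")
  }
  f <- stats::setNames(factors$tmm_factor, factors$sample_id)[colnames(counts)]
  log2(sweep(counts, 2, f, "/") + 1)
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical distribution: each column's
#' sorted values are replaced by the cross-sample means of the sorted
#' values at each rank; ties receive the mean of their tied rank-means.
#' Delegates to [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix without missing values.
#' @return Matrix of the same shape; the sorted value vector is identical
#'   across columns.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("matrix must not contain missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Full normalization cascade for one cohort
#'
#' Runs the pipeline in its fixed order: expressed-gene filter on the
#' FPKM universe, TMM factors on the counts of retained genes, scaled
#' `log2(count + 1)`, then quantile normalization. Genes present in only
#' one of the two matrices are an error, not a silent drop.
#'
#' @param counts Count matrix, genes x samples.
#' @param fpkm FPKM matrix over the same genes and samples.
#' @param groups Named `"case"`/`"control"` vector for the samples.
#' @inheritParams filter_expressed
#' @inheritParams tmm_factors
#'
#' @return List with `matrix` (normalized log2 matrix over kept genes),
#'   `factors` (the `norm_factors` table) and `kept_genes`.
#' @export
normalize_cohort <- function(counts, fpkm, groups, min_nonzero_fraction = 0.5,
                             max_fpkm_cutoff = 1, trim_m = 0.30,
                             trim_a = 0.05) {
  if (!setequal(rownames(counts), rownames(fpkm))) {
    only <- c(setdiff(rownames(counts), rownames(fpkm)),
              setdiff(rownames(fpkm), rownames(counts)))
    stop("genes present in only one matrix: ",
         paste(utils::head(only, 5), collapse = ", "))
  }
  keep <- filter_expressed(fpkm, groups, min_nonzero_fraction, max_fpkm_cutoff)
  kept_counts <- counts[keep, , drop = FALSE]
  factors <- tmm_factors(kept_counts, trim_m = trim_m, trim_a = trim_a)
  logged <- log_transform(kept_counts, factors)
  list(matrix = quantile_normalize(logged), factors = factors,
       kept_genes = keep)
}
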