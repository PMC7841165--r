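#' Run the full per-cohort analysis
#'
#' Convenience wrapper chaining the pipeline in its fixed order:
#' expressed-gene filter (FPKM) -> TMM -> log2 -> quantile normalization
#' -> permutation DE test -> direction-stratified gene-set enrichment
#' against the expressed-gene background.
#'
#' @param counts Count matrix, genes x samples.
#' @param fpkm FPKM matrix over the same genes and samples.
#' @param groups Named `"case"`/`"control"` vector.
#' @param gene_sets Optional [gene_set_collection()]; when given, up- and
#'   down-regulated DEG lists are tested separately with [enrich()].
#' @param de_cfg A [de_config()].
#' @param cohort_id Cohort identifier for the returned result.
#' @param alpha,min_count Enrichment thresholds passed to [enrich()].
#' @inheritParams normalize_cohort
#'
#' @return A list with `result` (a [cohort_result()]), `de` (the
#'   `de_result`), `normalized` (output of [normalize_cohort()]).
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_genes = 300, n_per_group = 5, seed = 1))
#' ana <- run_cohort(coh$counts, coh$fpkm, coh$groups,
#'                   de_cfg = de_config(n_permutations = 50, seed = 1))
#' ana$de
run_cohort <- function(counts, fpkm, groups, gene_sets = NULL,
                       de_cfg = de_config(), cohort_id = "cohort1",
                       alpha = 0.05, min_count = 5,
                       min_nonzero_fraction = 0.5, max_fpkm_cutoff = 1,
                       trim_m = 0.30, trim_a = 0.05) {
  norm <- normalize_cohort(counts, fpkm, groups,
                           min_nonzero_fraction = min_nonzero_fraction,
                           max_fpkm_cutoff = max_fpkm_cutoff,
                           trim_m = trim_m, trim_a = trim_a)
  de <- run_de(norm$matrix, groups, de_cfg)
  lists <- deg_lists(de)
  enr_up <- enr_down <- NULL
  if (!is.null(gene_sets)) {
    background <- norm$kept_genes
    enr_up <- enrich(intersect(lists$up, background), background, gene_sets,
                     alpha = alpha, min_count = min_count)
    enr_down <- enrich(intersect(lists$down, background), background,
                       gene_sets, alpha = alpha, min_count = min_count)
  }
  list(
    result = cohort_result(cohort_id, lists$up, lists$down, enr_up, enr_down),
    de = de,
    normalized = norm
  )
}
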