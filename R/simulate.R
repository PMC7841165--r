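#' Simulation configuration for one synthetic cohort
#'
#' Bundles the parameters of the negative-binomial count generator. The
#' defaults describe the study design the pipeline targets: a small
#' whole-blood cohort of 5 cases vs 5 controls with roughly 10% of genes
#' differentially expressed at |log2FC| = 1.
#'
#' @param n_genes Number of genes in the simulated universe.
#' @param n_per_group Samples per group (cases = controls).
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed, in `[0, 1)`. Split evenly between up and down.
#' @param effect_log2fc Planted absolute log2 fold-change (case vs
#'   control); non-negative.
#' @param dispersion Negative-binomial dispersion `phi`
#'   (`Var = mu + phi * mu^2`), constant across genes.
#' @param mean_library_size Expected total counts per sample.
#' @param seed Integer seed; identical configs give identical cohorts.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 7)
sim_config <- function(n_genes = 2000, n_per_group = 5, de_fraction = 0.1,
                       effect_log2fc = 1, dispersion = 0.1,
                       mean_library_size = 1e6, seed = 1L) {
  stopifnot(
    length(n_genes) == 1, n_genes >= 1,
    length(n_per_group) == 1, n_per_group >= 1,
    length(de_fraction) == 1, de_fraction >= 0, de_fraction < 1,
    length(effect_log2fc) == 1, effect_log2fc >= 0,
    length(dispersion) == 1, dispersion > 0,
    length(mean_library_size) == 1, mean_library_size > 0,
    length(seed) == 1, is.finite(seed)
  )
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_per_group = as.integer(n_per_group),
      de_fraction = de_fraction,
      effect_log2fc = effect_log2fc,
      dispersion = dispersion,
      mean_library_size = mean_library_size,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d genes, %d vs %d samples, %.1f%% DE at |log2FC| = %g, phi = %g, seed = %d\n",
    x$n_genes, x$n_per_group, x$n_per_group, 100 * x$de_fraction,
    x$effect_log2fc, x$dispersion, x$seed
  ))
  invisible(x)
}

.sim_gene_ids <- function(n_genes) sprintf("G%05d", seq_len(n_genes))

# Draw counts for a cohort given planted truth. Assumes the RNG state has
# already been seeded by the caller; baseline abundances and library sizes
# come from the same stream so one seed fixes the whole cohort.
.simulate_counts <- function(cfg, up, down) {
  n_genes <- cfg$n_genes
  n <- cfg$n_per_group
  genes <- .sim_gene_ids(n_genes)

  # Wide log-normal baseline so low-abundance genes exist and the FPKM
  # expressed-gene filter has something to remove.
  q <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
  q <- q / sum(q)
  lengths_kb <- stats::runif(n_genes, 0.5, 10)
  lib <- stats::rlnorm(2 * n, meanlog = log(cfg$mean_library_size) - 0.02,
                       sdlog = 0.2)

  # Symmetric split of the effect keeps library totals balanced.
  delta <- numeric(n_genes)
  names(delta) <- genes
  delta[up] <- cfg$effect_log2fc
  delta[down] <- -cfg$effect_log2fc
  mu_case <- q * 2^(delta / 2)
  mu_ctrl <- q * 2^(-delta / 2)

  samples <- c(sprintf("case_%d", seq_len(n)), sprintf("control_%d", seq_len(n)))
  groups <- stats::setNames(rep(c("case", "control"), each = n), samples)
  mu <- cbind(
    outer(mu_case, lib[seq_len(n)]),
    outer(mu_ctrl, lib[n + seq_len(n)])
  )
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
    nrow = n_genes, dimnames = list(genes, samples)
  )

  mapped_millions <- pmax(colSums(counts), 1) / 1e6
  fpkm <- sweep(counts / lengths_kb, 2, mapped_millions, "/")

  list(counts = counts, fpkm = fpkm, gene_lengths_kb = stats::setNames(lengths_kb, genes),
       groups = groups)
}

.new_sim_cohort <- function(parts, cfg, up, down, planted_term = NA_character_) {
  structure(
    list(
      counts = parts$counts, fpkm = parts$fpkm,
      gene_lengths_kb = parts$gene_lengths_kb, groups = parts$groups,
      truth = list(de_genes_up = up, de_genes_down = down,
                   planted_term = planted_term),
      config = cfg
    ),
    class = "sim_cohort"
  )
}

#' Simulate one two-group RNA-seq cohort
#'
#' Draws gene-level counts from a negative-binomial model
#' `count ~ NB(mean = lib * q_g * 2^(+/- effect/2), dispersion = phi)` with
#' log-normal baseline abundances `q_g`, converts them to FPKM using
#' simulated gene lengths (`FPKM = count / (length_kb * mapped_millions)`),
#' and records which genes carry the planted effect.
#'
#' @param cfg A [sim_config()].
#'
#' @return A `sim_cohort` list with elements `counts` (integer matrix,
#'   genes x samples), `fpkm`, `gene_lengths_kb`, `groups` (named vector of
#'   `"case"`/`"control"`), `truth` (`de_genes_up`, `de_genes_down`,
#'   `planted_term`) and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_genes = 300, seed = 1))
#' table(coh$groups)
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- .sim_gene_ids(cfg$n_genes)

  n_de <- round(cfg$de_fraction * cfg$n_genes)
  if (cfg$de_fraction > 0 && cfg$effect_log2fc > 0 && n_de < 1) {
    warning("de_fraction * n_genes rounds to zero; no genes planted")
  }
  up <- character(0)
  down <- character(0)
  if (n_de >= 1 && cfg$effect_log2fc > 0) {
    de <- sample(genes, n_de)
    n_up <- ceiling(n_de / 2)
    up <- sort(de[seq_len(n_up)])
    down <- sort(de[setdiff(seq_len(n_de), seq_len(n_up))])
  }
  parts <- .simulate_counts(cfg, up, down)
  .new_sim_cohort(parts, cfg, up, down)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d genes x %d samples; planted %d up / %d down%s\n",
    nrow(x$counts), ncol(x$counts),
    length(x$truth$de_genes_up), length(x$truth$de_genes_down),
    if (is.na(x$truth$planted_term)) "" else
      sprintf("; planted term %s", x$truth$planted_term)
  ))
  invisible(x)
}

#' Simulate several cohorts sharing one enriched annotation term
#'
#' Emulates the heterogeneity structure in which cohorts agree at the
#' pathway level but barely at the gene level: every cohort's planted
#' up-regulated genes are drawn from the membership of one shared
#' annotation term, with pairwise gene-identity overlap controlled by
#' `overlap_fraction` (a common core of `round(overlap_fraction *
#' min(n_up))` genes shared by all cohorts, remainders disjoint).
#' Down-regulated genes are planted outside the term with the same core
#' scheme. Decoy terms of the same size are sampled without regard to DE
#' status so enrichment nulls hold.
#'
#' @param cfgs List of [sim_config()] (>= 2, equal `n_genes`); give each a
#'   distinct seed.
#' @param shared_term_size Number of genes in the shared term.
#' @param overlap_fraction Target pairwise overlap of planted up-gene
#'   sets, in `[0, 1]`.
#' @param n_decoy_terms Number of size-matched decoy terms.
#'
#' @return A list with `cohorts` (list of `sim_cohort`, each with
#'   `truth$planted_term` set) and `gene_sets` (a
#'   [gene_set_collection()] containing the shared term `SET_SHARED` plus
#'   decoys).
#' @export
simulate_multi_cohort <- function(cfgs, shared_term_size = 300,
                                  overlap_fraction = 0.05,
                                  n_decoy_terms = 30) {
  stopifnot(is.list(cfgs), length(cfgs) >= 2,
            all(vapply(cfgs, inherits, logical(1), "sim_config")),
            overlap_fraction >= 0, overlap_fraction <= 1,
            shared_term_size >= 1, n_decoy_terms >= 0)
  n_genes <- unique(vapply(cfgs, `[[`, integer(1), "n_genes"))
  if (length(n_genes) != 1) {
    stop("all cohorts must share one gene universe (equal n_genes)")
  }
  universe <- .sim_gene_ids(n_genes)

  n_de <- vapply(cfgs, function(cf) round(cf$de_fraction * cf$n_genes), numeric(1))
  n_up <- ceiling(n_de / 2)
  n_dn <- n_de - n_up
  if (shared_term_size < max(n_up)) {
    stop(sprintf(
      "shared_term_size (%d) is smaller than the largest per-cohort DE count (%d)",
      shared_term_size, max(n_up)
    ))
  }

  set.seed(cfgs[[1]]$seed)
  term <- sort(sample(universe, shared_term_size))

  draw_sets <- function(pool, sizes, frac, what) {
    core_n <- round(frac * min(sizes))
    core <- sample(pool, core_n)
    avail <- setdiff(pool, core)
    out <- vector("list", length(sizes))
    for (i in seq_along(sizes)) {
      need <- sizes[i] - core_n
      if (need > length(avail)) {
        stop(sprintf(
          "%s pool too small to plant disjoint gene sets at overlap_fraction = %g",
          what, frac
        ))
      }
      extra <- if (need > 0) sample(avail, need) else character(0)
      avail <- setdiff(avail, extra)
      out[[i]] <- sort(c(core, extra))
    }
    out
  }
  ups <- draw_sets(term, n_up, overlap_fraction, "shared term")
  downs <- draw_sets(setdiff(universe, term), n_dn, overlap_fraction,
                     "off-term")

  members <- list(SET_SHARED = term)
  descriptions <- c(SET_SHARED = "planted shared process (lymphocyte activation-like)")
  if (n_decoy_terms > 0) {
    for (i in seq_len(n_decoy_terms)) {
      id <- sprintf("SET_%03d", i)
      members[[id]] <- sort(sample(universe, shared_term_size))
      descriptions[[id]] <- sprintf("decoy process %d", i)
    }
  }
  gene_sets <- gene_set_collection(members, descriptions)

  cohorts <- vector("list", length(cfgs))
  for (i in seq_along(cfgs)) {
    set.seed(cfgs[[i]]$seed)
    parts <- .simulate_counts(cfgs[[i]], ups[[i]], downs[[i]])
    cohorts[[i]] <- .new_sim_cohort(parts, cfgs[[i]], ups[[i]], downs[[i]],
                                    planted_term = "SET_SHARED")
  }
  names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  list(cohorts = cohorts, gene_sets = gene_sets)
}

#' Simulate a random gene-set annotation
#'
#' @param n_terms Number of terms.
#' @param size_range Length-2 integer range of term sizes (inclusive).
#' @param universe Character vector of gene ids to draw members from.
#' @param seed Optional seed.
#'
#' @return A [gene_set_collection()].
#' @export
simulate_go_annotation <- function(n_terms, size_range = c(10, 100), universe,
                                   seed = NULL) {
  stopifnot(n_terms >= 0, length(size_range) == 2, size_range[1] >= 1,
            size_range[1] <= size_range[2])
  if (length(universe) == 0) stop("universe must be non-empty")
  if (size_range[2] > length(universe)) {
    stop("size_range exceeds the universe size")
  }
  if (!is.null(seed)) set.seed(seed)
  members <- list()
  descriptions <- character(0)
  if (n_terms > 0) {
    sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
    for (i in seq_len(n_terms)) {
      id <- sprintf("SET_%03d", i)
      members[[id]] <- sort(sample(universe, sizes[i]))
      descriptions[[id]] <- sprintf("simulated process %d", i)
    }
  }
  gene_set_collection(members, descriptions)
}

#' Simulate a qPCR plate with a planted group shift
#'
#' Generates per-sample target and reference cycle-threshold (CT) values
#' for a case/control plate. The case group's delta-CT
#' (`CT_target - CT_reference`) mean is shifted by `-group_delta_ct`
#' cycles (lower CT means higher expression, so a positive
#' `group_delta_ct` plants up-regulation with relative quantity
#' `2^group_delta_ct`). Gaussian noise with sd `noise_sd` is added to the
#' target CT only; the reference CT is held at 20 cycles.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param group_delta_ct Planted case-vs-control shift, in cycles.
#' @param noise_sd Standard deviation of the CT noise (cycles); >= 0.
#' @param seed Integer seed.
#' @param base_delta_ct Baseline delta-CT of the control group (cycles).
#'
#' @return A data.frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`.
#' @export
#' @examples
#' plate <- simulate_qpcr_plate(5, group_delta_ct = 1, noise_sd = 0, seed = 1)
simulate_qpcr_plate <- function(n_per_group, group_delta_ct, noise_sd = 0.3,
                                seed = 1L, base_delta_ct = 5) {
  stopifnot(n_per_group >= 2)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  n <- as.integer(n_per_group)
  group <- rep(c("case", "control"), each = n)
  shift <- ifelse(group == "case", -group_delta_ct, 0)
  data.frame(
    sample_id = c(sprintf("case_%d", seq_len(n)), sprintf("control_%d", seq_len(n))),
    group = group,
    ct_target = 20 + base_delta_ct + shift + stats::rnorm(2 * n, 0, noise_sd),
    ct_reference = rep(20, 2 * n),
    stringsAsFactors = FALSE
  )
}
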