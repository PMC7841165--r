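#' EASE-score and Fisher over-representation p-values
#'
#' One-sided over-representation of `k` query genes in a term of size `K`
#' within a background of `N` genes, query size `n`. `p_fisher` is the
#' upper-tail hypergeometric probability `P(X >= k)`; the EASE score is
#' the same tail with one success removed (`k` replaced by
#' `max(k - 1, 0)`), a deliberately conservative variant that pushes
#' single-gene overlaps to p = 1. Vectorized over its arguments.
#'
#' @param k Overlap count(s).
#' @param K Term size(s) within the background.
#' @param n Query size(s).
#' @param N Background size(s).
#' @return A data.frame with columns `p_ease` and `p_fisher`; always
#'   `p_ease >= p_fisher`.
#' @export
#' @examples
#' ease_test(8, 20, 10, 100)
ease_test <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N | n > N) ||
      any(k > pmin(K, n))) {
    stop("inconsistent margins: need 0 <= k <= min(K, n) <= N")
  }
  p_fisher <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_ease <- stats::phyper(pmax(k - 1, 0) - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(p_ease = p_ease, p_fisher = p_fisher)
}

#' Gene-set over-representation with EASE post-filters
#'
#' Tests each term of a collection for over-representation of the query
#' within the background universe. Term memberships are intersected with
#' the background before testing; terms with no background member are
#' dropped. A term is flagged `enriched` when its EASE p-value is below
#' `alpha` and the overlap count is at least `min_count`. No
#' multiple-testing correction enters the flag; a Benjamini-Hochberg
#' column on the EASE p-values is emitted for information only.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `background`.
#' @param background Character vector: the testing universe (typically
#'   the expressed genes from [filter_expressed()]).
#' @param sets A [gene_set_collection()].
#' @param alpha EASE p-value threshold for the enriched flag.
#' @param min_count Minimum overlap count for the enriched flag.
#'
#' @return A data.frame sorted by `p_ease` (ties by term id) with columns
#'   `term_id`, `name`, `k`, `K`, `n`, `N`, `genes` (comma-collapsed
#'   overlap), `p_ease`, `p_fisher`, `p_bh`, `enriched`.
#' @export
enrich <- function(query, background, sets, alpha = 0.05, min_count = 5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  offenders <- setdiff(query, background)
  if (length(offenders) > 0) {
    stop("query genes absent from background: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  n <- length(query)
  N <- length(background)
  rows <- lapply(sets$ids, function(id) {
    mem <- intersect(sets$members[[id]], background)
    if (length(mem) == 0) return(NULL)
    ov <- intersect(query, mem)
    data.frame(
      term_id = id, name = unname(sets$descriptions[[id]]),
      k = length(ov), K = length(mem), n = n, N = N,
      genes = paste(sort(ov), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), genes = character(0))
  }
  p <- ease_test(out$k, out$K, out$n, out$N)
  out$p_ease <- p$p_ease
  out$p_fisher <- p$p_fisher
  out$p_bh <- stats::p.adjust(out$p_ease, method = "BH")
  out$enriched <- out$p_ease < alpha & out$k >= min_count
  out <- out[order(out$p_ease, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
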