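#' One cohort's DE and enrichment results
#'
#' The per-cohort unit of cross-cohort integration: up/down DEG lists
#' plus direction-stratified enriched-term tables from [enrich()].
#'
#' @param id Cohort identifier.
#' @param up,down Character vectors of up-/down-regulated gene ids
#'   (disjoint).
#' @param enriched_up,enriched_down Optional [enrich()] result tables.
#' @return An object of class `cohort_result`.
#' @export
cohort_result <- function(id, up, down, enriched_up = NULL,
                          enriched_down = NULL) {
  up <- unique(as.character(up))
  down <- unique(as.character(down))
  if (length(intersect(up, down)) > 0) {
    stop("up and down gene lists must be disjoint")
  }
  structure(list(id = id, up = up, down = down, enriched_up = enriched_up,
                 enriched_down = enriched_down),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result '%s': %d up / %d down DEGs", x$id,
              length(x$up), length(x$down)))
  if (!is.null(x$enriched_up)) {
    cat(sprintf("; %d/%d terms enriched (up/down)",
                sum(x$enriched_up$enriched),
                if (is.null(x$enriched_down)) 0 else sum(x$enriched_down$enriched)))
  }
  cat("\n")
  invisible(x)
}

#' Venn region counts for two or more gene lists
#'
#' Exact set arithmetic over `m` de-duplicated lists: every one of the
#' `2^m - 1` exclusive membership regions is counted (including empty
#' regions), labelled by the `&`-joined names of the lists an element
#' belongs to.
#'
#' @param lists Named list of >= 2 character vectors (names default to
#'   `list1`, `list2`, ...).
#' @return A data.frame with columns `region` and `count`; counts sum to
#'   the size of the union.
#' @export
#' @examples
#' venn_overlap(list(a = c("A", "B"), b = c("B", "C")))
venn_overlap <- function(lists) {
  stopifnot(is.list(lists), length(lists) >= 2)
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- sprintf("list%d", seq_along(lists))
  }
  lists <- lapply(lists, function(x) unique(as.character(x)))
  universe <- unique(unlist(lists))
  m <- length(lists)
  membership <- vapply(lists, function(l) universe %in% l,
                       logical(length(universe)))
  if (length(universe) == 0) {
    membership <- matrix(FALSE, 0, m, dimnames = list(NULL, names(lists)))
  }
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))[-1, ,
                                                                drop = FALSE]
  colnames(masks) <- names(lists)
  region <- apply(masks, 1, function(mask) {
    paste(names(lists)[mask], collapse = "&")
  })
  count <- apply(masks, 1, function(mask) {
    if (length(universe) == 0) return(0L)
    sum(apply(membership, 1, function(row) all(row == mask)))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Terms enriched in every cohort
#'
#' The pathway-level integration step: for one direction, the set of
#' term ids whose `enriched` flag (EASE p < alpha and count >= min_count,
#' as set by [enrich()]) is TRUE in every cohort. Sharing is defined on
#' the post-filter flag, not on raw p-values, and term identity is the
#' term-id string.
#'
#' @param results List of >= 2 [cohort_result()] objects with enrichment
#'   computed for `direction`.
#' @param direction `"up"` or `"down"`.
#' @return A list with `shared` (sorted term-id vector) and `presence`
#'   (data.frame of term x cohort with `p_ease` and `enriched`, for every
#'   term enriched in at least one cohort).
#' @export
shared_enriched_terms <- function(results, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.list(results), length(results) >= 2,
            all(vapply(results, inherits, logical(1), "cohort_result")))
  field <- paste0("enriched_", direction)
  tables <- lapply(results, `[[`, field)
  missing <- vapply(tables, is.null, logical(1))
  if (any(missing)) {
    stop("cohort(s) missing enrichment results: ",
         paste(vapply(results[missing], `[[`, character(1), "id"),
               collapse = ", "))
  }
  enriched_ids <- lapply(tables, function(tb) tb$term_id[tb$enriched])
  shared <- sort(Reduce(intersect, enriched_ids))
  any_enriched <- sort(unique(unlist(enriched_ids)))
  presence <- do.call(rbind, lapply(seq_along(results), function(i) {
    tb <- tables[[i]]
    idx <- match(any_enriched, tb$term_id)
    data.frame(
      cohort = results[[i]]$id, term_id = any_enriched,
      p_ease = tb$p_ease[idx],
      enriched = ifelse(is.na(idx), FALSE, tb$enriched[idx]),
      stringsAsFactors = FALSE
    )
  }))
  list(shared = shared, presence = presence)
}

#' Overlap of DEG lists with a reference gene panel
#'
#' Exact intersection of up- and down-regulated DEG lists with an
#' external reference panel (e.g. a published predictor-gene set), split
#' by direction.
#'
#' @param up,down Character vectors of DEG ids.
#' @param reference_panel Non-empty character vector.
#' @return List with `overlap` (sorted union of both intersections),
#'   `up`, `down` (per-direction intersections), `n_up`, `n_down`.
#' @export
overlap_with_reference <- function(up, down, reference_panel) {
  if (length(reference_panel) == 0) stop("reference panel must be non-empty")
  panel <- unique(as.character(reference_panel))
  ov_up <- sort(intersect(unique(up), panel))
  ov_down <- sort(intersect(unique(down), panel))
  list(overlap = sort(union(ov_up, ov_down)), up = ov_up, down = ov_down,
       n_up = length(ov_up), n_down = length(ov_down))
}
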