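#' Gene-set collection
#'
#' A light container for gene-set annotations: a named list of member
#' gene-id vectors plus one description string per term.
#'
#' @param members Named list of character vectors; names are unique term
#'   ids, each member set non-empty (members are de-duplicated).
#' @param descriptions Optional named character vector of term
#'   descriptions; defaults to the ids.
#'
#' @return An object of class `gene_set_collection` with fields `ids`,
#'   `members`, `descriptions`.
#' @export
gene_set_collection <- function(members, descriptions = NULL) {
  stopifnot(is.list(members))
  ids <- names(members)
  if (length(members) > 0 && (is.null(ids) || any(ids == ""))) {
    stop("every term needs an id (list names)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  members <- lapply(members, function(g) unique(as.character(g)))
  if (any(lengths(members) == 0)) {
    stop("member sets must be non-empty")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(ids, ids)
  } else {
    descriptions <- stats::setNames(as.character(descriptions)[match(ids, names(descriptions))], ids)
  }
  structure(list(ids = ids, members = members, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$ids)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms", length(x)))
  if (length(x) > 0) {
    cat(sprintf(", sizes %d-%d", min(lengths(x$members)), max(lengths(x$members))))
  }
  cat("\n")
  invisible(x)
}

.read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

.read_sample_sheet <- function(path) {
  sheet <- .read_tsv(path)
  if (ncol(sheet) < 2) stop("sample sheet needs columns sample_id and group")
  names(sheet)[1:2] <- c("sample_id", "group")
  bad <- setdiff(unique(sheet$group), c("case", "control"))
  if (length(bad) > 0) {
    stop("sample sheet groups must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  sheet
}

.matrix_from_tsv <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("matrix file needs a gene-id column plus samples")
  genes <- as.character(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("matrix values must be numeric")
  rownames(mat) <- genes
  mat
}

#' Read a count matrix and its sample sheet
#'
#' Reads a genes x samples TSV (first column gene ids, header sample ids)
#' and a two-column sample sheet (`sample_id`, `group` in
#' `{case, control}`), validating that counts are non-negative integers,
#' gene ids unique, every sample has a group, and each group has at least
#' two samples.
#'
#' @param path Count matrix TSV.
#' @param sample_sheet_path Sample sheet TSV.
#'
#' @return A list of class `count_matrix` with `counts` (integer matrix)
#'   and `groups` (named character vector).
#' @export
read_count_matrix <- function(path, sample_sheet_path) {
  mat <- .matrix_from_tsv(path)
  bad_na <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(bad_na) > 0) {
    stop(sprintf("missing count at gene %s, sample %s",
                 rownames(mat)[bad_na[1, 1]], colnames(mat)[bad_na[1, 2]]))
  }
  bad_neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(bad_neg) > 0) {
    stop(sprintf("negative count at gene %s, sample %s",
                 rownames(mat)[bad_neg[1, 1]], colnames(mat)[bad_neg[1, 2]]))
  }
  bad_int <- which(abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad_int) > 0) {
    stop(sprintf("non-integer count at gene %s, sample %s",
                 rownames(mat)[bad_int[1, 1]], colnames(mat)[bad_int[1, 2]]))
  }
  storage.mode(mat) <- "integer"
  sheet <- .read_sample_sheet(sample_sheet_path)
  missing <- setdiff(colnames(mat), sheet$sample_id)
  if (length(missing) > 0) {
    stop("samples missing from sample sheet: ", paste(missing, collapse = ", "))
  }
  groups <- stats::setNames(sheet$group, sheet$sample_id)[colnames(mat)]
  if (any(table(groups) < 2)) {
    stop("each group needs at least two samples")
  }
  structure(list(counts = mat, groups = groups), class = "count_matrix")
}

#' Write a count matrix and sample sheet
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param groups Named character vector mapping samples to
#'   `"case"`/`"control"`.
#' @param path Output matrix TSV.
#' @param sample_sheet_path Output sample sheet TSV.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, groups, path, sample_sheet_path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = colnames(counts),
                      group = unname(groups[colnames(counts)]))
  utils::write.table(sheet, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an FPKM matrix
#'
#' @param path Genes x samples TSV, first column gene ids.
#' @return A numeric matrix with gene-id rownames; values must be finite
#'   and non-negative.
#' @export
read_fpkm_matrix <- function(path) {
  mat <- .matrix_from_tsv(path)
  if (any(!is.finite(mat))) stop("FPKM values must be finite")
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  mat
}

#' Write an FPKM (or any numeric gene x sample) matrix
#'
#' @param mat Numeric matrix with gene-id rownames.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_fpkm_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated
#' `id <tab> description <tab> gene1 <tab> gene2 ...`. Duplicate member
#' genes within a term are de-duplicated; duplicate term ids are an
#' error; an empty file gives an empty collection.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop(sprintf("GMT line %d has fewer than 3 tab-separated fields", short[1]))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  descriptions <- stats::setNames(vapply(fields, `[[`, character(1), 2), ids)
  members <- stats::setNames(
    lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])])), ids
  )
  gene_set_collection(members, descriptions)
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_set_collection()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(sets$ids, function(id) {
    paste(c(id, sets$descriptions[[id]], sets$members[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write/read a results table with a provenance header
#'
#' Results tables (DEG records, enriched terms) are written as TSV with a
#' single `#`-prefixed header comment recording free-form `key=value`
#' metadata (e.g. config and seed). `read_results()` refuses files whose
#' first line is not such a comment.
#'
#' @param records A data.frame.
#' @param path Output TSV.
#' @param meta Named character/numeric vector written into the header
#'   comment.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a list with `records` (data.frame) and `meta` (named
#'   character vector).
#' @export
write_results <- function(records, path, meta = c(package = "permpath")) {
  header <- paste0("# ", paste(sprintf("%s=%s", names(meta), as.character(meta)),
                               collapse = "; "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) == 0 || !startsWith(first, "# ")) {
    stop("malformed header: expected a '# key=value; ...' comment line")
  }
  pairs <- strsplit(sub("^# ", "", first), "; ", fixed = TRUE)[[1]]
  kv <- strsplit(pairs, "=", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  records <- utils::read.delim(path, skip = 1, check.names = FALSE,
                               stringsAsFactors = FALSE)
  list(records = records, meta = meta)
}

#' Read/write a qPCR plate table
#'
#' Plate TSVs have columns `sample_id`, `group`, `ct_target`,
#' `ct_reference` (cycles). CT values outside the usual 10-40 cycle range
#' trigger a warning; non-finite values are an error.
#'
#' @param plate A plate data.frame.
#' @param path TSV path.
#' @return `read_qpcr_plate()` returns the validated data.frame.
#' @export
read_qpcr_plate <- function(path) {
  plate <- .read_tsv(path)
  required <- c("sample_id", "group", "ct_target", "ct_reference")
  missing <- setdiff(required, names(plate))
  if (length(missing) > 0) {
    stop("plate is missing columns: ", paste(missing, collapse = ", "))
  }
  ct <- c(plate$ct_target, plate$ct_reference)
  if (any(!is.finite(ct))) stop("CT values must be finite")
  if (any(ct < 10 | ct > 40)) {
    warning("CT values outside the typical 10-40 cycle range")
  }
  plate
}

#' @rdname read_qpcr_plate
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
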