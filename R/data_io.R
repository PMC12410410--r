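#' Read a gene-expression matrix from delimited text
#'
#' Expression files are plain delimited text with genes in rows and samples in
#' columns: the header row holds sample identifiers and the first column holds
#' gene identifiers. Tab and comma delimiters are auto-detected from the file
#' extension (`.csv` implies comma, anything else tab) unless `sep` is given.
#'
#' Gene and sample identifiers are stripped of surrounding whitespace and must
#' be unique; duplicated gene rows are an error rather than being silently
#' collapsed. Every cell must parse as a finite number.
#'
#' @param path Path to the delimited text file.
#' @param cohort_name Cohort label attached to the matrix (used to tag
#'   cohort-level results downstream).
#' @param sep Field separator; `NULL` (default) auto-detects from the file
#'   extension.
#' @return A numeric matrix (genes x samples) with `rownames` = gene IDs,
#'   `colnames` = sample IDs and attribute `cohort_name`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t1\t2", "B\t3\t4"), tf)
#' X <- read_expression(tf, "demo")
#' dim(X)
#' @export
read_expression <- function(path, cohort_name, sep = NULL) {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("empty expression matrix in ", path, call. = FALSE)
  }
  gene_ids <- trimws(raw[[1L]])
  sample_ids <- trimws(colnames(raw)[-1L])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    stop("duplicate sample id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw), ncol = length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or non-finite value at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
         call. = FALSE)
  }
  expression_matrix(vals, cohort_name)
}

#' Construct a validated expression matrix
#'
#' Programmatic counterpart of [read_expression()]: wraps an existing numeric
#' matrix after checking the container invariants (unique, non-empty gene and
#' sample identifiers; finite values).
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   `rownames` and `colnames` set.
#' @param cohort_name Cohort label.
#' @return The matrix with attribute `cohort_name` set.
#' @export
expression_matrix <- function(values, cohort_name) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stop("empty expression matrix", call. = FALSE)
  }
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate gene id", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample id", call. = FALSE)
  if (any(!is.finite(values))) {
    stop("expression values must be finite", call. = FALSE)
  }
  attr(values, "cohort_name") <- as.character(cohort_name)
  values
}

#' @rdname expression_matrix
#' @param X An expression matrix.
#' @export
cohort_name <- function(X) {
  nm <- attr(X, "cohort_name")
  if (is.null(nm)) "unnamed" else nm
}

#' Read per-sample class labels
#'
#' Labels live in a two-column delimited sidecar file (`sample_id`, `class`),
#' separate from the expression matrix.
#'
#' @param path Path to the two-column file (tab- or comma-separated by
#'   extension).
#' @param class_order Optional explicit ordering of class labels; defaults to
#'   order of first appearance in the file. The first class plays the role of
#'   the positive / responder class in binary analyses.
#' @return Named factor: names are sample IDs, levels are the class order.
#' @export
read_labels <- function(path, class_order = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("label file needs columns (sample_id, class)",
                           call. = FALSE)
  ids <- trimws(tab[[1L]])
  cls <- trimws(tab[[2L]])
  label_map(stats::setNames(cls, ids), class_order)
}

#' Construct a validated label map
#'
#' @param labels Named character vector (names = sample IDs) or named factor.
#' @param class_order Optional class-level ordering (first level = positive
#'   class).
#' @return Named factor with `levels` giving the class order.
#' @export
label_map <- function(labels, class_order = NULL) {
  ids <- names(labels)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("labels must be named by unique sample ids", call. = FALSE)
  }
  cls <- as.character(labels)
  if (is.null(class_order)) class_order <- unique(cls)
  if (!all(cls %in% class_order)) {
    stop("label(s) outside class_order: ",
         paste(setdiff(cls, class_order), collapse = ", "), call. = FALSE)
  }
  if (length(class_order) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  stats::setNames(factor(cls, levels = class_order), ids)
}

#' Read a survival sidecar table
#'
#' Three-column delimited file: `sample_id`, `time` (non-negative, in the
#' study's unit, typically days or months) and `event` (1 = death or
#' progression, 0 = censored).
#'
#' @param path Path to the file.
#' @return `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  if (ncol(tab) < 3L) {
    stop("survival file needs columns (sample_id, time, event)", call. = FALSE)
  }
  out <- data.frame(sample_id = trimws(as.character(tab[[1L]])),
                    time = as.numeric(tab[[2L]]),
                    event = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  survival_table(out)
}

#' @rdname read_survival
#' @param surv `data.frame` with columns `sample_id`, `time`, `event`.
#' @export
survival_table <- function(surv) {
  stopifnot(is.data.frame(surv),
            all(c("sample_id", "time", "event") %in% names(surv)))
  if (anyDuplicated(surv$sample_id)) {
    stop("duplicate sample id in survival table", call. = FALSE)
  }
  if (any(!is.finite(surv$time)) || any(surv$time < 0)) {
    stop("survival time must be finite and >= 0", call. = FALSE)
  }
  if (!all(surv$event %in% c(0L, 1L))) {
    stop("survival event must be 0 or 1", call. = FALSE)
  }
  surv
}

#' Read a gene whitelist (one symbol per line)
#'
#' @param path Path to a text file with one gene symbol per line; whitespace
#'   is stripped, blank lines ignored.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Intersect cohorts on shared genes
#'
#' Restricts every cohort to the genes common to all cohorts (optionally
#' further intersected with a whitelist such as a disease-associated gene
#' list). The order of `shared_genes` follows the gene order of the first
#' cohort, which fixes the canonical pair indexing deterministically across
#' runs. Gene matching is exact string match after whitespace stripping; no
#' symbol-alias resolution is attempted.
#'
#' @param cohorts List of expression matrices (see [expression_matrix()]);
#'   names default to each matrix's `cohort_name`.
#' @param whitelist Optional character vector of gene IDs to intersect with.
#' @param roles Optional named character vector mapping cohort names to roles
#'   `"discovery"`, `"training"` or `"test"`.
#' @return An object of class `cohort_set`: list with `cohorts` (subset and
#'   reordered matrices), `shared_genes`, and `roles`.
#' @export
intersect_genes <- function(cohorts, whitelist = NULL, roles = NULL) {
  if (length(cohorts) < 1L) stop("need at least one cohort", call. = FALSE)
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- vapply(cohorts, cohort_name, character(1L))
  }
  if (anyDuplicated(names(cohorts))) {
    stop("duplicate cohort names", call. = FALSE)
  }
  shared <- rownames(cohorts[[1L]])
  for (co in cohorts[-1L]) shared <- shared[shared %in% rownames(co)]
  if (!is.null(whitelist)) shared <- shared[shared %in% trimws(whitelist)]
  if (length(shared) == 0L) stop("empty gene intersection", call. = FALSE)
  out <- lapply(cohorts, function(co) {
    sub <- co[shared, , drop = FALSE]
    attr(sub, "cohort_name") <- cohort_name(co)
    sub
  })
  if (!is.null(roles)) {
    bad <- setdiff(names(cohorts), names(roles))
    if (length(bad) > 0L) {
      stop("no role assigned for cohort(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!all(roles[names(cohorts)] %in% c("discovery", "training", "test"))) {
      stop("roles must be one of discovery/training/test", call. = FALSE)
    }
    roles <- roles[names(cohorts)]
  }
  structure(list(cohorts = out, shared_genes = shared, roles = roles),
            class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("cohort_set:", length(x$cohorts), "cohort(s),",
      length(x$shared_genes), "shared genes\n")
  for (nm in names(x$cohorts)) {
    role <- if (is.null(x$roles)) "" else paste0(" [", x$roles[[nm]], "]")
    cat("  ", nm, ": ", ncol(x$cohorts[[nm]]), " samples", role, "\n", sep = "")
  }
  invisible(x)
}
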