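#' Per-gene sample standard deviations
#'
#' Computes, for every gene, the sample standard deviation across all samples
#' of the cohort, i.e. `S_i = sqrt( sum_k (G_ik - mean_i)^2 / (n - 1) )`.
#' These feed the per-pair adaptive difference threshold `a * sqrt(S_i^2 +
#' S_j^2)`.
#'
#' @param X Expression matrix (genes x samples), at least 2 samples.
#' @return List of class `gene_stats`: `sd` (named numeric per gene), `n`
#'   (sample count) and `cohort` (source cohort name).
#' @export
gene_stddev <- function(X) {
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 samples to estimate variance", call. = FALSE)
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (n - 1L))
  structure(list(sd = stats::setNames(s, rownames(X)), n = n,
                 cohort = cohort_name(X)),
            class = "gene_stats")
}

#' Welch-Satterthwaite degrees of freedom for a gene pair
#'
#' `nu = (n - 1) * (S_i^2 + S_j^2)^2 / (S_i^4 + S_j^4)`. This is the degrees
#' of freedom of the approximate t distribution of the within-sample
#' difference of two genes with unequal variances; it underpins the
#' interpretation of the adaptive coefficient `a` as a t-quantile. Limiting
#' cases: equal variances give `2 * (n - 1)`; one zero variance gives
#' `n - 1`. Both variances zero leaves the distribution undefined and is an
#' error.
#'
#' @param s_i,s_j Per-gene sample standard deviations (vectorized).
#' @param n Sample count the standard deviations were computed on.
#' @return Numeric vector of degrees of freedom.
#' @export
welch_df <- function(s_i, s_j, n) {
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  v <- s_i^2 + s_j^2
  if (any(v == 0)) {
    stop("welch_df undefined when both variances are zero", call. = FALSE)
  }
  (n - 1) * v^2 / (s_i^4 + s_j^4)
}

#' Canonical gene-pair index
#'
#' Maps an ordered gene pair `(i, j)` with `1 <= i < j <= m` to its 1-based
#' rank `l = [sum_{b=1}^{i-1} (m - b)] + j - i` in the canonical lexicographic
#' enumeration of all `choose(m, 2)` pairs, and back. The mapping is a
#' bijection onto `1..choose(m, 2)`.
#'
#' @param i,j 1-based gene ranks with `i < j` (vectorized).
#' @param m Total number of genes.
#' @return `pair_index`: integer pair rank(s). `pair_from_index`: a
#'   two-column integer matrix with columns `i`, `j`.
#' @examples
#' pair_index(1, 2, 5)   # 1
#' pair_index(4, 5, 5)   # 10 == choose(5, 2)
#' pair_from_index(10, 5)
#' @export
pair_index <- function(i, j, m) {
  i <- as.numeric(i); j <- as.numeric(j)
  if (any(i < 1 | j <= i | j > m)) {
    stop("pair index requires 1 <= i < j <= m", call. = FALSE)
  }
  (i - 1) * m - i * (i - 1) / 2 + (j - i)
}

#' @rdname pair_index
#' @param l 1-based pair rank(s) in `1..choose(m, 2)`.
#' @export
pair_from_index <- function(l, m) {
  l <- as.numeric(l)
  if (any(l < 1 | l > m * (m - 1) / 2)) {
    stop("pair rank out of range 1..choose(m,2)", call. = FALSE)
  }
  # offset(i) = (i-1)*m - (i-1)*i/2 is the number of pairs with first index
  # < i; solve offset(i) < l <= offset(i+1) via the quadratic root, then fix
  # rounding locally.
  i <- floor(m + 0.5 - sqrt((m - 0.5)^2 - 2 * (l - 1)))
  offset <- function(i) (i - 1) * m - (i - 1) * i / 2
  i <- ifelse(offset(i) >= l, i - 1, i)
  i <- ifelse(offset(i + 1) < l, i + 1, i)
  j <- l - offset(i) + i
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Ternary adaptive pair coding
#'
#' Codes the relation of two genes within one sample against the pair's
#' adaptive difference threshold: `+1` if `g_i - g_j > a * sqrt(S_i^2 +
#' S_j^2)`, `-1` if `g_j - g_i` exceeds the same threshold, `0` otherwise.
#' The inequality is strict, so a difference exactly equal to the threshold
#' codes 0. With `a = 0` (and at least one positive variance) this reduces to
#' the sign of the difference; for a zero-variance pair the threshold is 0
#' and the coding falls back to a strict sign comparison, keeping the
#' transform total.
#'
#' @param g_i,g_j Expression values of the two genes (vectorized).
#' @param s_i,s_j Per-gene sample standard deviations.
#' @param a Non-negative adaptive coefficient.
#' @return Integer vector in `{-1, 0, 1}`.
#' @export
ternary_code <- function(g_i, g_j, s_i, s_j, a) {
  if (a < 0) stop("adaptive coefficient a must be >= 0", call. = FALSE)
  thr <- a * sqrt(s_i^2 + s_j^2)
  d <- g_i - g_j
  (d > thr) - (-d > thr)
}

all_pairs <- function(m) {
  # canonical enumeration: i ascending, j ascending within i
  i <- rep.int(seq_len(m - 1L), (m - 1L):1L)
  j <- sequence((m - 1L):1L) + i
  cbind(i = i, j = j)
}

resolve_pairs <- function(X, pairs) {
  genes <- rownames(X)
  if (is.null(pairs)) {
    idx <- all_pairs(nrow(X))
  } else if (is.data.frame(pairs)) {
    idx <- resolve_pairs(X, cbind(as.character(pairs$gene_a),
                                  as.character(pairs$gene_b)))
    return(idx)
  } else if (is.character(pairs) && !is.matrix(pairs)) {
    idx <- resolve_pairs(X, matrix(pairs, ncol = 2L))
    return(idx)
  } else if (is.matrix(pairs) && is.character(pairs[1L])) {
    missing <- setdiff(unique(c(pairs)), genes)
    if (length(missing) > 0L) {
      stop("gene(s) absent from expression matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    idx <- cbind(i = match(pairs[, 1L], genes), j = match(pairs[, 2L], genes))
  } else {
    idx <- cbind(i = as.integer(pairs[, 1L]), j = as.integer(pairs[, 2L]))
    if (any(idx < 1L | idx > nrow(X))) {
      stop("pair gene index out of range", call. = FALSE)
    }
  }
  idx
}

#' Build the ternary gene-pair matrix
#'
#' Applies [ternary_code()] to every requested gene pair in every sample,
#' producing the pairs x samples ternary matrix. By default all
#' `choose(m, 2)` pairs in canonical order are coded; a subset of pairs (by
#' gene name or index) can be requested, e.g. to featurize a cohort on a
#' fixed signature. Evaluation is chunked over blocks of pairs so peak memory
#' is bounded by `block_size`; the block decomposition is an implementation
#' detail and does not change the result.
#'
#' @param X Expression matrix (genes x samples).
#' @param a Non-negative adaptive coefficient.
#' @param stats Optional `gene_stats` (see [gene_stddev()]); defaults to
#'   statistics computed on `X` itself (per-cohort variance provenance). Pass
#'   statistics frozen from a training cohort for single-sample deployment.
#' @param pairs Optional pair subset: two-column matrix/data.frame of gene
#'   names (`gene_a`, `gene_b`) or of integer gene ranks. `NULL` = all pairs.
#' @param block_size Number of pairs coded per block (default 65536).
#' @return Object of class `pair_matrix`: list with integer `values`
#'   (pairs x samples, entries in -1/0/1), `pairs` (data.frame `l`, `i`, `j`,
#'   `gene_a`, `gene_b`), `a`, `gene_order`, `cohort`.
#' @export
build_pair_matrix <- function(X, a, stats = NULL, pairs = NULL,
                              block_size = 65536L) {
  if (a < 0) stop("adaptive coefficient a must be >= 0", call. = FALSE)
  if (is.null(stats)) stats <- gene_stddev(X)
  sds <- stats$sd[rownames(X)]
  if (any(is.na(sds))) {
    stop("gene_stats missing genes: ",
         paste(rownames(X)[is.na(sds)][1:5], collapse = ", "), call. = FALSE)
  }
  idx <- resolve_pairs(X, pairs)
  np <- nrow(idx)
  genes <- rownames(X)
  vals <- matrix(0L, nrow = np, ncol = ncol(X))
  colnames(vals) <- colnames(X)
  thr_all <- a * sqrt(sds[idx[, 1L]]^2 + sds[idx[, 2L]]^2)
  for (start in seq(1L, np, by = block_size)) {
    end <- min(start + block_size - 1L, np)
    blk <- start:end
    D <- X[idx[blk, 1L], , drop = FALSE] - X[idx[blk, 2L], , drop = FALSE]
    thr <- thr_all[blk]
    vals[blk, ] <- (D > thr) - (-D > thr)
  }
  pair_df <- data.frame(
    l = if (is.null(pairs)) pair_index(idx[, 1L], idx[, 2L], nrow(X))
        else seq_len(np),
    i = idx[, 1L], j = idx[, 2L],
    gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]],
    stringsAsFactors = FALSE)
  rownames(vals) <- paste(pair_df$gene_a, pair_df$gene_b, sep = "|")
  structure(list(values = vals, pairs = pair_df, a = a,
                 gene_order = genes, cohort = cohort_name(X)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat("pair_matrix:", nrow(x$values), "pairs x", ncol(x$values),
      "samples (a =", x$a, ")\n")
  invisible(x)
}

#' Dump a pair matrix to delimited text
#'
#' Writes columns (`pair_id`, `gene_a`, `gene_b`, then one ternary column per
#' sample).
#'
#' @param P `pair_matrix` from [build_pair_matrix()].
#' @param path Output TSV path.
#' @export
write_pair_matrix <- function(P, path) {
  out <- data.frame(pair_id = P$pairs$l, gene_a = P$pairs$gene_a,
                    gene_b = P$pairs$gene_b, P$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
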