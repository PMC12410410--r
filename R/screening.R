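#' Contingency table of a ternary pair row across classes
#'
#' Counts, per class, the samples coded `+1` (first row) and `-1` (second
#' row); samples coded `0` are excluded from the table and hence from its
#' total `N`.
#'
#' @param pair_row Integer vector in `{-1, 0, 1}`, one entry per sample. If
#'   named, entries are matched to labels by sample ID; otherwise positional
#'   order against `labels` is assumed.
#' @param labels Named factor of class labels (see [label_map()]).
#' @return Integer matrix 2 x z with rownames `c("+1", "-1")` and one column
#'   per class, attribute `N` = sum of all cells.
#' @export
contingency <- function(pair_row, labels) {
  if (!is.null(names(pair_row))) {
    missing <- setdiff(names(pair_row), names(labels))
    if (length(missing) > 0L) {
      stop("unlabeled sample(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    lab <- labels[names(pair_row)]
  } else {
    if (length(pair_row) != length(labels)) {
      stop("pair row and labels differ in length", call. = FALSE)
    }
    lab <- labels
  }
  lev <- levels(lab)
  tab <- rbind(
    `+1` = vapply(lev, function(cl) sum(pair_row == 1L & lab == cl), 0L),
    `-1` = vapply(lev, function(cl) sum(pair_row == -1L & lab == cl), 0L))
  attr(tab, "N") <- sum(tab)
  tab
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The p-value is the sum, over all tables sharing the observed margins, of
#' the hypergeometric point probabilities not exceeding that of the observed
#' table (with the standard `1 + 1e-7` relative guard against floating-point
#' ties). Degenerate margins (any zero row or column total) give `p = 1` by
#' convention, which keeps uninformative pairs at the bottom of the ranking
#' instead of erroring mid-scan. One-sided alternatives are available:
#' `"greater"` tests enrichment of `+1` codes in the first class.
#'
#' @param tab 2x2 non-negative integer matrix.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return The p-value.
#' @export
fisher_p <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("fisher_p needs a 2x2 table",
                                        call. = FALSE)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  k_obs <- tab[1L, 1L]
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p <- switch(alternative,
    two.sided = sum(probs[probs <= probs[support == k_obs] * (1 + 1e-7)]),
    greater = sum(probs[support >= k_obs]),
    less = sum(probs[support <= k_obs]))
  min(p, 1)
}

#' Pearson's chi-squared test for a 2 x z contingency table
#'
#' Uses the product-moment form of the statistic,
#' `N * (sum_ij T_ij^2 / (row_i * col_j) - 1)`, algebraically identical to
#' the classical `sum (O - E)^2 / E`, referred to the chi-squared
#' distribution with `z - 1` degrees of freedom (right tail). A zero row or
#' column marginal gives `p = 1` by convention.
#'
#' @param tab 2 x z non-negative integer matrix with positive total.
#' @return List with `statistic` and `p_value`.
#' @export
chisq_p <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2L) stop("chisq_p needs a 2 x z table", call. = FALSE)
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  N <- sum(tab)
  if (N == 0) stop("empty contingency table (N = 0)", call. = FALSE)
  rows <- rowSums(tab); cols <- colSums(tab)
  if (any(rows == 0) || any(cols == 0)) {
    return(list(statistic = NA_real_, p_value = 1))
  }
  stat <- N * (sum(tab^2 / outer(rows, cols)) - 1)
  z <- ncol(tab)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = z - 1, lower.tail = FALSE))
}

screen_from_counts <- function(pos, neg, pair_df, class_order,
                               test, alternative, fdr, a) {
  z <- length(class_order)
  np <- nrow(pair_df)
  N <- rowSums(pos) + rowSums(neg)
  pvals <- numeric(np)
  for (p in seq_len(np)) {
    tab <- rbind(pos[p, ], neg[p, ])
    if (N[p] == 0) {
      pvals[p] <- 1
    } else if (test == "fisher") {
      pvals[p] <- fisher_p(tab, alternative)
    } else {
      pvals[p] <- chisq_p(tab)$p_value
    }
  }
  if (z == 2L) {
    direction <- sign(pos[, 1L] * neg[, 2L] - pos[, 2L] * neg[, 1L])
  } else {
    share1 <- ifelse(pos[, 1L] + neg[, 1L] > 0,
                     pos[, 1L] / (pos[, 1L] + neg[, 1L]), 0.5)
    overall <- ifelse(N > 0, rowSums(pos) / N, 0.5)
    direction <- sign(share1 - overall)
  }
  cnt <- cbind(pos, neg)
  colnames(cnt) <- c(paste0("T1_", class_order), paste0("T2_", class_order))
  res <- data.frame(l = pair_df$l, gene_a = pair_df$gene_a,
                    gene_b = pair_df$gene_b, cnt, N = N,
                    p_value = pvals, direction = as.integer(direction),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (fdr) res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  ord <- order(res$p_value, res$l)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(np)
  rownames(res) <- NULL
  res <- res[, c("rank", setdiff(names(res), "rank"))]
  structure(res, class = c("aigps_screen", "data.frame"),
            test = test, z = z, class_order = class_order, a = a)
}

counts_by_class <- function(values, lab) {
  lev <- levels(lab)
  pos <- sapply(lev, function(cl) {
    cols <- which(lab == cl)
    rowSums(values[, cols, drop = FALSE] == 1L)
  })
  neg <- sapply(lev, function(cl) {
    cols <- which(lab == cl)
    rowSums(values[, cols, drop = FALSE] == -1L)
  })
  if (is.null(dim(pos))) { pos <- rbind(pos); neg <- rbind(neg) }
  list(pos = pos, neg = neg)
}

#' Screen gene pairs for class-dependent reversal
#'
#' Builds the 2 x z contingency table of every pair and computes its
#' p-value: Fisher's exact test when there are two classes, Pearson's
#' chi-squared test otherwise (overridable via `test`). Results are ordered
#' by ascending p-value with ties broken by ascending canonical pair index
#' `l`, making the ranking total and deterministic. Raw p-values are ranked;
#' no multiple-testing correction is applied to the ordering (an optional
#' Benjamini-Hochberg column can be emitted for reporting).
#'
#' @param P A `pair_matrix` from [build_pair_matrix()].
#' @param labels Named factor of class labels covering every sample of `P`.
#' @param test `"auto"` (Fisher for 2 classes, chi-squared for more),
#'   `"fisher"` or `"chisq"`.
#' @param alternative Sidedness for the Fisher test (two-sided default).
#' @param fdr Emit a BH-adjusted column (reporting only)?
#' @return Object of class `aigps_screen`: data.frame with columns `rank`,
#'   `l`, `gene_a`, `gene_b`, the contingency cells `T1_*`/`T2_*`, `N`,
#'   `p_value`, `direction` (+1 = `gene_a > gene_b` enriched in the first
#'   class) and optionally `fdr`.
#' @export
screen <- function(P, labels, test = c("auto", "fisher", "chisq"),
                   alternative = "two.sided", fdr = FALSE) {
  test <- match.arg(test)
  samples <- colnames(P$values)
  missing <- setdiff(samples, names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- droplevels(labels[samples])
  lab <- factor(lab, levels = levels(labels)[levels(labels) %in% levels(lab)])
  z <- nlevels(lab)
  if (z < 2L) stop("need at least 2 classes among screened samples",
                   call. = FALSE)
  if (test == "auto") test <- if (z == 2L) "fisher" else "chisq"
  cc <- counts_by_class(P$values, lab)
  screen_from_counts(cc$pos, cc$neg, P$pairs, levels(lab),
                     test, alternative, fdr, P$a)
}

#' Screen a cohort by streaming pair blocks
#'
#' Equivalent to `screen(build_pair_matrix(X, a), labels)` but never holds
#' the full ternary pair matrix in memory: pairs are coded block by block
#' (ascending canonical index) and only the per-class `+1`/`-1` counts are
#' retained per pair.
#'
#' @inheritParams build_pair_matrix
#' @inheritParams screen
#' @return An `aigps_screen` object (see [screen()]).
#' @export
screen_cohort <- function(X, labels, a, stats = NULL,
                          test = c("auto", "fisher", "chisq"),
                          alternative = "two.sided", fdr = FALSE,
                          block_size = 65536L) {
  test <- match.arg(test)
  missing <- setdiff(colnames(X), names(labels))
  if (length(missing) > 0L) {
    stop("unlabeled sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lab <- droplevels(labels[colnames(X)])
  z <- nlevels(lab)
  if (z < 2L) stop("need at least 2 classes among screened samples",
                   call. = FALSE)
  if (test == "auto") test <- if (z == 2L) "fisher" else "chisq"
  if (is.null(stats)) stats <- gene_stddev(X)
  sds <- stats$sd[rownames(X)]
  m <- nrow(X)
  idx <- all_pairs(m)
  np <- nrow(idx)
  lev <- levels(lab)
  pos <- matrix(0L, np, z); neg <- matrix(0L, np, z)
  thr_all <- a * sqrt(sds[idx[, 1L]]^2 + sds[idx[, 2L]]^2)
  class_cols <- lapply(lev, function(cl) which(lab == cl))
  for (start in seq(1L, np, by = block_size)) {
    end <- min(start + block_size - 1L, np)
    blk <- start:end
    D <- X[idx[blk, 1L], , drop = FALSE] - X[idx[blk, 2L], , drop = FALSE]
    codes <- (D > thr_all[blk]) - (-D > thr_all[blk])
    for (ci in seq_len(z)) {
      sub <- codes[, class_cols[[ci]], drop = FALSE]
      pos[blk, ci] <- rowSums(sub == 1L)
      neg[blk, ci] <- rowSums(sub == -1L)
    }
  }
  genes <- rownames(X)
  pair_df <- data.frame(l = seq_len(np), gene_a = genes[idx[, 1L]],
                        gene_b = genes[idx[, 2L]], stringsAsFactors = FALSE)
  screen_from_counts(pos, neg, pair_df, lev, test, alternative, fdr, a)
}

#' Select the top-ranked screened pairs
#'
#' @param result An `aigps_screen` object.
#' @param x Positive number of pairs to keep (`x <=` number screened).
#' @return The first `x` rows of the deterministic ranking.
#' @export
select_top <- function(result, x) {
  if (length(x) != 1L || is.na(x) || x <= 0) {
    stop("x must be a positive integer", call. = FALSE)
  }
  if (x > nrow(result)) {
    stop("x exceeds the number of screened pairs", call. = FALSE)
  }
  result[seq_len(x), , drop = FALSE]
}

#' Write a screen report TSV
#'
#' @param result An `aigps_screen` object.
#' @param path Output path.
#' @export
write_screen_report <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
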