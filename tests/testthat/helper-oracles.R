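# Independent oracles used across tests.

# Two-sided Fisher p by brute-force enumeration of all tables with the
# observed margins, with point probabilities computed from the factorial
# identity (row1! row2! col1! col2! / (N! T11! T12! T21! T22!)) via lgamma --
# a code path independent of the package's dhyper-based implementation.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  N <- r1 + r2
  point_p <- function(t11) {
    t12 <- r1 - t11; t21 <- c1 - t11; t22 <- r2 - t21
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(N) - lfactorial(t11) - lfactorial(t12) -
          lfactorial(t21) - lfactorial(t22))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, point_p, numeric(1))
  obs <- probs[support == tab[1, 1]]
  min(sum(probs[probs <= obs * (1 + 1e-7)]), 1)
}

# Random non-negative 2 x z contingency table with total about N.
random_table <- function(N, z = 2) {
  p <- runif(2 * z); p <- p / sum(p)
  matrix(as.integer(stats::rmultinom(1, N, p)), nrow = 2)
}

# Classical chi-squared statistic sum (O - E)^2 / E.
chisq_oe <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Tiny deterministic expression fixture: m genes x n samples.
toy_matrix <- function(m = 4, n = 3, seed = 42, cohort = "toy") {
  set.seed(seed)
  vals <- matrix(rnorm(m * n, mean = 5), m, n,
                 dimnames = list(paste0("g", seq_len(m)),
                                 paste0("s", seq_len(n))))
  expression_matrix(vals, cohort)
}

# Separable ternary feature fixture: k pairs that perfectly track the label.
separable_features <- function(n = 30, k = 3, seed = 1) {
  set.seed(seed)
  y <- rep(c("R", "NR"), length.out = n)
  f <- sapply(seq_len(k), function(i) ifelse(y == "R", 1L, -1L))
  colnames(f) <- paste0("gA", seq_len(k), "|gB", seq_len(k))
  rownames(f) <- sprintf("s%02d", seq_len(n))
  list(features = f,
       labels = label_map(setNames(y, rownames(f)), c("R", "NR")))
}

write_expr_tsv <- function(X, path) {
  df <- data.frame(gene = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_labels_tsv <- function(labels, path) {
  write.table(data.frame(sample_id = names(labels),
                         class = as.character(labels)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
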