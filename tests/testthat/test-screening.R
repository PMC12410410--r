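test_that("contingency tables count +1/-1 per class and drop zeros", {
  lab <- label_map(setNames(c("A", "A", "B", "B"), paste0("s", 1:4)),
                   c("A", "B"))
  tab <- contingency(setNames(c(1L, 1L, -1L, 0L), paste0("s", 1:4)), lab)
  expect_equal(unname(tab), rbind(c(2L, 0L), c(0L, 1L)), ignore_attr = TRUE)
  expect_equal(attr(tab, "N"), 3L)

  tab0 <- contingency(setNames(rep(0L, 4), paste0("s", 1:4)), lab)
  expect_equal(sum(tab0), 0L)

  lab1 <- label_map(setNames(c("A", "A", "B"), paste0("t", 1:3)), c("A", "B"))
  tab1 <- contingency(setNames(c(1L, -1L), c("t1", "t2")), lab1)
  expect_equal(unname(tab1), rbind(c(1L, 0L), c(1L, 0L)), ignore_attr = TRUE)

  expect_error(contingency(setNames(1L, "zz"), lab), "unlabeled sample")
})

test_that("Fisher p matches hand enumeration on the worked tables", {
  expect_equal(fisher_p(rbind(c(5, 0), c(0, 5))), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_p(rbind(c(3, 3), c(3, 3))), 1)
  expect_equal(fisher_p(rbind(c(4, 0), c(0, 0))), 1)  # degenerate margin
  expect_error(fisher_p(rbind(c(-1, 1), c(1, 1))), "negative")
})

test_that("Fisher p agrees with the enumeration oracle and stats::fisher.test", {
  set.seed(3)
  for (i in 1:200) {
    tab <- random_table(sample(4:200, 1))
    p <- fisher_p(tab)
    expect_lt(abs(p - fisher_enum_p(tab)), 1e-10)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
    }
  }
})

test_that("chi-squared product-moment form equals sum((O-E)^2/E) and stats::chisq.test", {
  res <- chisq_p(rbind(c(10, 0), c(0, 10)))
  expect_equal(res$statistic, 20)
  expect_equal(res$p_value, pchisq(20, 1, lower.tail = FALSE))

  prop <- chisq_p(rbind(c(2, 4), c(1, 2)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)

  set.seed(4)
  for (i in 1:200) {
    z <- sample(2:5, 1)
    tab <- random_table(sample(10:200, 1), z)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- chisq_p(tab)
    expect_lt(abs(res$statistic - chisq_oe(tab)), 1e-9)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-8)
  }
  expect_error(chisq_p(rbind(c(0, 0), c(0, 0))), "N = 0")
})

test_that("screening ranks a strongly planted pair first", {
  spec <- synthetic_spec(m = 50, n = 100, k = 1, delta = 5)
  co <- generate_cohorts(spec, 1, seed = 0)[[1]]
  P <- build_pair_matrix(co$X, a = 0)
  scr <- screen(P, co$labels)
  # the planted pair attains the global minimum p-value (pairs coupling one
  # planted gene with a stable background gene can tie with it, and ties
  # break by pair index, so equality of p is the sharp guarantee)
  key <- paste(scr$gene_a, scr$gene_b, sep = "|")
  planted <- key == paste(sort(c(co$truth$gene_a, co$truth$gene_b))[1],
                          sort(c(co$truth$gene_a, co$truth$gene_b))[2],
                          sep = "|")
  expect_true(any(planted))
  expect_equal(scr$p_value[planted], min(scr$p_value))
  expect_lt(scr$p_value[planted], 1e-10)
  expect_identical(select_top(scr, 1)$l, scr$l[1])
})

test_that("ties in p-value break by ascending canonical pair index", {
  # two identical planted pairs produce identical tables
  vals <- rbind(a1 = c(5, 5, 1, 1), a2 = c(1, 1, 5, 5),
                b1 = c(5, 5, 1, 1), b2 = c(1, 1, 5, 5))
  colnames(vals) <- paste0("s", 1:4)
  X <- expression_matrix(vals, "t")
  lab <- label_map(setNames(c("A", "A", "B", "B"), colnames(vals)),
                   c("A", "B"))
  scr <- screen(build_pair_matrix(X, a = 0), lab)
  same_p <- scr[scr$p_value == min(scr$p_value), ]
  expect_equal(same_p$l, sort(same_p$l))
})

test_that("screening is invariant to sample order and label renaming", {
  spec <- synthetic_spec(m = 20, n = 40, k = 2, delta = 3)
  co <- generate_cohorts(spec, 1, seed = 5)[[1]]
  P <- build_pair_matrix(co$X, a = 0)
  scr <- screen(P, co$labels)

  perm <- sample(ncol(co$X))
  Xp <- expression_matrix(unclass(co$X)[, perm], "perm")
  scr_p <- screen(build_pair_matrix(Xp, a = 0), co$labels)
  expect_equal(scr_p$p_value, scr$p_value)
  expect_equal(scr_p$l, scr$l)

  renamed <- label_map(setNames(ifelse(co$labels == "class1", "X", "Y"),
                                names(co$labels)), c("X", "Y"))
  scr_r <- screen(P, renamed)
  expect_equal(scr_r$p_value, scr$p_value)
})

test_that("pairs with empty tables get p = 1 and select_top validates x", {
  vals <- rbind(g1 = c(1, 1), g2 = c(1, 1))
  colnames(vals) <- c("s1", "s2")
  X <- expression_matrix(vals, "t")
  lab <- label_map(setNames(c("A", "B"), c("s1", "s2")), c("A", "B"))
  scr <- screen(build_pair_matrix(X, a = 0), lab)
  expect_equal(scr$p_value, 1)
  expect_equal(scr$N, 0)
  expect_error(select_top(scr, 0), "positive")
  expect_error(select_top(scr, 5), "exceeds")
  expect_equal(nrow(select_top(scr, 1)), 1)
})
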