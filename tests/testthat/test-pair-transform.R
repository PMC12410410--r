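test_that("per-gene standard deviations match hand arithmetic", {
  vals <- rbind(const = c(5, 5, 5), g2 = c(1, 2, 3))
  colnames(vals) <- paste0("s", 1:3)
  X <- expression_matrix(vals, "t")
  st <- gene_stddev(X)
  expect_equal(unname(st$sd["const"]), 0)
  expect_equal(unname(st$sd["g2"]), 1)

  X2 <- expression_matrix(matrix(c(0, 2), 1, 2,
                                 dimnames = list("g", c("a", "b"))), "t")
  expect_equal(unname(gene_stddev(X2)$sd), sqrt(2))

  # affine shift leaves the SD vector unchanged
  X3 <- toy_matrix(5, 6)
  shifted <- expression_matrix(unclass(X3) + 3.7, "t")
  expect_equal(gene_stddev(shifted)$sd, gene_stddev(X3)$sd)

  one <- expression_matrix(matrix(1, 1, 1, dimnames = list("g", "s")), "t")
  expect_error(gene_stddev(one), "at least 2 samples")
})

test_that("Welch-Satterthwaite df matches its closed forms and hand value", {
  for (n in 2:100) {
    expect_equal(welch_df(1.3, 1.3, n), 2 * (n - 1))
    expect_equal(welch_df(2, 0, n), n - 1)
  }
  expect_equal(welch_df(1, 2, 10), 225 / 17)
  expect_error(welch_df(0, 0, 5), "undefined")
})

test_that("pair indexing is the canonical lexicographic bijection", {
  expect_equal(pair_index(1, 2, 5), 1)
  expect_equal(pair_index(4, 5, 5), choose(5, 2))
  expect_error(pair_index(3, 3, 5), "i < j")
  expect_error(pair_from_index(11, 5), "out of range")

  for (m in c(2, 3, 7, 17, 40)) {
    # enumeration oracle: pairs in (i < j) lexicographic order
    enum <- do.call(rbind, lapply(seq_len(m - 1), function(i)
      cbind(i, j = (i + 1):m)))
    l <- pair_index(enum[, 1], enum[, 2], m)
    expect_equal(l, seq_len(choose(m, 2)))
    inv <- pair_from_index(l, m)
    expect_equal(unname(inv[, 1]), unname(enum[, 1]))
    expect_equal(unname(inv[, 2]), unname(enum[, 2]))
  }
})

test_that("ternary coding obeys the strict-inequality rule", {
  # boundary: difference exactly equal to the threshold codes 0
  expect_identical(ternary_code(3, 1, 1, 1, 2 / sqrt(2)), 0L)
  expect_identical(ternary_code(2, 1, 0, 0, 0), 1L)
  expect_identical(ternary_code(1, 1, 0, 0, 0), 0L)
  expect_identical(ternary_code(1, 2, 0, 0, 0), -1L)
  # 4 > 2 * sqrt(2) so the pair codes +1
  expect_identical(ternary_code(5, 1, 1, 1, 2), 1L)
  expect_error(ternary_code(1, 2, 1, 1, -1), ">= 0")
})

test_that("pair matrix reproduces hand-coded toy examples", {
  X <- expression_matrix(matrix(c(3, 1, 0, 2), 2, 2,
                                dimnames = list(c("gA", "gB"),
                                                c("s1", "s2"))), "t")
  P0 <- build_pair_matrix(X, a = 0)
  expect_identical(unname(P0$values[1, ]), c(1L, -1L))
  # threshold exceeding both |differences| zeroes the row
  Pbig <- build_pair_matrix(X, a = 10)
  expect_identical(unname(Pbig$values[1, ]), c(0L, 0L))
})

test_that("block decomposition does not change the pair matrix", {
  X <- toy_matrix(30, 12, seed = 9)
  full <- build_pair_matrix(X, a = 1.5)
  tiny <- build_pair_matrix(X, a = 1.5, block_size = 1L)
  mid <- build_pair_matrix(X, a = 1.5, block_size = 37L)
  expect_identical(tiny$values, full$values)
  expect_identical(mid$values, full$values)
})

test_that("coding is antisymmetric and shrinks monotonically in a", {
  set.seed(11)
  for (rep in 1:5) {
    X <- toy_matrix(12, 10, seed = rep)
    st <- gene_stddev(X)
    P <- build_pair_matrix(X, a = 1)
    swapped <- build_pair_matrix(X, a = 1,
                                 pairs = cbind(P$pairs$gene_b,
                                               P$pairs$gene_a))
    expect_identical(unname(swapped$values), unname(-P$values))

    nz_prev <- Inf
    for (a in seq(0, 5, by = 0.5)) {
      Pa <- build_pair_matrix(X, a = a, stats = st)
      nz <- which(Pa$values != 0L)
      expect_lte(length(nz), nz_prev)
      if (is.finite(nz_prev)) expect_true(all(nz %in% prev_set))
      nz_prev <- length(nz)
      prev_set <- nz
    }
  }
})

test_that("a = 0 coding equals the brute-force sign comparison", {
  for (rep in 1:5) {
    X <- toy_matrix(15, 8, seed = 100 + rep)
    P <- build_pair_matrix(X, a = 0)
    oracle <- apply(P$pairs, 1, function(pr) {
      sign(X[pr[["gene_a"]], ] - X[pr[["gene_b"]], ])
    })
    storage.mode(oracle) <- "integer"
    expect_identical(unname(P$values), unname(t(oracle)))
  }
})

test_that("global affine transforms leave the pair matrix invariant", {
  set.seed(21)
  for (rep in 1:5) {
    X <- toy_matrix(10, 9, seed = 200 + rep)
    s <- runif(1, 0.1, 4); c0 <- runif(1, -10, 10)
    Y <- expression_matrix(s * unclass(X) + c0, "t2")
    P1 <- build_pair_matrix(X, a = 2)
    P2 <- build_pair_matrix(Y, a = 2)
    expect_identical(P1$values, P2$values)
  }
})
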