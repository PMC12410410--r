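test_that("odds-based risk split follows the mean-odds rule", {
  rs <- risk_split(setNames(c(0.8, 0.2), c("s1", "s2")))
  expect_equal(rs$odds, c(4, 0.25))
  expect_equal(attr(rs, "threshold"), 2.125)
  expect_equal(as.character(rs$group), c("low-risk", "high-risk"))

  expect_equal(risk_split(setNames(0.5, "x"))$odds, 1)

  # equal probabilities: nobody strictly exceeds the mean -> all high-risk
  eq <- risk_split(setNames(rep(0.3, 4), paste0("s", 1:4)))
  expect_true(all(eq$group == "high-risk"))

  expect_warning(rs1 <- risk_split(setNames(c(1, 0.2, 0.4), paste0("s", 1:3))),
                 "p = 1")
  expect_equal(as.character(rs1$group[1]), "low-risk")
  expect_equal(attr(rs1, "threshold"), mean(c(0.25, 2 / 3)))
  expect_error(risk_split(c(a = 1.2)), "\\[0, 1\\]")
})

test_that("log-rank handles identical groups, planted effects, missing data", {
  surv <- survival_table(data.frame(
    sample_id = paste0("s", 1:8),
    time = rep(c(5, 10, 15, 20), 2),
    event = rep(c(1, 0, 1, 1), 2)))
  # same survival experience in both groups -> statistic 0, p = 1
  rs <- structure(data.frame(sample_id = paste0("s", 1:8),
                             probability = rep(c(0.8, 0.2), each = 4),
                             odds = rep(c(4, 0.25), each = 4),
                             group = factor(rep(c("low-risk", "high-risk"),
                                                each = 4),
                                            c("low-risk", "high-risk"))),
                  class = c("risk_assignment", "data.frame"))
  res <- km_logrank(rs, surv)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_true(all(c("time", "survival", "group") %in% names(res$km)))

  missing <- rs
  missing$sample_id[1] <- "unknown"
  expect_error(km_logrank(missing, surv), "unknown")

  lab <- label_map(setNames(rep(c("R", "NR"), each = 100),
                            sprintf("p%03d", 1:200)), c("R", "NR"))
  st <- survival_from_labels(lab, hr = 3, censor_rate = 0.2, seed = 0)
  rs2 <- structure(data.frame(sample_id = names(lab),
                              probability = ifelse(lab == "R", 0.9, 0.1),
                              odds = ifelse(lab == "R", 9, 1 / 9),
                              group = factor(ifelse(lab == "R", "low-risk",
                                                    "high-risk"),
                                             c("low-risk", "high-risk"))),
                   class = c("risk_assignment", "data.frame"))
  expect_lt(km_logrank(rs2, st)$p_value, 0.01)
  hr <- cox_hr(rs2, st)
  expect_gt(hr$hazard_ratio, 2)
  expect_lt(hr$hazard_ratio, 4.5)
  expect_true(hr$ci_lower < hr$hazard_ratio &&
                hr$hazard_ratio < hr$ci_upper)
})

test_that("Cox on identical groups gives HR near 1; no events errors", {
  surv <- survival_table(data.frame(
    sample_id = paste0("s", 1:40),
    time = rep(c(3, 6, 9, 12, 15), 8),
    event = rep(c(1, 1, 0, 1, 0), 8)))
  rs <- structure(data.frame(sample_id = paste0("s", 1:40),
                             probability = 0.5, odds = 1,
                             group = factor(rep(c("low-risk", "high-risk"),
                                                20),
                                            c("low-risk", "high-risk"))),
                  class = c("risk_assignment", "data.frame"))
  hr <- cox_hr(rs, surv)
  expect_true(hr$ci_lower <= 1 && 1 <= hr$ci_upper)

  no_event <- surv
  no_event$event <- 0L
  expect_error(cox_hr(rs, no_event), "no events")
})

test_that("pair networks have one edge per pair, correct degrees and direction", {
  vals <- rbind(A = c(9, 9, 1, 1), B = c(1, 1, 9, 9), C = c(5, 5, 5, 5))
  colnames(vals) <- paste0("s", 1:4)
  X <- expression_matrix(vals, "net")
  lab <- label_map(setNames(c("R", "R", "NR", "NR"), colnames(vals)),
                   c("R", "NR"))
  pairs <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "C"),
                      direction = 1L, p_value = 0.01,
                      importance = c(0.7, 0.3))
  sig <- structure(list(pairs = pairs, coefficient_a = 0, method = "rf",
                        fit = NULL, class_order = c("R", "NR"), seed = 1),
                   class = "aigps_signature")
  g <- build_network(sig, X, lab)
  expect_equal(igraph::ecount(g), 2)
  deg <- igraph::V(g)$degree
  names(deg) <- igraph::V(g)$name
  expect_equal(deg[["A"]], 2L)
  expect_equal(deg[["B"]], 1L)
  # hub gene listed first
  expect_equal(igraph::V(g)$name[1], "A")
  # mean(A) > mean(B) in responders -> edge A -> B
  ed <- igraph::as_data_frame(g)
  expect_true(all(ed$from == "A"))
  expect_equal(sort(ed$to), c("B", "C"))

  tmp <- tempfile(fileext = ".graphml")
  write_network(g, tmp)
  expect_true(file.exists(tmp) && file.size(tmp) > 0)
  expect_error(build_network(sig, X[2:3, ], lab), "absent")
})
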