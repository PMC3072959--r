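test_that("EST sets collapse to distinct gene sets", {
  expr <- structure(list(
    queen = data.frame(id = c("e1", "e2", "e3", "e9")),
    worker = data.frame(id = c("e4", "e5")),
    no_difference = data.frame(id = c("e6", "e7"))),
    contrast = c("queen", "worker"), class = "expression_sets")
  aln <- data.frame(
    est_id = c("e1", "e2", "e3", "e4", "e5", "e6", "e7"),
    gene_id = c("gA", "gA", "gA", "gB", "gC", "gD", NA),
    accepted = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  sets <- build_gene_sets(expr, aln)
  expect_equal(sets$queen, "gA")           # 3 ESTs -> one gene
  expect_setequal(sets$worker, c("gB", "gC"))
  expect_equal(sets$no_difference, "gD")   # unaligned EST contributes nothing
})

test_that("genes claimed by both opposite-bias sets are excluded with warning", {
  expr <- structure(list(
    queen = data.frame(id = "e1"), worker = data.frame(id = "e2"),
    no_difference = data.frame(id = character(0))),
    contrast = c("queen", "worker"), class = "expression_sets")
  aln <- data.frame(est_id = c("e1", "e2"), gene_id = c("gX", "gX"),
                    accepted = TRUE, stringsAsFactors = FALSE)
  expect_warning(sets <- build_gene_sets(expr, aln), "both")
  expect_length(sets$queen, 0)
  expect_length(sets$worker, 0)
})

test_that("contingency tables have consistent margins and collapse modes", {
  classes <- c(g1 = "orphan", g2 = "orphan", g3 = "metazoa", g4 = "insect",
               g5 = "other", g6 = "hymenoptera")
  sets <- list(queen = c("g1", "g3"), worker = c("g2", "g4", "g6"),
               no_difference = c("g5"))
  ct <- build_contingency(classes, sets, collapse = "orphan")
  expect_equal(dim(ct$observed), c(2L, 3L))
  expect_equal(sum(ct$observed), 6)
  expect_equal(colSums(ct$expected), colSums(ct$observed))
  expect_equal(rowSums(ct$expected), rowSums(ct$observed))
  # full seven-row table conserves class counts
  ct7 <- build_contingency(classes, sets, collapse = "none")
  expect_equal(rowSums(ct7$observed)[["orphan"]], 2)
  expect_equal(sum(ct7$observed), 6)
  # trg-group pooling
  ctt <- build_contingency(classes, sets, collapse = "trg_group")
  expect_equal(rowSums(ctt$observed)[["trg"]], 4)
  expect_error(build_contingency(classes, list(q = character(0))), "empty")
})

test_that("chi-square matches the 2x2 closed form and stats::chisq.test", {
  O <- matrix(c(12L, 18L, 8L, 22L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  ct <- contingency_from_observed(O)
  res <- chi_square(ct, yates = FALSE)
  a <- O[1, 1]; b <- O[1, 2]; c <- O[2, 1]; d <- O[2, 2]; n <- sum(O)
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, closed)
  ref <- chisq.test(O, correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  # Yates agrees with the reference implementation too
  resy <- chi_square(ct, yates = TRUE)
  refy <- chisq.test(O, correct = TRUE)
  expect_equal(resy$statistic, unname(refy$statistic))
  # 2x3 without correction
  O2 <- matrix(c(18L, 37L, 61L, 645L, 501L, 1819L), 2, 3, byrow = TRUE)
  res2 <- chi_square(contingency_from_observed(O2))
  expect_equal(res2$statistic,
               unname(chisq.test(O2, correct = FALSE)$statistic))
  expect_equal(res2$df, 2L)
})

test_that("chi-square preconditions are enforced", {
  O3 <- matrix(1:6, 2, 3)
  expect_error(chi_square(contingency_from_observed(O3), yates = TRUE),
               "2x2")
  Oz <- matrix(c(0L, 0L, 5L, 5L), 2, 2,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(chi_square(contingency_from_observed(Oz)), "zero")
  # O = E exactly gives statistic 0
  Oe <- matrix(c(10L, 10L, 10L, 10L), 2, 2)
  expect_equal(chi_square(contingency_from_observed(Oe))$statistic, 0)
})

test_that("chi-square is invariant to row and column permutation", {
  withr::local_seed(50)
  O <- matrix(rpois(6, 30) + 1L, 2, 3,
              dimnames = list(c("a", "b"), c("x", "y", "z")))
  s1 <- chi_square(contingency_from_observed(O))$statistic
  s2 <- chi_square(contingency_from_observed(O[2:1, c(3, 1, 2)]))$statistic
  expect_equal(s1, s2)
})

test_that("percentage deviations match hand arithmetic", {
  O <- matrix(c(12L, 8L, 18L, 22L), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  ct <- contingency_from_observed(O)
  dev <- percentage_deviations(ct)
  E11 <- 20 * 30 / 60
  expect_equal(dev$deviations["a", "x"], 100 * (12 - E11) / E11)
  # uniform table deviates nowhere
  Ou <- matrix(c(10L, 10L, 10L, 10L), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_true(all(percentage_deviations(
    contingency_from_observed(Ou))$deviations == 0))
})

test_that("the cutoff scan degenerates correctly and handles sparse data", {
  withr::local_seed(51)
  n <- 300
  est <- data.frame(
    est_id = sprintf("e%03d", 1:n),
    gene_id = sprintf("g%03d", 1:n),
    direction = sample(c("queen", "worker", NA), n, TRUE,
                       prob = c(0.25, 0.25, 0.5)),
    p_value = runif(n), stringsAsFactors = FALSE)
  classes <- setNames(sample(c("orphan", "metazoa"), n, TRUE,
                             prob = c(0.2, 0.8)), est$gene_id)
  scan <- cutoff_sensitivity_scan(est, classes, c(1, 0.5, 1e-9))
  # threshold 1.0 keeps every candidate EST biased (degenerate threshold)
  full_biased <- sum(!is.na(est$direction))
  expect_equal(scan$n_biased_1[1] + scan$n_biased_2[1], full_biased)
  # an impossible threshold empties the biased sets -> insufficient data
  expect_true(scan$insufficient_data[3])
  expect_true(is.na(scan$statistic[3]))
  expect_error(cutoff_sensitivity_scan(est, classes, numeric(0)),
               "non-empty")
})
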