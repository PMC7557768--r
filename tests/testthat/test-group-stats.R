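test_that("wilcoxonSignedRank agrees with stats::wilcox.test when exact", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)  # continuous: no ties, no zeros
    r <- wilcoxonSignedRank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                              correct = FALSE)
    expect_equal(r@statistic, unname(ref$statistic))
    expect_equal(r@pValue, ref$p.value, tolerance = 1e-12)
  }
})

test_that("wilcoxonSignedRank handles zeros, ties and the normal branch", {
  # zeros dropped: effective n shrinks
  r <- wilcoxonSignedRank(c(1, 2, 3, 5, 5), c(1, 2, 1, 1, 9))
  expect_equal(r@nEffective, 3L)
  expect_equal(r@nTotal, 5L)
  expect_error(wilcoxonSignedRank(c(1, 2), c(1, 2)), "all differences")
  # large n switches to the tie-corrected normal approximation
  set.seed(4)
  x <- rpois(30, 20); y <- rpois(30, 20)
  r2 <- wilcoxonSignedRank(x, y)
  expect_equal(r2@method, "normal-approximation")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(r2@pValue, ref$p.value, tolerance = 1e-10)
  # p is capped at 1
  expect_lte(wilcoxonSignedRank(c(1, 5, 2, 9), c(5, 1, 9, 2))@pValue, 1)
})

test_that("summarizeNos computes mean and standard error per bundle", {
  tab <- data.frame(subject = rep(c("a", "b", "c"), 2),
                    bundle = rep(c("x", "y"), each = 3),
                    nos = c(10, 12, 14, 1, 2, 3))
  s <- summarizeNos(tab)
  expect_equal(s$mean[s$bundle == "x"], 12)
  expect_equal(s$se[s$bundle == "x"], sd(c(10, 12, 14)) / sqrt(3))
  expect_error(summarizeNos(tab[1:4, ]), "at least 2")
})

test_that("runPallidalComparisons runs the seven fixed pairs in order", {
  set.seed(8)
  bundles <- c("L_GPi_ipsi", "R_GPi_ipsi", "L_GPe_ipsi", "R_GPe_ipsi",
               "L_GPi_contra", "R_GPi_contra")
  mu <- c(400, 500, 200, 250, 500, 437)
  tab <- do.call(rbind, lapply(1:12, function(i)
    data.frame(subject = sprintf("s%02d", i), bundle = bundles,
               nos = rpois(6, mu))))
  out <- runPallidalComparisons(tab)
  expect_equal(nrow(out), 7L)
  expect_equal(out$x[1:2], c("L_GPi_ipsi", "R_GPi_ipsi"))
  expect_equal(out$y[1:2], c("L_GPe_ipsi", "R_GPe_ipsi"))
  # planted GPi > GPe must be detected in both hemispheres
  expect_true(all(out$significant[1:2]))
  # Holm option adds adjusted p-values that are never smaller
  outH <- runPallidalComparisons(tab, holm = TRUE)
  expect_true(all(outH$p_holm >= outH$p - 1e-15))
  expect_error(runPallidalComparisons(tab[tab$bundle != "L_GPe_ipsi", ]),
               "L_GPe_ipsi")
})

test_that("pairing in comparisons is by subject, not by row order", {
  # identical per-subject values in shuffled row order: all differences
  # zero -> the test must error (perfect pairing), not see noise
  tab1 <- data.frame(subject = c("a", "b", "c", "d"), bundle = "L_GPi_ipsi",
                     nos = c(5, 6, 7, 8))
  tab2 <- data.frame(subject = c("d", "c", "b", "a"), bundle = "L_GPe_ipsi",
                     nos = c(8, 7, 6, 5))
  filler <- do.call(rbind, lapply(
    c("R_GPi_ipsi", "R_GPe_ipsi", "L_GPi_contra", "R_GPi_contra"),
    function(b) data.frame(subject = c("a", "b", "c", "d"), bundle = b,
                           nos = c(1, 2, 3, 5))))
  tab <- rbind(tab1, tab2, filler)
  expect_error(runPallidalComparisons(tab), "all differences")
})
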