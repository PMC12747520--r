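test_that("pooled t-test matches the hand formula and its conventions", {
  tt <- tTest2Sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.02131, tolerance = 1e-3)

  same <- tTest2Sample(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  const <- tTest2Sample(c(3, 3), c(3, 3))
  expect_equal(const$p, 1)
  expect_error(tTest2Sample(c(3, 3), c(5, 5)), "undefined")
})

test_that("analytic t p-values agree with a permutation oracle", {
  set.seed(17)
  for (i in 1:12) {
    a <- rnorm(5); b <- rnorm(5, mean = runif(1, 0, 2))
    pAna <- tTest2Sample(a, b)$p
    pPerm <- permutationP(a, b, nPerm = 3000)
    expect_lt(abs(pAna - pPerm), 0.06)
  }
})

test_that("one-way ANOVA matches first-principles sums of squares", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(10, 11, 12))
  res <- oneWayAnova(g)
  expect_equal(res$F, bruteForceF(g), tolerance = 1e-12)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)

  ident <- oneWayAnova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)

  degen <- oneWayAnova(list(c(1, 1), c(1, 1)))
  expect_identical(degen$flags, "degenerate within-group variance")

  expect_error(oneWayAnova(list(1, c(2, 3))), ">= 2")
})

test_that("t-squared equals F on two groups and SS decomposition conserves", {
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(4 + i %% 3); b <- rnorm(5)
    expect_equal(tTest2Sample(a, b)$t^2, oneWayAnova(list(a, b))$F,
                 tolerance = 1e-9)
    ## SS conservation on a random 3-group table
    g <- list(rnorm(4), rnorm(6), rnorm(5))
    y <- unlist(g)
    sst <- sum((y - mean(y))^2)
    ssw <- sum(unlist(lapply(g, function(x) (x - mean(x))^2)))
    ssb <- sum(lengths(g) * (vapply(g, mean, numeric(1)) - mean(y))^2)
    expect_equal(ssb + ssw, sst, tolerance = 1e-9)
    expect_equal(oneWayAnova(g)$F, (ssb / 2) / (ssw / (length(y) - 3)),
                 tolerance = 1e-9)
  }
})

test_that("two-way ANOVA handles balanced designs and degeneracies", {
  ## additive cell means with zero noise: interaction F = 0
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), r = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  ## replicate effects shared by every cell keep the cell means additive,
  ## so the interaction sum of squares is exactly zero
  d$value <- ifelse(d$A == "a1", 0, 2) + ifelse(d$B == "b1", 0, 5) + (d$r - 2)
  res <- twoWayAnova(d, c("A", "B"))
  expect_lt(res$F[res$effect == "A:B"], 1e-9)
  expect_gt(res$F[res$effect == "A"], 1)

  ## balanced 2x3: type II equals the classical decomposition, SS conserve
  d2 <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"), r = 1:3,
                    KEEP.OUT.ATTRS = FALSE)
  set.seed(3); d2$value <- rnorm(nrow(d2))
  res2 <- twoWayAnova(d2, c("A", "B"))
  fit <- lm(value ~ A * B, data = d2)
  cls <- anova(fit)
  expect_equal(res2$F, cls$`F value`[1:3], tolerance = 1e-9)
  ssTot <- sum((d2$value - mean(d2$value))^2)
  expect_equal(sum(cls$`Sum Sq`), ssTot, tolerance = 1e-9)

  dEmpty <- d2[!(d2$A == "a2" & d2$B == "b3"), ]
  expect_error(twoWayAnova(dEmpty, c("A", "B")), "empty cells")
})

test_that("group summaries report mean, sample SD and n", {
  s <- summarizeGroups(list(x = c(2, 4), y = c(5), z = c(7, 7, 7)))
  expect_equal(s$mean, c(3, 5, 7))
  expect_equal(s$sd, c(sqrt(2), NA, 0))
  expect_equal(s$n, c(2L, 1L, 3L))
  expect_match(s$label[1], "3 ± 1.41")
  expect_match(s$label[2], "NA")
  expect_error(summarizeGroups(list()), "no groups")
})

test_that("Holm-adjusted pairwise tests accompany the omnibus ANOVA", {
  g <- list(a = c(1, 2, 3), b = c(1.1, 2.1, 3.1), c = c(10, 11, 12))
  pw <- pairwiseTTests(g)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$pAdj >= pw$p))
  expect_true(all(pw$p >= 0 & pw$pAdj <= 1))
})
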