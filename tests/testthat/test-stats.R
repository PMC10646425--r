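test_that("one-way ANOVA matches algebraic identities and a hand oracle", {
  # identical group means with spread: no between-group variance
  g0 <- list(a = c(1, 2, 3), b = c(3, 2, 1), c = c(2, 1, 3))
  a0 <- oneWayAnova(g0)
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1, tolerance = 1e-12)

  # two groups: F equals the square of the pooled two-sample t statistic
  g2 <- list(x = c(5.1, 4.8, 6.0, 5.5), y = c(6.2, 6.8, 5.9, 7.1))
  a2 <- oneWayAnova(g2)
  tt <- t.test(g2$x, g2$y, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-10)

  # fixed 3x4 toy table against a direct sum-of-squares computation
  g3 <- list(a = c(10, 12, 11, 13), b = c(14, 15, 13, 16),
             c = c(9, 8, 10, 11))
  a3 <- oneWayAnova(g3)
  all3 <- unlist(g3)
  ssb <- sum(vapply(g3, function(g)
    length(g) * (mean(g) - mean(all3))^2, numeric(1)))
  ssw <- sum(vapply(g3, function(g) sum((g - mean(g))^2), numeric(1)))
  Fhand <- (ssb / 2) / (ssw / 9)
  expect_equal(a3$F, Fhand, tolerance = 1e-12)
  expect_equal(a3$p, pf(Fhand, 2, 9, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(a3$msWithin, ssw / 9, tolerance = 1e-12)

  expect_error(oneWayAnova(list(a = 1:3)), "two groups")
  expect_error(oneWayAnova(list(a = 1, b = 2)), "at least two values")
  expect_error(oneWayAnova(list(a = c(1, 1), b = c(1, 1))), "variance")
})

test_that("ANOVA is shift-invariant and scales correctly", {
  g <- list(a = c(10, 12, 11, 13), b = c(14, 15, 13, 16),
            c = c(9, 8, 10, 11))
  a1 <- oneWayAnova(g)
  aShift <- oneWayAnova(lapply(g, `+`, 100))
  expect_equal(aShift$F, a1$F, tolerance = 1e-10)
  aScale <- oneWayAnova(lapply(g, `*`, 3.5))
  expect_equal(aScale$F, a1$F, tolerance = 1e-10)
  expect_equal(aScale$msWithin, 3.5^2 * a1$msWithin, tolerance = 1e-10)
})

test_that("Fisher LSD matches pooled pairwise t tests", {
  g <- list(a = c(10, 12, 11, 13), b = c(14, 15, 13, 16),
            c = c(9, 8, 10, 11))
  a <- oneWayAnova(g)
  lsd <- fisherLSD(g, a)
  # equal-means pair is exactly null
  gEq <- list(a = c(1, 2, 3), b = c(2, 3, 1), c = c(10, 11, 12))
  lsdEq <- fisherLSD(gEq, oneWayAnova(gEq))
  ab <- lsdEq[lsdEq$group1 == "a" & lsdEq$group2 == "b", ]
  expect_equal(ab$t, 0, tolerance = 1e-12)
  expect_equal(ab$p, 1, tolerance = 1e-12)
  expect_false(ab$significant)

  # symmetry: swapping the pair negates t, keeps p
  gSwap <- g[c(2, 1, 3)]
  lsdSwap <- fisherLSD(gSwap, oneWayAnova(gSwap))
  expect_equal(lsdSwap$t[1], -lsd$t[1], tolerance = 1e-10)
  expect_equal(lsdSwap$p[1], lsd$p[1], tolerance = 1e-10)

  # cross-check against base R's pooled pairwise t tests (no adjustment)
  df <- data.frame(v = unlist(g), gr = rep(names(g), lengths(g)))
  ref <- pairwise.t.test(df$v, df$gr, p.adjust.method = "none",
                         pool.sd = TRUE)$p.value
  for (i in seq_len(nrow(lsd))) {
    pRef <- ref[lsd$group2[i], lsd$group1[i]]
    if (is.na(pRef)) pRef <- ref[lsd$group1[i], lsd$group2[i]]
    expect_equal(lsd$p[i], unname(pRef), tolerance = 1e-10)
  }
})

test_that("LSD p-values agree with a permutation approximation", {
  set.seed(20)
  g <- list(a = c(10.1, 11.8, 10.9, 12.6), b = c(12.9, 14.2, 12.4, 15.0),
            c = c(10.5, 9.4, 11.2, 12.0))
  a <- oneWayAnova(g)
  lsd <- fisherLSD(g, a)
  obs <- lsd$t[lsd$group1 == "a" & lsd$group2 == "b"]
  vals <- unlist(g, use.names = FALSE)
  sizes <- lengths(g)
  nPerm <- 1e5
  # vectorised label permutations: recompute the LSD t for pair (a, b)
  tPerm <- vapply(seq_len(nPerm), function(i) {
    v <- vals[sample.int(length(vals))]
    gp <- split(v, rep(seq_along(sizes), sizes))
    msw <- sum(vapply(gp, function(x) sum((x - mean(x))^2),
                      numeric(1))) / (length(vals) - length(sizes))
    (mean(gp[[1]]) - mean(gp[[2]])) /
      sqrt(msw * (1 / sizes[1] + 1 / sizes[2]))
  }, numeric(1))
  pPerm <- mean(abs(tPerm) >= abs(obs))
  pLSD <- lsd$p[lsd$group1 == "a" & lsd$group2 == "b"]
  expect_lt(abs(pPerm - pLSD), 0.03)
})

test_that("anovaLSD bundles a valid StatsResult", {
  g <- list(a = rnorm(5, 10), b = rnorm(5, 10), c = rnorm(5, 12))
  res <- anovaLSD(g)
  expect_s4_class(res, "StatsResult")
  expect_true(validObject(res))
  expect_equal(nrow(res@lsd), 3)
  expect_identical(res@lsd$significant, res@lsd$p < 0.05)
})
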