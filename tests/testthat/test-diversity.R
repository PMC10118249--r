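test_that("chao1 matches its closed forms and dominates observed richness", {
  expect_equal(chao1(c(5, 3, 1, 1, 2)), 7)       # S=5, F1=2, F2=1
  expect_equal(chao1(c(4, 4, 4)), 3)             # no singletons
  expect_equal(chao1(c(1, 1)), 3)                # F2=0: bias-corrected form
  expect_equal(chao1(c(1, 1), bias_corrected = TRUE), 3)
  expect_equal(chao1(c(5, 3, 1, 1, 2), bias_corrected = TRUE),
               5 + 2 * 1 / (2 * 2))
  expect_error(chao1(c(0.5, 1)), "requires counts")

  set.seed(42)
  for (i in 1:50) {
    x <- rpois(30, 2)
    if (sum(x) == 0) next
    est <- chao1(x)
    expect_gte(est, sum(x > 0))
    if (sum(x == 1) == 0) expect_equal(est, sum(x > 0))
  }
})

test_that("inverse Simpson hits its closed forms and is maximal at uniform", {
  for (S in c(2, 4, 7)) expect_equal(inverseSimpson(rep(1 / S, S)), S)
  expect_equal(inverseSimpson(1), 1)
  expect_equal(inverseSimpson(c(0.5, 0.3, 0.2)), 1 / 0.38, tolerance = 1e-5)
  expect_error(inverseSimpson(c(0, 0)), "positive")
  expect_error(inverseSimpson(c(0.5, 0.1)), "sum to 1")

  set.seed(7)
  for (S in 3:6) for (i in 1:100) {
    p <- rgamma(S, 1); p <- p / sum(p)
    expect_lte(inverseSimpson(p), S + 1e-12)
  }
})

test_that("Faith's PD spans the minimal rooted subtree and is monotone", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(faithPD(c("a", "b", "c", "d"), star), 4)
  expect_equal(faithPD("a", star), 1)

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_equal(faithPD(c("A", "B"), tr), 3)
  expect_equal(faithPD(c("A", "B", "C"), tr), sum(tr$edge.length))
  expect_error(faithPD(c("A", "Zz"), tr), "Zz")

  big <- generateTree(sprintf("t%02d", 1:12), seed = 3)
  present <- c("t01", "t05")
  pd <- faithPD(present, big)
  for (extra in c("t02", "t08", "t11")) {
    pd2 <- faithPD(c(present, extra), big)
    expect_gte(pd2, pd)
    present <- c(present, extra); pd <- pd2
  }
  expect_equal(faithPD(big$tip.label, big), sum(big$edge.length))

  # independent implementation cross-check (root-inclusive PD)
  samp <- matrix(c(1, 0, 1, 0, 1, 0, 0, 0, 1, 1, 1, 1), nrow = 1,
                 dimnames = list("s1", big$tip.label))
  ref <- suppressWarnings(picante::pd(samp, big, include.root = TRUE))
  expect_equal(faithPD(colnames(samp)[samp[1, ] > 0], big), ref$PD,
               tolerance = 1e-10)
})

test_that("richness-diversity correlation has exact and null behaviour", {
  x <- 1:10
  expect_equal(richnessDiversityCorrelation(x, 2 * x)$r, 1)
  expect_equal(richnessDiversityCorrelation(x, -x)$r, -1)
  expect_error(richnessDiversityCorrelation(x, rep(1, 10)), "constant")
  expect_error(richnessDiversityCorrelation(1:2, 1:2), "3")

  set.seed(11)
  ok <- replicate(200, {
    x <- rnorm(1000); y <- rnorm(1000)
    ct <- richnessDiversityCorrelation(x, y)
    abs(ct$r) < 0.1 && ct$p_value > 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("one-way ANOVA matches the classical F decomposition", {
  expect_equal(oneWayAnova(list(c(1, 2, 3), c(1, 2, 3))),
               list(F = 0, p_value = 1))

  set.seed(5)
  sep <- oneWayAnova(list(rnorm(3, 0, 1e-4), rnorm(3, 10, 1e-4)))
  expect_lt(sep$p_value, 1e-6)

  # direct sum-of-squares oracle on random data
  groups <- list(rnorm(6), rnorm(5, 1), rnorm(7, -0.5))
  y <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  ssb <- sum(lengths(groups) *
               (vapply(groups, mean, 1) - mean(y))^2)
  ssw <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2)))
  Fo <- (ssb / 2) / (ssw / (length(y) - 3))
  res <- oneWayAnova(groups)
  expect_equal(res$F, Fo, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pf(Fo, 2, length(y) - 3, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(oneWayAnova(list(1, c(1, 2))), "at least 2 observations")
  expect_error(oneWayAnova(list(c(1, 2))), "at least 2 groups")
})

test_that("ANOVA type-I error is calibrated under a shared normal", {
  set.seed(123)
  rej <- replicate(1000, {
    oneWayAnova(list(rnorm(5), rnorm(5), rnorm(5)))$p_value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("per-sample records and group summaries assemble correctly", {
  tab <- tinyCounts()
  div <- sampleDiversity(tab)
  expect_equal(nrow(div), 4)
  expect_equal(div$reads, rowSums(abundances(tab)), ignore_attr = TRUE)
  expect_equal(div$chao1[1], chao1(abundances(tab)[1, ]))
  expect_true(all(is.na(div$faith_pd)))

  rec <- data.frame(sample_id = paste0("s", 1:4),
                    group = rep(c("A", "B"), each = 2),
                    reads = c(1, 3, 5, 7), s_obs = c(1, 3, 5, 7),
                    f1 = 0, f2 = 0, chao1 = c(1, 3, 5, 7),
                    inv_simpson = c(1, 3, 5, 7), faith_pd = NA_real_)
  sm <- summarizeGroups(rec)
  num <- sm$numeric
  expect_equal(num$mean[num$group == "A" & num$index == "chao1"], 2)
  expect_equal(num$mean[num$group == "B" & num$index == "chao1"], 6)
  expect_equal(num$mean[num$group == "ALL" & num$index == "chao1"], 4)
  expect_false("faith_pd" %in% num$index)

  same <- rec; same$chao1 <- 5; same$group <- "A"
  expect_true(all(summarizeGroups(same)$numeric$sd[
    summarizeGroups(same)$numeric$index == "chao1"] == 0))
})
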