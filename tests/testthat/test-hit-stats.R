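test_that("SSMD matches direct evaluation and is antisymmetric", {
  expect_equal(ssmd(100, 57.3), 0) # null case regardless of variance
  expect_equal(ssmd(140, 400, 100, 100), 40 / sqrt(500), tolerance = 1e-12)
  # brute-force check over random pooled inputs; swap flips the sign exactly
  set.seed(4)
  for (i in 1:25) {
    m1 <- runif(1, 60, 160); m2 <- runif(1, 60, 160)
    v1 <- runif(1, 1, 500); v2 <- runif(1, 1, 500)
    expect_equal(ssmd(m1, v1, m2, v2), (m1 - m2) / sqrt(v1 + v2),
                 tolerance = 1e-12)
    expect_identical(ssmd(m1, v1, m2, v2), -ssmd(m2, v2, m1, v1))
  }
  expect_warning(inf <- ssmd(120, 0, 100, 0), "infinite")
  expect_identical(inf, Inf)
  expect_equal(ssmd(100, 0, 100, 0), 0)
})

test_that("Dunnett with one comparison is Student's two-sample t test", {
  set.seed(11)
  for (i in 1:5) {
    a <- rnorm(3 + i, 100, 12)
    b <- rnorm(4, 105, 12)
    d <- dunnett_test(list(KO = b), a)
    tt <- t.test(b, a, var.equal = TRUE)
    expect_equal(d$p_adj, tt$p.value, tolerance = 1e-12)
    expect_equal(d$t, unname(tt$statistic), tolerance = 1e-12)
  }
})

test_that("Dunnett adjusted p agrees with the multivariate-t reference", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  k <- 6
  vals <- lapply(1:k, function(i) rnorm(3, 100 + 4 * i, 8))
  names(vals) <- paste0("KO", 1:k)
  ctrl <- rnorm(9, 100, 8)
  mine <- dunnett_test(vals, ctrl)
  g <- factor(rep(c("ctrl", names(vals)), c(9, rep(3, k))),
              levels = c("ctrl", names(vals)))
  fit <- stats::aov(c(ctrl, unlist(vals)) ~ g)
  set.seed(1) # multcomp integrates stochastically
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))
  expect_equal(mine$p_adj, as.numeric(ref$test$pvalues), tolerance = 5e-4)
  expect_equal(mine$t, unname(as.numeric(ref$test$tstat)), tolerance = 1e-8)
})

test_that("family-wise adjustment can only inflate the per-comparison p", {
  set.seed(31)
  for (rep in 1:4) {
    k <- sample(2:8, 1)
    vals <- lapply(seq_len(k), function(i) rnorm(3, 100, 10))
    names(vals) <- paste0("KO", seq_len(k))
    ctrl <- rnorm(6, 100, 10)
    d <- dunnett_test(vals, ctrl)
    raw <- 2 * pt(-abs(d$t), d$df)
    expect_true(all(d$p_adj >= raw - 1e-10))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(dunnett_test(list(KO = c(1, 2)), 5), ">= 2 control")
  expect_error(dunnett_test(list(KO = 3), c(1, 2)), ">= 2 replicates")
  expect_error(dunnett_test(list(KO = c(5, 5)), c(5, 5)), "pooled variance")
})

test_that("hit classes follow the dual SSMD + significance criterion", {
  st <- data.frame(
    variant = paste0("KO", 1:6),
    ssmd = c(1.5, 1.5, -1.2, 0.8, -0.5, 1.2),
    p_adj = c(0.01, 0.2, 0.03, 0.01, 0.5, 0.049),
    dfbar = c(140, 135, 70, 110, 95, 125)
  )
  out <- classify_hits(st)
  expect_equal(as.character(out$hit_class),
               c("up_hit", "possible_up", "down_hit", "none", "none",
                 "up_hit"))
  # SSMD at exactly the threshold is not beyond it
  at <- classify_hits(data.frame(ssmd = 1, p_adj = 0.01, dfbar = 120))
  expect_equal(as.character(at$hit_class), "none")
  # infinite SSMD never classifies as a hit
  inf <- classify_hits(data.frame(ssmd = Inf, p_adj = 0.001, dfbar = 150))
  expect_equal(as.character(inf$hit_class), "none")
})

test_that("replication concordance confirms, demotes and reports untested", {
  s1 <- data.frame(variant = c("A", "B", "C", "D", "E"),
                   dfbar = c(135, 130, 128, 122, 101),
                   ssmd = c(1.8, 1.6, 1.5, 1.4, 0.05),
                   p_adj = c(0.01, 0.02, 0.01, 0.03, 0.95),
                   hit_class = c("up_hit", "up_hit", "up_hit", "up_hit",
                                 "none"))
  s2 <- data.frame(variant = c("A", "B", "C", "E"),
                   dfbar = c(118, 90, 131, 100),
                   ssmd = c(1.1, -0.9, 2.0, 0.1),
                   p_adj = c(0.2, 0.6, 0.01, 0.9),
                   hit_class = c("possible_up", "none", "up_hit", "none"))
  out <- replication_concordance(s1, s2)
  get <- function(v) out$status[out$variant == v]
  expect_equal(get("A"), "hit")      # strong same-direction SSMD confirms
  expect_equal(get("B"), "none")     # opposite direction demotes
  expect_equal(get("C"), "hit")      # significant in both series
  expect_equal(get("D"), "untested") # absent from series 2
  expect_equal(get("E"), "none")     # never a hit in either series
  # confirmation by the 120% consistency margin without strong SSMD
  s2b <- s2; s2b$ssmd[1] <- 0.7; s2b$dfbar[1] <- 124
  expect_equal(replication_concordance(s1, s2b)$status[1], "hit")
})

test_that("screen summary counts threshold crossings by direction", {
  st <- data.frame(
    variant = paste0("KO", 1:4), metric = "mean",
    dfbar = c(85, 95, 115, 125), s2 = 10, n = 3,
    ssmd = c(-1.5, -0.3, 0.8, 2.1), t = c(-3.5, -0.4, 1.2, 3.6),
    p_adj = c(0.01, 0.9, 0.4, 0.02)
  )
  s <- screen_summary(st)
  expect_equal(s$gt110, 2)
  expect_equal(s$gt120, 1)
  expect_equal(s$lt90, 1)
  expect_equal(s$lt80, 0)
  expect_equal(s$ssmd_gt1, 1)
  expect_equal(s$ssmd_lt_m1, 1)
  expect_equal(s$sig_up, 1)
  expect_equal(s$sig_down, 1)
  all100 <- st; all100$dfbar <- 100; all100$ssmd <- 0; all100$p_adj <- 1
  s0 <- screen_summary(all100)
  expect_true(all(s0[, c("gt110", "gt120", "lt90", "lt80", "ssmd_gt1",
                         "ssmd_lt_m1", "sig_up", "sig_down")] == 0))
})

test_that("analyze_screen produces a consistent stats table", {
  scr <- simulate_screen(tiny_config(seed = 55L))
  st <- analyze_screen(scr)
  expect_setequal(unique(st$metric), c("mean", "median"))
  expect_equal(sum(st$metric == "mean"), 6)
  expect_true(all(is.finite(st$t)))
  expect_true(all(st$p_adj >= 0 & st$p_adj <= 1))
  # sign of SSMD equals sign of the mean excess over 100%
  expect_true(all(sign(st$ssmd) == sign(st$dfbar - 100)))
})
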