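# Brute-force Kruskal-Wallis H from the rank definition (tie-corrected).
bruteKW <- function(groups) {
  x <- unlist(groups); N <- length(x)
  rk <- rank(x)
  offs <- cumsum(c(0, head(vapply(groups, length, integer(1)), -1)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(i) {
      ri <- rk[offs[i] + seq_along(groups[[i]])]
      sum(ri)^2 / length(ri)
    }, numeric(1))) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Brute-force one-way ANOVA F from sums of squares.
bruteF <- function(groups) {
  x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
  gm <- mean(x)
  ssb <- sum(vapply(groups, function(v) length(v) * (mean(v) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- length(groups) - 1; dfw <- length(x) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

test_that("Kruskal-Wallis matches the rank-formula oracle", {
  g <- list(a = c(1, 2, 3), b = c(101, 102, 103))
  r <- kwAnova(g)
  expect_equal(r$H, 3.857142857142857, tolerance = 1e-10)
  expect_equal(r$H, bruteKW(g), tolerance = 1e-10)

  set.seed(31)
  for (k in 1:10) {
    g3 <- list(a = rnorm(7), b = rnorm(5, 1), c = sample(1:8, 6, TRUE))
    expect_equal(kwAnova(g3)$H, bruteKW(g3), tolerance = 1e-10)
  }

  same <- list(a = c(5, 6, 7), b = c(5, 6, 7))
  rs <- kwAnova(same)
  expect_lt(rs$H, 1e-9)
  expect_gt(rs$p.value, 0.95)
  expect_error(kwAnova(list(a = 1:3)), "two groups")
  expect_error(kwAnova(list(a = 1:3, b = numeric())), "empty")
})

test_that("Kruskal-Wallis H is invariant under monotone transforms", {
  set.seed(8)
  g <- list(a = runif(8), b = runif(6) + 0.3, c = runif(7))
  h0 <- kwAnova(g)$H
  expect_equal(kwAnova(lapply(g, exp))$H, h0, tolerance = 1e-10)
  expect_equal(kwAnova(lapply(g, function(v) v^3 + 5))$H, h0,
               tolerance = 1e-10)
})

test_that("Kruskal-Wallis type-I error is close to nominal", {
  set.seed(99)
  rej <- mean(vapply(1:1000, function(i) {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    kwAnova(g)$p.value < 0.05
  }, logical(1)))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Dunn post-hoc separates what should be separated", {
  g <- list(lo = c(1, 2, 3, 4, 5), hi = c(101, 102, 103, 104, 105),
            mid = c(50, 51, 52, 53, 54))
  ph <- kwAnova(g)$posthoc
  expect_identical(nrow(ph), 3L)
  expect_lt(ph$p.adj[ph$group1 == "lo" & ph$group2 == "hi"], 0.05)
  same <- kwAnova(list(a = c(1, 3, 2, 4), b = c(2, 1, 4, 3)))$posthoc
  expect_gt(same$p.adj[1], 0.5)
})

test_that("ANOVA with Tukey matches the sums-of-squares oracle", {
  g <- list(ctrl = c(18, 20, 21, 22), t1 = c(24, 26, 27, 25),
            t2 = c(30, 31, 33, 29))
  r <- anovaTukey(g)
  expect_equal(r$F, bruteF(g), tolerance = 1e-10)
  expect_lt(r$p.value, 0.01)
  expect_identical(nrow(r$posthoc), 3L)

  ident <- anovaTukey(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_lt(abs(ident$F), 1e-20)

  set.seed(4)
  for (k in 1:8) {
    g3 <- list(a = rnorm(6), b = rnorm(9), c = rnorm(5))
    expect_equal(anovaTukey(g3)$F, bruteF(g3), tolerance = 1e-10)
  }
})

test_that("null ANOVA F is near one in expectation", {
  set.seed(12)
  fs <- vapply(1:500, function(i)
    anovaTukey(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$F,
    numeric(1))
  # E[F(2, 27)] = 27/25 = 1.08
  expect_lt(abs(mean(fs) - 1.08), 0.25)
})

test_that("intact classification and per-region counts behave", {
  expect_identical(classifyIntact(c(0.3, 0.05, 0.3), c(TRUE, TRUE, FALSE),
                                  deltaThreshold = 0.1),
                   c(TRUE, FALSE, FALSE))

  obs <- data.frame(
    region = rep(c("UTJ", "amp"), each = 8),
    replicate = rep(rep(1:2, each = 4), 2),
    intact_catsper = c(rep(FALSE, 8), rep(TRUE, 8)))
  ct <- classifyCounts(obs)$intact_catsper
  expect_equal(ct$proportion[ct$region == "amp"], 1.0)
  expect_equal(ct$proportion[ct$region == "UTJ"], 0.0)
  expect_identical(ct$n_cells, c(8L, 8L))

  # graded proportions over 4 regions x 4 replicates: ordering recovered
  ok <- 0L
  probs <- c(0.2, 0.4, 0.6, 0.8)
  set.seed(77)
  for (repl in 1:100) {
    obs2 <- do.call(rbind, lapply(1:4, function(ri)
      do.call(rbind, lapply(1:4, function(re) data.frame(
        region = paste0("R", ri), replicate = re,
        intact_catsper = runif(30) < probs[ri])))))
    ct2 <- classifyCounts(obs2)$intact_catsper
    p <- ct2$proportion[match(paste0("R", 1:4), ct2$region)]
    if (all(diff(p) > 0)) ok <- ok + 1L
  }
  expect_gte(ok, 95L)

  # letter coding: clearly separated groups do not share letters
  sep <- data.frame(
    region = rep(c("lo", "hi"), each = 8),
    replicate = rep(rep(1:4, each = 2), 2),
    intact_catsper = c(runif(8) < 0.05, runif(8) > 0.1))
  lt <- classifyCounts(sep)$intact_catsper
  expect_false(lt$letters[1] == lt$letters[2])
})

test_that("reports are structured, explicit about gaps, and deterministic", {
  empty <- buildReport(list(deltaTable = data.frame(region = character(),
                                                    n = integer())))
  expect_match(empty, "No cells")
  expect_match(empty, "not provided")

  dt <- regionDeltaTable(c(0.1, 0.2, 0.5, 0.6),
                         c("UTJ", "UTJ", "amp", "amp"))
  kw <- kwAnova(list(UTJ = c(0.1, 0.2), amp = c(0.5, 0.6)))
  sens <- data.frame(noise_rate = c(0, 0.01), mean_sensitivity = c(1, 0.9),
                     sd_sensitivity = c(0, 0.05))
  full1 <- buildReport(list(deltaTable = dt, kw = kw,
                            sensitivityTable = sens, configHash = "abc"),
                       path = withr::local_tempfile(fileext = ".md"))
  full2 <- buildReport(list(deltaTable = dt, kw = kw,
                            sensitivityTable = sens, configHash = "abc"))
  expect_identical(full1, full2)
  expect_match(full1, "delta by region")
  expect_match(full1, "sensitivity vs noise")
  expect_match(full1, "Kruskal-Wallis")
})
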