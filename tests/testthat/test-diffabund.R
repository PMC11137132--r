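test_that("normalize_bait_counts scales every sample to the minimum total", {
  keys <- c("A@+0.0", "B@+0.0")
  m <- make_counts(c(150, 50, 60, 40), keys, c("s1", "s2"))  # totals 200, 100
  norm <- normalize_bait_counts(m)
  expect_equal(unname(colSums(norm)), c(100, 100), tolerance = 1e-9)
  expect_equal(unname(attr(norm, "norm_factors")), c(0.5, 1))
  expect_equal(norm[, "s2"], m[, "s2"])       # minimum sample unchanged

  # three samples, {90, 60, 30} -> factors {1/3, 1/2, 1}
  m3 <- make_counts(c(90, 60, 30), "A@+0.0", c("x", "y", "z"))
  n3 <- normalize_bait_counts(m3)
  expect_equal(unname(attr(n3, "norm_factors")), c(1/3, 1/2, 1))
  expect_equal(unname(colSums(n3)), rep(30, 3), tolerance = 1e-9)
})

test_that("normalization preserves proportions and is idempotent", {
  set.seed(9)
  m <- make_counts(rpois(40, 8) + 1, sprintf("P%dK@+0.0", 1:10),
                   c("a", "b", "c", "d"))
  norm <- normalize_bait_counts(m)
  props_before <- sweep(m, 2, colSums(m), "/")
  props_after <- sweep(norm, 2, colSums(norm), "/")
  expect_equal(props_after, props_before, ignore_attr = TRUE)
  # idempotence: all totals already equal
  norm2 <- normalize_bait_counts(norm)
  expect_equal(norm2, norm, ignore_attr = TRUE, tolerance = 1e-12)
  # equal totals -> identity
  eq <- make_counts(c(5, 5, 5, 5), c("A@+0.0", "B@+0.0"), c("a", "b"))
  expect_equal(normalize_bait_counts(eq), eq, ignore_attr = TRUE)
})

test_that("normalize_bait_counts rejects zero-total samples by name", {
  m <- make_counts(c(5, 0), "A@+0.0", c("good", "empty"))
  expect_error(normalize_bait_counts(m), "empty")
})

test_that("filter_singletons removes rows with dataset-wide total 1", {
  keys <- c("A@+0.0", "B@+0.0", "C@+0.0")
  m <- make_counts(c(1, 3, 2, 0, 2, 0), keys, c("s1", "s2"))  # totals 1, 5, 2
  f <- filter_singletons(m)
  expect_equal(rownames(f), c("B@+0.0", "C@+0.0"))            # total 2 retained
  expect_equal(attr(f, "removed"), "A@+0.0")
  # degenerate: everything a singleton
  all1 <- make_counts(c(1, 1), c("A@+0.0", "B@+0.0"), "s1")
  expect_warning(f0 <- filter_singletons(all1), "singleton")
  expect_equal(nrow(f0), 0L)
})

test_that("score_internal matches the two-component Poisson model", {
  design <- make_design(n_test = 3, n_control = 3)
  keys <- c("UP@+0.0", "FLAT@+0.0", "DOWN@+0.0")
  m <- make_counts(c(0, 5, 10, 0, 5, 10, 0, 5, 10,     # c1 c2 c3
                     10, 5, 0, 10, 5, 0, 10, 5, 0),    # t1 t2 t3
                   keys, c("c1", "c2", "c3", "t1", "t2", "t3"))
  res <- score_internal(m, design, list(test = "test", control = "control"))
  up <- res[res$peptidoform == "UP@+0.0", ]
  flat <- res[res$peptidoform == "FLAT@+0.0", ]
  down <- res[res$peptidoform == "DOWN@+0.0", ]
  # control {0,0,0}, test {10,10,10}: avgp > 0.999 (lambda0=0.1, lambda1=10.1)
  expect_gt(up$avgp, 0.999)
  # identical counts: likelihood ratio 1 -> p = prior exactly
  expect_equal(flat$avgp, 0.5)
  # depletion clamps lambda1 to lambda0 -> never "significant up"
  expect_equal(down$avgp, 0.5)
  expect_equal(up$log2fc, log2(10.1 / 0.1))
  # oracle: independent per-replicate posterior for the UP row
  lam0 <- 0.1; lam1 <- 10.1
  p_k <- 0.5 * dpois(10, lam1) / (0.5 * dpois(10, lam1) + 0.5 * dpois(10, lam0))
  expect_equal(up$avgp, p_k, tolerance = 1e-12)
})

test_that("score_internal handles fractional counts via continuous Poisson", {
  design <- make_design(n_test = 2, n_control = 2)
  m <- make_counts(c(2.5, 2.5, 20.25, 20.25), "A@+0.0",
                   c("c1", "c2", "t1", "t2"))
  res <- score_internal(m, design, list(test = "test", control = "control"))
  # oracle via explicit gamma-function density
  dc <- function(x, l) exp(x * log(l) - l - lgamma(x + 1))
  lam0 <- 2.6; lam1 <- 20.35
  p <- 0.5 * dc(20.25, lam1) / (0.5 * dc(20.25, lam1) + 0.5 * dc(20.25, lam0))
  expect_equal(res$avgp, p, tolerance = 1e-12)
  expect_error(score_internal(m, design, list(test = "nope", control = "control")),
               "zero test")
})

test_that("compute_bfdr is the cumulative mean of 1 - AvgP down the ranking", {
  r <- data.frame(peptidoform = c("a", "b", "c"), avgp = c(1, 1, 0.5))
  out <- compute_bfdr(r)
  expect_equal(out$bfdr, c(0, 0, 1/6))
  expect_equal(compute_bfdr(data.frame(avgp = rep(1, 4)))$bfdr, rep(0, 4))
  expect_equal(compute_bfdr(data.frame(avgp = rep(0, 4)))$bfdr, rep(1, 4))
  empty <- compute_bfdr(data.frame(avgp = numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("BFDR is in [0,1], non-decreasing, and ties share one value", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:30, 1)
    avgp <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding makes ties
    out <- compute_bfdr(data.frame(avgp = avgp))
    expect_true(all(out$bfdr >= 0 & out$bfdr <= 1))
    expect_true(all(diff(out$bfdr) >= -1e-12))
    for (v in unique(out$avgp))
      expect_length(unique(out$bfdr[out$avgp == v]), 1L)
  }
})

test_that("call_significant uses a strict BFDR threshold", {
  r <- data.frame(bfdr = c(0.049, 0.05, 0.2))
  out <- call_significant(r)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(call_significant(data.frame(bfdr = numeric(0)))), 0L)
})

test_that("score_comparison runs both directions on normalized counts", {
  design <- make_design(n_test = 3, n_control = 3)
  keys <- c("UP@+58.0", "DOWN@+0.0", paste0("N", 1:6, "@+0.0"))
  set.seed(13)
  null_part <- matrix(rpois(36, 8), nrow = 6)
  m <- rbind(c(0, 1, 0, 24, 30, 26),        # up in test
             c(25, 28, 31, 0, 1, 0),        # up in control
             null_part)
  dimnames(m) <- list(keys, c("c1", "c2", "c3", "t1", "t2", "t3"))
  res <- score_comparison(m, design, list(test = "test", control = "control"))
  expect_setequal(unique(res$test), c("test", "control"))
  up <- res[res$peptidoform == "UP@+58.0" & res$test == "test", ]
  down <- res[res$peptidoform == "DOWN@+0.0" & res$test == "control", ]
  expect_true(up$significant)
  expect_true(down$significant)
  expect_gt(up$log2fc, 2)
  expect_gt(down$log2fc, 2)
  # the same forms are not called in the wrong direction
  expect_false(res$significant[res$peptidoform == "UP@+58.0" &
                                 res$test == "control"])
})

test_that("run_saintexpress falls back to the surrogate when binary is absent", {
  design <- make_design(n_test = 2, n_control = 2)
  m <- make_counts(c(5, 5, 9, 9), "A@+0.0", c("c1", "c2", "t1", "t2"))
  expect_warning(
    res <- run_saintexpress(m, design, list(test = "test", control = "control"),
                            binary = "no-such-binary-xyz"),
    "falling back")
  expect_true(is.data.frame(res))
  expect_true("avgp" %in% names(res))
})
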