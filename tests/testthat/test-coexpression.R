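test_that("similarity handles duplicates, negation, and matches the textbook formula", {
  set.seed(1)
  x <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  x[2, ] <- x[1, ]          # exact duplicate
  x[3, ] <- -x[1, ]         # exact negation
  su <- correlation_similarity(x, "unsigned")
  ss <- correlation_similarity(x, "signed")
  expect_equal(su["g1", "g2"], 1)
  expect_equal(su["g1", "g3"], 1)
  expect_equal(ss["g1", "g3"], 0)
  # direct Pearson formula for an arbitrary pair
  a <- x[4, ]; b <- x[5, ]
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(su["g4", "g5"], abs(r), tolerance = 1e-12)
  expect_equal(ss["g4", "g5"], (1 + r) / 2, tolerance = 1e-12)
})

test_that("constant genes are excluded with a warning and few samples are an error", {
  x <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("g", 1:3), NULL))
  x[2, ] <- 5
  expect_warning(s <- correlation_similarity(x), "constant")
  expect_equal(rownames(s), c("g1", "g3"))
  expect_error(correlation_similarity(x[, 1:3]), "4 samples")
})

test_that("a perfect power-law degree sequence has signed fit index 1", {
  # bins fall exactly on log-spaced points with log-linear frequencies
  k <- rep(c(10, 20, 40, 80), times = c(1000, 100, 10, 1))
  expect_equal(suppressWarnings(scale_free_fit(k, n_bins = 10)), 1,
               tolerance = 1e-12)
  # increasing frequency flips the sign
  k_inc <- rep(c(10, 20, 40, 80), times = c(1, 10, 100, 1000))
  expect_equal(suppressWarnings(scale_free_fit(k_inc, n_bins = 10)), -1,
               tolerance = 1e-12)
})

test_that("degenerate degree distributions are rejected", {
  expect_error(scale_free_fit(rep(4, 50)), "degenerate")
  expect_error(scale_free_fit(c(rep(1, 10), rep(10, 10)), n_bins = 10),
               "degenerate")
})

test_that("binned log-log regression matches an independent implementation", {
  set.seed(42)
  k <- rexp(500)^1.7 * 50
  oracle <- function(k, n_bins) {
    cuts <- seq(min(k), max(k), length.out = n_bins + 1)
    idx <- findInterval(k, cuts, rightmost.closed = TRUE, all.inside = TRUE)
    xs <- ys <- c()
    for (b in unique(idx)) {
      xs <- c(xs, mean(k[idx == b])); ys <- c(ys, sum(idx == b))
    }
    keep <- ys > 0 & xs > 0
    fit <- summary(lm(log10(ys[keep]) ~ log10(xs[keep])))
    unname(fit$r.squared * sign(-fit$coefficients[2, 1]))
  }
  expect_equal(scale_free_fit(k, 10), oracle(k, 10), tolerance = 1e-10)
})

test_that("soft threshold selection follows the smallest-qualifying rule", {
  b <- default_network()
  st <- b$sft
  fit <- st$fit
  qualifying <- fit$power[!is.na(fit$r2) & fit$r2 >= 0.8]
  expect_equal(st$power, min(qualifying))
  expect_true(st$reached_goal)
  # with r2_goal = 0, the first candidate whose signed fit is non-negative wins
  st0 <- suppressWarnings(
    pick_soft_threshold(b$similarity[1:200, 1:200], 2:6, r2_goal = 0))
  expect_equal(st0$power, min(st0$fit$power[!is.na(st0$fit$r2) &
                                              st0$fit$r2 >= 0]))
})

test_that("raising the power never increases adjacency entries", {
  s <- abs(random_adjacency(30, seed = 5))
  diag(s) <- 1
  for (p in 1:5) expect_true(all(s^(p + 1) <= s^p + 1e-15))
})

test_that("TOM matches hand-computed values on a 3-node path", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.5
  a[2, 3] <- a[3, 2] <- 0.5
  tom <- compute_tom(a)
  expect_equal(tom[1, 2], 0.5 / 1.0, tolerance = 1e-12)
  expect_equal(tom[1, 3], 0.25 / 1.5, tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))
  expect_equal(compute_tom(matrix(0, 4, 4))[upper.tri(diag(4))], rep(0, 6))
})

test_that("TOM equals the naive triple-loop definition on random matrices", {
  tom_oracle <- function(a) {
    n <- nrow(a)
    diag(a) <- 0
    out <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    out
  }
  for (seed in 1:3) {
    a <- random_adjacency(40, seed)
    expect_lt(max(abs(compute_tom(a) - tom_oracle(a))), 1e-10)
  }
})

test_that("TOM validates its input", {
  a <- random_adjacency(5, 1)
  a[1, 2] <- a[1, 2] + 0.1  # break symmetry
  expect_error(compute_tom(a), "symmetric")
  b <- random_adjacency(5, 1) * 3
  expect_error(compute_tom(b), "\\[0,1\\]")
})

block_tom <- function(sizes, within, between) {
  n <- sum(sizes)
  w <- matrix(between, n, n)
  start <- 1
  for (s in sizes) {
    idx <- start:(start + s - 1)
    w[idx, idx] <- within
    start <- start + s
  }
  diag(w) <- 1
  rownames(w) <- colnames(w) <- paste0("g", seq_len(n))
  w
}

test_that("two planted blocks are recovered as exactly two modules", {
  w <- block_tom(c(5, 5), 0.9, 0.05)
  part <- detect_modules(w, min_module_size = 3)
  expect_setequal(setdiff(unique(part), "grey"), c("turquoise", "blue"))
  expect_equal(unname(table(part[1:5]))[1], 5L)
  expect_length(unique(part[1:5]), 1)
  expect_length(unique(part[6:10]), 1)
})

test_that("clusters below the minimum size fall into grey", {
  w <- block_tom(c(5, 5), 0.9, 0.05)
  expect_true(all(detect_modules(w, min_module_size = 6) == "grey"))
  # boundary: a 99-gene cluster is grey at min size 100, a 105-gene one is not
  w2 <- block_tom(c(105, 99), 0.9, 0.02)
  part <- detect_modules(w2, min_module_size = 100)
  expect_true(all(part[1:105] == "turquoise"))
  expect_true(all(part[106:204] == "grey"))
  expect_error(detect_modules(w, min_module_size = 1), ">= 2")
})

test_that("module labels follow size rank", {
  w <- block_tom(c(4, 8, 6), 0.9, 0.05)
  part <- detect_modules(w, min_module_size = 3)
  expect_equal(unname(part[5]), "turquoise")   # size 8 block
  expect_equal(unname(part[13]), "blue")       # size 6 block
  expect_equal(unname(part[1]), "brown")       # size 4 block
})

test_that("module eigengenes match a principal-component oracle", {
  set.seed(9)
  x <- matrix(rnorm(4 * 10), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  part <- structure(setNames(rep("turquoise", 4), rownames(x)),
                    class = "module_partition")
  eg <- module_eigengene(x, part)
  # oracle: leading eigenvector of the sample covariance of z-scored genes
  z <- t(scale(t(x)))
  ev <- eigen(crossprod(z))$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  if (cor(ev, colMeans(x)) < 0) ev <- -ev
  expect_equal(unname(eg[, "turquoise"]), unname(ev), tolerance = 1e-8)
  expect_true(attr(eg, "var_explained")["turquoise"] >= 0)
  expect_true(attr(eg, "var_explained")["turquoise"] <= 1)
})

test_that("a module of identical genes has its shared profile as eigengene", {
  prof <- sin(seq_len(12))
  x <- matrix(rep(prof, each = 3), 3, 12, byrow = FALSE,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:12)))
  part <- structure(setNames(rep("blue", 3), rownames(x)),
                    class = "module_partition")
  eg <- module_eigengene(x, part)
  expect_equal(abs(cor(eg[, "blue"], prof)), 1, tolerance = 1e-8)
})

test_that("network export applies an inclusive weight threshold", {
  w <- matrix(c(1, 0.74, 0.75,
                0.74, 1, 0.76,
                0.75, 0.76, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  e <- export_network(w, 0.75)
  expect_equal(nrow(e), 2)
  expect_true(all(e$weight >= 0.75))
  expect_equal(nrow(export_network(w, 0)), 3)  # n(n-1)/2
  expect_error(export_network(w, 1 + 1e-9), "\\[0,1\\]")
})
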