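test_that("quantile comparison metrics vanish on identical samples", {
  set.seed(1)
  x <- rexp(500)
  qc <- quantile_compare(x, x, "peak_mean", 100)
  expect_equal(unname(qc$metrics), rep(0, 6))
})

test_that("a constant log-scale shift moves MAD/MAE/RMSE but not the PCC term", {
  set.seed(2)
  x <- rlnorm(2000, 7, 0.5)
  qc <- quantile_compare(x, x * exp(0.3), "library_size", 100)
  m <- qc$metrics
  expect_equal(unname(m["MAD"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(m["MAE"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(m["RMSE"]), 0.3, tolerance = 1e-9)
  expect_equal(unname(m["one_minus_PCC"]), 0, tolerance = 1e-9)
})

test_that("KS statistic matches theory and a brute-force sweep", {
  set.seed(3)
  u <- runif(20000); v <- runif(20000, 0.5, 1.5)
  expect_equal(ks_statistic(u, v), 0.5, tolerance = 0.02)

  for (i in 1:5) {
    a <- rnorm(30); b <- rnorm(25, 0.5)
    expect_equal(ks_statistic(a, b), ks_bruteforce(a, b))
  }
  expect_error(quantile_compare(u, v, n_quantiles = 1), "n_quantiles")
})

test_that("peak-pair correlations match hand-computed ranks", {
  x <- rbind(c(5, 3, 9, 1), c(2, 4, 6, 8), c(1, 1, 3, 2), c(0, 1, 0, 0))
  cm <- cm_from(x)
  out <- peak_pair_correlation(cm, cm, top_k = 3)
  expect_identical(out$real, out$synth)
  hand <- c(cor(x[3, ], x[1, ], method = "spearman"),
            cor(x[3, ], x[2, ], method = "spearman"),
            cor(x[1, ], x[2, ], method = "spearman"))
  expect_setequal(round(out$real, 10), round(hand, 10))
  expect_warning(peak_pair_correlation(cm, cm, top_k = 10), "clamped")
})

test_that("clustering scores are exact on hand cases", {
  expect_equal(unname(clustering_scores(c(0, 0, 1, 1), c(0, 0, 1, 1))),
               c(1, 1, 1))
  expect_equal(unname(clustering_scores(c(0, 0, 1, 1), c(1, 1, 0, 0))),
               c(1, 1, 1))   # permutation invariance
  ari <- clustering_scores(c(0, 0, 1, 1), c(0, 1, 0, 1))[["ARI"]]
  expect_equal(ari, -0.5)    # closed-form pair-counting value
})

# independent brute-force oracles: pair-counting ARI and permutation-model AMI
ari_bruteforce <- function(u, v) {
  n <- length(u)
  s <- a <- b <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    su <- u[i] == u[j]; sv <- v[i] == v[j]
    s <- s + (su && sv); a <- a + su; b <- b + sv
  }
  np <- choose(n, 2)
  exp_s <- a * b / np
  if ((a + b) / 2 == exp_s) return(1)
  (s - exp_s) / ((a + b) / 2 - exp_s)
}
mi_of <- function(u, v) {
  tab <- table(u, v); n <- sum(tab)
  nz <- which(tab > 0, arr.ind = TRUE)
  sum((tab[nz] / n) * log(n * tab[nz] / (rowSums(tab)[nz[, 1]] *
                                           colSums(tab)[nz[, 2]])))
}
ami_bruteforce <- function(u, v) {
  # EMI by exhaustive averaging over all permutations of v
  n <- length(v)
  perms <- function(x) if (length(x) == 1) list(x) else
    do.call(c, lapply(seq_along(x), function(i)
      lapply(perms(x[-i]), function(p) c(x[i], p))))
  emi <- mean(vapply(perms(seq_len(n)), function(p) mi_of(u, v[p]), numeric(1)))
  h <- function(z) { pr <- table(z) / length(z); -sum(pr * log(pr)) }
  den <- (h(u) + h(v)) / 2 - emi
  if (abs(den) < 1e-12) return(1)
  (mi_of(u, v) - emi) / den
}

test_that("ARI and AMI match exhaustive oracles on all partitions of 4 items", {
  parts4 <- list()   # all 15 set partitions of 4 items as label vectors
  for (a in 0:1) for (b in 0:2) for (cc in 0:3) {
    lab <- c(0, a, b, cc)
    key <- paste(as.integer(factor(lab, levels = unique(lab))), collapse = "")
    parts4[[key]] <- as.integer(strsplit(key, "")[[1]])
  }
  expect_length(parts4, 15L)
  for (u in parts4) for (v in parts4) {
    got <- clustering_scores(u, v)
    expect_equal(got[["ARI"]], ari_bruteforce(u, v), tolerance = 1e-12)
    expect_equal(got[["AMI"]], ami_bruteforce(u, v), tolerance = 1e-10)
  }
})

test_that("ARI and AMI match oracles on sampled partitions of 6 items", {
  set.seed(4)
  for (r in 1:15) {
    u <- sample(0:2, 6, replace = TRUE)
    v <- sample(0:2, 6, replace = TRUE)
    got <- clustering_scores(u, v)
    expect_equal(got[["ARI"]], ari_bruteforce(u, v), tolerance = 1e-12)
    expect_equal(got[["AMI"]], ami_bruteforce(u, v), tolerance = 1e-10)
  }
})

test_that("homogeneity is 1 for pure clusters and 0 for a single cluster", {
  expect_equal(clustering_scores(c(0, 0, 1, 1), c(0, 1, 2, 3))[["Homo"]], 1)
  expect_equal(clustering_scores(c(0, 0, 1, 1), c(0, 0, 0, 0))[["Homo"]], 0)
  expect_error(clustering_scores(1:3, 1:4), "equal length")
})

test_that("miLISI separates disjoint data and mixes duplicated data", {
  ref <- fixture_ref(600, 150, n_types = 1, seed = 31)
  expect_gt(milisi(ref, ref), 1.9)   # duplicated matrix: perfect mixing

  set.seed(5)
  a <- matrix(rpois(600 * 150, 0.5), 600, 150)
  a[301:600, ] <- 0
  b <- matrix(rpois(600 * 150, 0.5), 600, 150)
  b[1:300, ] <- 0
  expect_lt(milisi(cm_from(a), cm_from(b)), 1.1)  # disjoint support

  # invariance to swapping the real/synthetic roles
  expect_equal(milisi(cm_from(a), cm_from(b)), milisi(cm_from(b), cm_from(a)),
               tolerance = 1e-6)
  expect_error(milisi(cm_from(a[, 1:20]), cm_from(b[, 1:20])), "perplexity")
})

test_that("miLISI of random label splits of one dataset is near 2", {
  ref <- fixture_ref(600, 300, n_types = 1, seed = 31)
  for (s in 1:5) {
    set.seed(s)
    idx <- sample(300, 150)
    left <- count_matrix(ref$counts[, idx])
    right <- count_matrix(ref$counts[, -idx])
    v <- milisi(left, right)
    expect_gte(v, 1.9); expect_lte(v, 2.0)
  }
})

test_that("interaction F1 matches closed forms", {
  hub <- hub_spec("h1", 1:66, 1:40)
  expect_equal(unname(interaction_f1(list(hub), list(1:40))), 1)
  f_all <- 2 * (40 / 66) / (1 + 40 / 66)
  expect_equal(unname(interaction_f1(list(hub), list(1:66))), f_all,
               tolerance = 1e-12)
  expect_equal(unname(interaction_f1(list(hub), list(200:300))), 0)
  expect_warning(f0 <- interaction_f1(list(hub), list()), "empty")
  expect_equal(unname(f0), 0)
})
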