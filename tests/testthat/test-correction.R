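test_that("raw parameter matrix is the PEM-CEM product", {
  P <- rbind(diag(2), 0)
  C <- matrix(1, 2, 2)
  m <- raw_param_matrix(P, C)
  expect_equal(m$values, P %*% C)
  expect_equal(m$stage, "raw")
  expect_true(all(raw_param_matrix(P, matrix(0, 2, 3))$values == 0))
  expect_error(raw_param_matrix(P, matrix(1, 3, 2)), "shape mismatch")
})

test_that("activations are positive, monotone and match closed forms", {
  m <- accessim:::param_matrix(matrix(c(0, -40, 40, 2), 2), "raw")
  sp <- activate(m, "softplus")
  expect_equal(sp$values[1, 1], log(2))
  expect_true(all(sp$values > 0))
  expect_equal(sp$values[1, 2], 40, tolerance = 1e-12)   # stable at large x

  ex <- suppressWarnings(activate(m, "exponential"))
  expect_equal(ex$values[1, 1], 1)
  expect_equal(ex$values[1, 2], exp(30))                 # clipped
  expect_warning(activate(m, "exponential"), "clipped 1")

  set.seed(1)
  x <- sort(rnorm(100, 0, 5))
  for (kind in c("softplus", "exponential")) {
    v <- suppressWarnings(activate(accessim:::param_matrix(matrix(x, 1), "raw"),
                                   kind))$values
    expect_true(all(diff(as.numeric(v)) >= 0))
  }
})

test_that("peak-wise correction rank-matches and rescales rows", {
  m <- accessim:::param_matrix(matrix(c(1, 3, 1, 1), 2), "activated")
  out <- correct_peakwise(m, c(8, 2))
  expect_equal(rowSums(out$values), c(2, 8))   # row 2 had the larger sum
  expect_equal(out$values[2, ] / sum(out$values[2, ]), c(0.75, 0.25))

  # targets equal to current sums: identity
  idn <- correct_peakwise(m, rowSums(m$values))
  expect_equal(idn$values, m$values)

  set.seed(2)
  big <- accessim:::param_matrix(matrix(rexp(200 * 30), 200), "activated")
  tg <- rexp(200, 0.1)
  cor_out <- correct_peakwise(big, tg)
  expect_equal(cor(rank(rowSums(big$values)), rank(rowSums(cor_out$values))), 1)
  expect_error(correct_peakwise(big, c(-1, tg[-1])), ">= 0")
})

test_that("cell-wise correction hits library and sparsity targets", {
  set.seed(3)
  # fixed point: columns are one shape at increasing scale, so both current
  # statistics are monotone in the scale and rank-matching returns each
  # cell its own targets
  w0 <- rexp(500)
  v <- outer(w0, seq(0.2, 4, length.out = 40))
  m <- accessim:::param_matrix(v, "peak_corrected")
  cur_lib <- colSums(v)
  cur_sp <- apply(v, 2, function(w) mean(1 - exp(-w)))
  fp <- correct_cellwise(m, cur_lib, cur_sp, cur_lib)
  expect_equal(colSums(fp$values), cur_lib, tolerance = 1e-9)
  expect_lt(max(abs(apply(fp$values, 2, function(w) mean(1 - exp(-w))) - cur_sp)),
            1e-3)

  scores <- rnorm(40)
  lib_t <- runif(40, 20, 900)
  sp_t <- runif(40, 0.2, 0.6)
  out <- correct_cellwise(m, lib_t, sp_t, scores)
  expect_equal(colSums(out$values), attr(out, "lib_targets"),
               tolerance = 1e-9)
  expect_equal(sum(out$values), sum(attr(out, "lib_targets")),
               tolerance = 1e-12)
  got_sp <- apply(out$values, 2, function(w) mean(1 - exp(-w)))
  free <- setdiff(seq_len(40), attr(out, "clamped_cells"))
  expect_lt(max(abs(got_sp[free] - attr(out, "sparsity_targets")[free])), 1e-3)
  # larger CEV score implies larger assigned library target
  expect_equal(order(attr(out, "lib_targets")), order(scores))
})

test_that("single-cell column solves the closed-form non-zero proportion", {
  m <- accessim:::param_matrix(matrix(c(1, 1), 2, 1), "peak_corrected")
  out <- correct_cellwise(m, lib_targets = 2, sparsity_targets = 1 - exp(-1),
                          cev_scores = 0)
  expect_equal(out$values[, 1], c(1, 1), tolerance = 1e-3)  # gamma = 1
  expect_equal(mean(1 - exp(-out$values[, 1])), 1 - exp(-1), tolerance = 1e-3)
})

test_that("unattainable sparsity targets are clamped with a warning", {
  m <- accessim:::param_matrix(matrix(rexp(100), 100, 1), "peak_corrected")
  expect_warning(out <- correct_cellwise(m, 5, 0.999, 0), "clamped")
  expect_equal(attr(out, "clamped_cells"), 1L)
  expect_equal(colSums(out$values), attr(out, "lib_targets"), tolerance = 1e-9)
})

test_that("Poisson sampling matches its mean parameters", {
  z <- accessim:::param_matrix(matrix(0, 10, 10), "final")
  expect_true(all(sample_counts_poisson(z)$counts == 0))

  set.seed(4)
  m4 <- accessim:::param_matrix(matrix(4, 250, 400), "final")
  cm <- sample_counts_poisson(m4)
  x <- as.matrix(cm$counts)
  expect_equal(mean(x), 4, tolerance = 0.05 / 4)
  expect_equal(var(as.numeric(x)), 4, tolerance = 0.1 / 4)

  bad <- accessim:::param_matrix(matrix(NaN, 2, 2), "final")
  expect_error(sample_counts_poisson(bad), "non-finite")
})

test_that("realized column sums concentrate around library targets", {
  set.seed(5)
  v <- matrix(rexp(400 * 50, 0.5), 400, 50)
  lib_t <- runif(50, 200, 2000)
  m <- correct_cellwise(accessim:::param_matrix(v, "peak_corrected"),
                        lib_t, runif(50, 0.3, 0.7), rnorm(50))
  cm <- sample_counts_poisson(m)
  got <- as.numeric(Matrix::colSums(cm$counts))
  tg <- attr(m, "lib_targets")
  expect_true(all(abs(got - tg) / tg < 3 / sqrt(tg)))
})

test_that("Bernoulli sampling emits the Poisson non-zero probability", {
  z <- accessim:::param_matrix(matrix(0, 5, 5), "final")
  expect_true(all(sample_counts_bernoulli(z)$counts == 0))
  big <- accessim:::param_matrix(matrix(30, 5, 5), "final")
  set.seed(6)
  expect_true(all(sample_counts_bernoulli(big)$counts == 1))

  m <- accessim:::param_matrix(matrix(log(2), 400, 250), "final")
  set.seed(7)
  cm <- sample_counts_bernoulli(m)
  expect_true(cm$binarized)
  expect_equal(mean(as.matrix(cm$counts)), 0.5, tolerance = 0.01 / 0.5)
})
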