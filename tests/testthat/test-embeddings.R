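test_that("homogeneous CEM has unit mean and the requested dispersion", {
  set.seed(1)
  tiny <- generate_homogeneous_cem(3, 50, sigma = 1e-9)
  expect_lt(max(abs(tiny - 1)), 1e-6)

  set.seed(2)
  m <- generate_homogeneous_cem(2, 10000, sigma = 0.5)
  expect_equal(mean(m), 1, tolerance = 0.02)
  expect_equal(sd(m), 0.5, tolerance = 0.04)

  set.seed(3); a <- generate_homogeneous_cem(4, 10, 0.5)
  set.seed(3); b <- generate_homogeneous_cem(4, 10, 0.5)
  expect_identical(a, b)
  expect_error(generate_homogeneous_cem(2, 10, sigma = 0), "sigma")
})

test_that("PEM zeroing fraction matches eta", {
  set.seed(4)
  expect_true(all(generate_pem(50, 6, eta = 1) == 0))
  p <- generate_pem(2000, 12, eta = 0.5)
  expect_equal(mean(p == 0), 0.5, tolerance = 0.02)
  p0 <- generate_pem(500, 12, eta = 0)
  expect_equal(sum(p0 == 0), 0)
  expect_error(generate_pem(10, 2, eta = 1.5), "eta")
})

test_that("CEV is standard normal of the embedding dimension", {
  set.seed(5)
  expect_length(generate_cev(12), 12L)
  v <- generate_cev(50000)
  expect_equal(mean(v), 0, tolerance = 0.02)
  expect_equal(sd(v), 1, tolerance = 0.02)
})

test_that("discrete centers recover the population covariance", {
  set.seed(6)
  H <- generate_discrete_centers(5, 5000, diag(5))
  expect_equal(unname(colMeans(H)), rep(1, 5), tolerance = 0.05)
  expect_equal(cor(H[, 1], H[, 2]), 0, tolerance = 0.05)

  for (rho in c(0.56, 0.78)) {
    S <- diag(3); S[1, 2] <- S[2, 1] <- rho
    set.seed(7)
    H <- generate_discrete_centers(3, 5000, S)
    expect_equal(cor(H[, 1], H[, 2]), rho, tolerance = 0.05)
  }
  bad <- matrix(c(1, 2, 2, 1), 2)   # eigenvalue -1
  expect_error(generate_discrete_centers(2, 10, bad), "positive semi-definite")
})

test_that("discrete CEM scatters cells around their population center", {
  set.seed(8)
  H <- matrix(rnorm(10 * 5), 10, 5)
  out <- generate_discrete_cem(H, rep(300, 5), sigma = 1e-9)
  expect_equal(out$C_hete[, 1], H[, 1], tolerance = 1e-6)
  expect_length(out$population, 1500L)
  expect_equal(as.integer(table(out$population)), rep(300L, 5))

  out2 <- generate_discrete_cem(H, rep(300, 5), sigma = 0.5)
  for (k in c(1, 3)) {
    cols <- which(out2$population == sprintf("pop_%d", k))
    dev <- rowMeans(out2$C_hete[, cols]) - H[, k]
    expect_true(all(abs(dev) < 4 * 0.5 / sqrt(300)))   # CLT bound
  }
  expect_error(generate_discrete_cem(H, c(0, rep(300, 4)), 0.5), "positive")
})

test_that("cells are placed on branches in proportion to length", {
  tr <- parse_newick("(A:1,B:3);")
  pl <- place_cells_on_tree(tr, 40)
  expect_equal(as.integer(table(pl$branch)[c("A", "B")]), c(10L, 30L))

  single <- place_cells_on_tree(parse_newick("(A:2);"), 4)
  expect_equal(single$position, c(0.5, 1.0, 1.5, 2.0))
  expect_equal(single$pseudotime, single$position)
  expect_equal(single$predecessor, c(0L, 1L, 2L, 3L))

  expect_error(place_cells_on_tree(tr, 1), "branches")
})

test_that("pseudotime never exceeds the tree height (graph oracle)", {
  set.seed(10)
  for (i in 1:4) {
    phy <- ape::rtree(5 + i, br = function(n) runif(n, 0.2, 2))
    height <- max(ape::node.depth.edgelength(phy))   # independent oracle
    pl <- place_cells_on_tree(parse_newick(ape::write.tree(phy)), 100)
    expect_lte(max(pl$pseudotime), height + 1e-9)
    # pseudotime non-decreasing along every predecessor chain
    ok <- pl$predecessor == 0 | pl$pseudotime >
      c(0, pl$pseudotime)[pl$predecessor + 1L] - 1e-12
    expect_true(all(ok))
  }
})

test_that("Brownian CEM follows the trajectory variance law", {
  tr <- parse_newick("(A:2);")
  pl <- place_cells_on_tree(tr, 8)
  set.seed(11)
  out <- generate_continuous_cem(pl, nhete = 8000, sigma = 0.5)
  dev <- sweep(out$C_hete, 1, out$root_value)
  v <- apply(dev, 2, var)
  expect_equal(v, pl$pseudotime, tolerance = 0.05)

  # sibling branches decorrelate after the split
  tr2 <- parse_newick("(A:1,B:1);")
  pl2 <- place_cells_on_tree(tr2, 10)
  set.seed(12)
  out2 <- generate_continuous_cem(pl2, nhete = 8000, sigma = 0.5)
  dev2 <- sweep(out2$C_hete, 1, out2$root_value)
  endA <- which(out2$branch == "A")[5]; endB <- which(out2$branch == "B")[5]
  expect_equal(cov(dev2[, endA], dev2[, endB]), 0, tolerance = 0.05)
})

test_that("assemble_cem stacks homogeneous rows first", {
  h <- matrix(1, 2, 10); e <- matrix(2, 10, 10)
  C <- assemble_cem(h, e)
  expect_equal(dim(C), c(12L, 10L))
  expect_equal(C[1:2, ], h)
  expect_identical(assemble_cem(h, NULL), h)
  expect_error(assemble_cem(h, matrix(0, 3, 9)), "same number of cells")
})
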