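test_that("squash matches its closed form and bounds lengths to [0, 1)", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- squash(c(3, 4))
  expect_equal(sqrt(sum(v^2)), 25 / 26, tolerance = 1e-7)
  expect_equal(v, c(3, 4) / 5 * 25 / 26, tolerance = 1e-7)
  # unit-norm input maps to length 1/2 exactly
  expect_equal(sqrt(sum(squash(c(1, 0))^2)), 0.5, tolerance = 1e-7)
  expect_error(squash(c(1, NaN)), "non-finite")
  # bounds and monotonicity of the length map
  lens <- seq(0.01, 50, length.out = 100)
  out_lens <- vapply(lens, function(L) sqrt(sum(squash(c(L, 0))^2)), numeric(1))
  expect_true(all(out_lens >= 0 & out_lens < 1))
  expect_true(all(diff(out_lens) > 0))
})

test_that("votes are per-pair matrix products", {
  u <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)  # 2 capsules of dim 3
  # identity weights replicate u over the upper index
  w_id <- array(0, c(2, 2, 3, 3))
  for (i in 1:2) for (j in 1:2) w_id[i, j, , ] <- diag(3)
  votes <- compute_votes(u, w_id)
  for (j in 1:2) expect_equal(votes[, j, ], u)
  # zero weights give zero votes
  expect_true(all(compute_votes(u, array(0, c(2, 2, 3, 3))) == 0))
  # random case against an explicit dot-product loop
  set.seed(1)
  w <- array(rnorm(2 * 2 * 3 * 4), c(2, 2, 3, 4))
  votes2 <- compute_votes(u, w)
  for (i in 1:2) for (j in 1:2) {
    expect_equal(votes2[i, j, ], as.vector(u[i, ] %*% w[i, j, , ]), tolerance = 1e-12)
  }
  expect_error(compute_votes(u, array(0, c(2, 2, 5, 4))), "dim 3")
})

test_that("routing reproduces a loop transcription of the procedure", {
  set.seed(2)
  votes <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  for (r in c(1, 3, 5)) {
    got <- dynamic_routing(votes, r = r)
    ref <- naive_routing(votes, r)
    expect_equal(got$v, ref$v, tolerance = 1e-10)
    expect_equal(got$state$couplings, ref$couplings, tolerance = 1e-10)
    expect_equal(got$state$logits, ref$logits, tolerance = 1e-10)
  }
  # larger toy case
  votes2 <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  got2 <- dynamic_routing(votes2, r = 3)
  ref2 <- naive_routing(votes2, 3)
  expect_equal(got2$v, ref2$v, tolerance = 1e-10)
})

test_that("couplings are uniform at r = 1 and always normalize over upper capsules", {
  set.seed(3)
  votes <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  r1 <- dynamic_routing(votes, r = 1)
  expect_true(all(abs(r1$state$couplings - 0.25) < 1e-12))
  # v_j = squash(sum of votes / J) at r = 1 (uniform couplings 1/J)
  for (j in 1:4) {
    expect_equal(r1$v[j, ], squash(colSums(votes[, j, ]) / 4), tolerance = 1e-10)
  }
  for (r in 1:4) {
    st <- dynamic_routing(votes, r = r)$state
    expect_true(all(abs(rowSums(st$couplings) - 1) < 1e-6))
  }
})

test_that("a single lower capsule routes its vote through the coupling softmax", {
  set.seed(4)
  # one route (J = 1): the single vote gets full coupling and is squashed
  v1 <- array(rnorm(1 * 1 * 4), c(1, 1, 4))
  for (r in 1:3) {
    expect_equal(dynamic_routing(v1, r = r)$v[1, ], squash(v1[1, 1, ]),
                 tolerance = 1e-10)
  }
  # several upper capsules split the unit coupling: v_j = squash(vote/J) at r = 1
  vJ <- array(rnorm(1 * 3 * 4), c(1, 3, 4))
  r1 <- dynamic_routing(vJ, r = 1)
  for (j in 1:3) expect_equal(r1$v[j, ], squash(vJ[1, j, ] / 3), tolerance = 1e-10)
})

test_that("identical votes keep the routing output parallel to the vote", {
  w <- c(2, -1, 0.5)
  votes <- array(rep(w, each = 6), c(6, 1, 3))  # all lower capsules agree
  for (r in 1:4) {
    v <- dynamic_routing(votes, r = r)$v[1, ]
    cosang <- sum(v * w) / sqrt(sum(v^2) * sum(w^2))
    expect_equal(cosang, 1, tolerance = 1e-9)
  }
})

test_that("the printed-variant routing defers the agreement update", {
  set.seed(5)
  votes <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  pr <- dynamic_routing(votes, r = 4, mode = "printed")
  # all iterations identical: output equals the single uniform-coupling pass
  one <- dynamic_routing(votes, r = 1, mode = "inloop")
  expect_equal(pr$v, one$v, tolerance = 1e-12)
  expect_error(dynamic_routing(votes, r = 0), "r must be >= 1")
})

test_that("margin loss matches hand-computed hinge terms", {
  # perfect configuration: true class above m+, others below m-
  expect_equal(margin_loss(c(0.95, 0.05, 0.02), c(1, 0, 0)), 0)
  # absent true class contributes (0.9 - 0)^2
  expect_equal(margin_loss(c(0, 0.05), c(1, 0)), 0.81)
  # confident wrong class contributes lambda * (1 - 0.1)^2
  expect_equal(margin_loss(c(0.95, 1), c(1, 0)), 0.5 * 0.81)
  # mixed batch: per-sample values
  L <- rbind(c(0, 0.05), c(0.95, 1))
  Tk <- rbind(c(1, 0), c(1, 0))
  expect_equal(margin_loss(L, Tk), c(0.81, 0.405))
  expect_error(margin_loss(c(0.5, 0.5), c(1, 1)), "one-hot")
  expect_error(margin_loss(c(0.5, 0.5), c(0.5, 0.5)), "one-hot")
})

test_that("primary capsules reshape convolutions into squashed capsule grids", {
  set.seed(6)
  # printed spatial chain: 32 -> 14 with kernel 5 stride 2; 12 types x 8D = 96 ch
  fmap <- array(runif(32 * 32 * 3), c(32, 32, 3))
  pc <- primary_capsule_forward(fmap, n_types = 12, dim = 8, kernel = 5, stride = 2)
  expect_equal(pc$grid, c(14, 14, 12))
  expect_equal(dim(pc$fmap_view), c(14, 14, 96))
  expect_equal(dim(pc$caps), c(14 * 14 * 12, 8))
  # 5 -> 2 with kernel 3 stride 2
  pc2 <- primary_capsule_forward(array(runif(25), c(5, 5, 1)),
                                 n_types = 2, dim = 4, kernel = 3, stride = 2)
  expect_equal(pc2$grid[1:2], c(2, 2))
  # capsule lengths in [0, 1)
  lens <- sqrt(rowSums(pc$caps^2))
  expect_true(all(lens >= 0 & lens < 1))
  expect_error(primary_capsule_forward(array(0, c(3, 3, 1)), 2, 4, 5, 2),
               "larger than input")
})

test_that("class capsules agree with the routing oracle on a toy case", {
  set.seed(7)
  caps <- matrix(rnorm(4 * 3), 4, 3)
  w <- array(rnorm(4 * 2 * 3 * 5), c(4, 2, 3, 5))
  got <- class_capsule_forward(caps, n_classes = 2, out_dim = 5, r = 3, weights = w)
  ref <- naive_routing(compute_votes(caps, w), 3)
  expect_equal(got$v, ref$v, tolerance = 1e-10)
  # single lower capsule, J upper: squashed scaled votes at r = 1
  one <- class_capsule_forward(matrix(rnorm(3), 1, 3), n_classes = 2, out_dim = 5,
                               r = 1, weights = array(rnorm(30), c(1, 2, 3, 5)))
  expect_equal(dim(one$v), c(2, 5))
})
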