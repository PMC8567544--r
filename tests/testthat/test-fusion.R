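test_that("lmf_transform reproduces hand-computed contractions", {
  # M=2, rank 1, out_dim 1, no appended constant:
  # w1 selects z1[1], w2 selects z2[2]; fused = 3 * 6 = 18
  f <- fusion_factors(
    list(array(c(1, 0), c(2, 1, 1)), array(c(0, 1), c(2, 1, 1))),
    bias = 0, append_one = FALSE
  )
  view <- list(matrix(c(3, 4), 1), matrix(c(5, 6), 1))
  expect_equal(drop(lmf_transform(view, f)), 18)
  expect_equal(drop(full_tensor_oracle(view, f)), 18)

  # an all-zero modality annihilates every product term: output = bias
  f2 <- fusion_factors(
    list(array(rnorm(6), c(2, 3, 1)), array(rnorm(6), c(2, 3, 1))),
    bias = c(7, 8, 9), append_one = FALSE
  )
  view2 <- list(matrix(0, 1, 2), matrix(c(1, 2), 1))
  expect_equal(drop(lmf_transform(view2, f2)), c(7, 8, 9))

  # rank 1, all-ones factors and inputs, no bias: every coordinate = d1 * d2
  d1 <- 3; d2 <- 4
  f3 <- fusion_factors(
    list(array(1, c(d1, 2, 1)), array(1, c(d2, 2, 1))),
    bias = c(0, 0), append_one = FALSE
  )
  view3 <- list(matrix(1, 2, d1), matrix(1, 2, d2))
  expect_equal(unname(full_tensor_oracle(view3, f3)),
               matrix(d1 * d2, 2, 2))
  expect_equal(lmf_transform(view3, f3), full_tensor_oracle(view3, f3))

  # zero factors leave only the bias
  f4 <- fusion_factors(list(array(0, c(2, 2, 2))), bias = c(1, -1),
                       append_one = FALSE)
  expect_equal(unname(full_tensor_oracle(list(matrix(rnorm(4), 2)), f4)),
               matrix(c(1, -1), 2, 2, byrow = TRUE))
})

test_that("factored fusion equals the full tensor contraction on random instances", {
  set.seed(202)
  for (rep in 1:200) {
    M <- sample(1:3, 1)
    inst <- random_fusion_instance(M, append_one = rep %% 2 == 0)
    a <- lmf_transform(inst$view, inst$f)
    b <- full_tensor_oracle(inst$view, inst$f)
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("fusion is linear in one modality when append_one is off", {
  set.seed(9)
  inst <- random_fusion_instance(2, append_one = FALSE)
  bias <- matrix(inst$f$bias, 3, inst$f$out_dim, byrow = TRUE)
  v1 <- inst$view
  v2 <- inst$view
  v2[[1]] <- 2 * v2[[1]]
  base <- lmf_transform(v1, inst$f) - bias   # linear part only
  expect_equal(lmf_transform(v2, inst$f) - bias, 2 * base)
  v3 <- inst$view
  v3[[1]] <- v1[[1]] + v2[[1]]
  expect_equal(lmf_transform(v3, inst$f) - bias, 3 * base)
})

test_that("initialization is seed-deterministic and well-formed", {
  f1 <- init_fusion_factors(c(5, 7), rank = 3, out_dim = 4, seed = 99)
  f2 <- init_fusion_factors(c(5, 7), rank = 3, out_dim = 4, seed = 99)
  f3 <- init_fusion_factors(c(5, 7), rank = 3, out_dim = 4, seed = 100)
  expect_identical(f1, f2)
  expect_false(identical(f1$factors[[1]], f3$factors[[1]]))
  expect_s3_class(f1, "fusion_factors")
  expect_identical(dim(f1$factors[[1]]), c(6L, 4L, 3L))  # width 5 + constant
  expect_identical(f1$bias, rep(0, 4))

  # passthrough: a term owned by the other modality contributes exactly 1
  fp <- init_fusion_factors(c(5, 7), rank = 2, out_dim = 3, seed = 1,
                            method = "passthrough")
  expect_equal(fp$factors[[2]][, , 1], rbind(matrix(0, 7, 3), 1))
  expect_error(init_fusion_factors(c(5), 2, 3, 1, append_one = FALSE,
                                   method = "passthrough"), "append_one")
})

test_that("fuse_entity_side is row-permutation equivariant and validates ids", {
  set.seed(21)
  n <- 6
  ids <- paste0("e", 1:n)
  mk_sim <- function() {
    a <- matrix(runif(n * n), n)
    s <- (a + t(a)) / 2
    diag(s) <- 1
    dimnames(s) <- list(ids, ids)
    s
  }
  s1 <- mk_sim(); s2 <- mk_sim()
  f <- init_fusion_factors(c(n, n), rank = 2, out_dim = 3, seed = 5)
  base <- fuse_entity_side(list(s1, s2), f)
  expect_identical(rownames(base), ids)

  # permuting entities permutes output rows identically (features stay put:
  # only the rows of the similarity matrices move)
  perm <- sample(n)
  out_p <- lmf_transform(list(s1[perm, ], s2[perm, ]), f)
  expect_equal(out_p, base[perm, ])

  s_bad <- s2[rev(seq_len(n)), ]
  expect_error(fuse_entity_side(list(s1, s_bad), f), "ids differ")
})

test_that("a single-modality side degenerates to a linear map plus bias", {
  set.seed(33)
  n <- 5
  s <- matrix(runif(n * n), n); s <- (s + t(s)) / 2; diag(s) <- 1
  dimnames(s) <- list(paste0("e", 1:n), paste0("e", 1:n))
  f <- init_fusion_factors(n, rank = 3, out_dim = 2, seed = 8,
                           append_one = FALSE)
  # sum the rank-1 maps into one matrix and compare to a plain product
  Wlin <- apply(f$factors[[1]], c(1, 2), sum)
  expect_equal(unname(fuse_entity_side(list(s), f)),
               unname(s %*% Wlin + matrix(f$bias, n, 2, byrow = TRUE)))
})

test_that("the oracle refuses oversized tensors and mismatched shapes are named", {
  inst <- random_fusion_instance(2)
  expect_error(full_tensor_oracle(inst$view, inst$f, cap = 1),
               "exceeds cap")
  bad_view <- inst$view
  bad_view[[2]] <- cbind(bad_view[[2]], 0)
  expect_error(lmf_transform(bad_view, inst$f), "modality 2")
})
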