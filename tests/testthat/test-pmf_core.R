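# Joint-pmf container and the classical Shannon measures.

test_that("joint_pmf validates its invariants", {
  df <- data.frame(X = c("0", "1"), Y = c("0", "1"))
  expect_s3_class(joint_pmf(df, c(0.5, 0.5)), "joint_pmf")
  expect_error(joint_pmf(df, c(0.5, 0.4)), "sum")
  expect_error(joint_pmf(df, c(1.2, -0.2)), "non-negative")
  expect_error(joint_pmf(data.frame(X = c("0", "0"), Y = c("1", "1")),
                         c(0.5, 0.5)), "duplicate")
  expect_error(joint_pmf(df, c(0.5, 0.5),
                         alphabets = list(X = "0", Y = c("0", "1"))),
               "missing from declared alphabet")
  # zero-probability states are retained under declared alphabets
  p <- joint_pmf(df, c(0.5, 0.5),
                 alphabets = list(X = c("0", "1"), Y = c("0", "1")))
  expect_equal(length(p$p), 4L)
  expect_equal(sum(p$p > 0), 2L)
})

test_that("marginalize reproduces the worked examples", {
  tbc <- named_distribution("two_bit_copy")
  expect_equal(marginalize(tbc, "X")$p, c(1 / 2, 1 / 2))
  keep_all <- marginalize(tbc, tbc$variables)
  expect_equal(keep_all$p, tbc$p)
  expect_equal(keep_all$states, tbc$states)
  expect_equal(marginalize(named_distribution("and"), "Z")$p, c(3 / 4, 1 / 4))
  expect_error(marginalize(tbc, "Q"), "unknown variable")
})

test_that("entropy is Shannon entropy in bits", {
  u <- joint_pmf(data.frame(X = c("0", "1")), c(0.5, 0.5))
  expect_equal(entropy(u), 1)
  d <- joint_pmf(data.frame(X = c("0", "1")), c(1, 0))
  expect_equal(entropy(d), 0)
  expect_equal(entropy(marginalize(named_distribution("sum"), "Z")), 1.5)
})

test_that("mutual information matches direct evaluation and is symmetric", {
  t3a <- named_distribution("common_cause_3var")
  expect_equal(mutual_information(t3a, "X", "Y"), 0.3112781, tolerance = 1e-6)
  expect_equal(mutual_information(t3a, "X", "Y"),
               mutual_information(t3a, "Y", "X"))
  ind <- joint_pmf(expand.grid(X = c("0", "1"), Y = c("0", "1"),
                               stringsAsFactors = FALSE), rep(1 / 4, 4))
  expect_equal(mutual_information(ind, "X", "Y"), 0)
  tbc <- named_distribution("two_bit_copy")
  expect_equal(mutual_information(tbc, c("X", "Y"), "Z"), 2)
  expect_error(mutual_information(tbc, c("X", "Y"), c("Y", "Z")), "disjoint")
})

test_that("conditional MI reproduces worked values and the chain rule", {
  xor <- named_distribution("xor")
  expect_equal(conditional_mutual_information(xor, "X", "Y", "Z"), 1)
  t3a <- named_distribution("common_cause_3var")
  expect_equal(conditional_mutual_information(t3a, "X", "Y", "Z"),
               0.1887219, tolerance = 1e-6)
  # conditioning on an independent dummy leaves MI unchanged
  w4 <- named_distribution("5b")
  expect_equal(conditional_mutual_information(w4, "X", "Z", "Y"),
               mutual_information(w4, "X", "Z"), tolerance = 1e-9)
  expect_error(conditional_mutual_information(t3a, "X", "Y", "X"), "disjoint")
})

test_that("interaction information is I(X;Y|Z) - I(X;Y)", {
  t3a <- named_distribution("common_cause_3var")
  expect_equal(interaction_information(t3a, "X", "Y", "Z"), -0.1225562,
               tolerance = 1e-6)
  expect_equal(interaction_information(named_distribution("xor"),
                                       "X", "Y", "Z"), 1)
  ind <- joint_pmf(expand.grid(X = c("0", "1"), Y = c("0", "1"),
                               Z = c("0", "1"), stringsAsFactors = FALSE),
                   rep(1 / 8, 8))
  expect_equal(interaction_information(ind, "X", "Y", "Z"), 0)
})

test_that("probability form and tensor form of MI agree", {
  for (nm in c("common_cause_3var", "reduced_or", "pwunq", "dyadic")) {
    pmf <- named_distribution(nm)
    ch <- channel_from_joint(pmf, "X", "Z")
    M <- pathpid:::.joint_matrix(pmf, "X", "Z")
    pz <- colSums(M)
    pos <- which(M > 0, arr.ind = TRUE)
    tensor_form <- sum(M[pos] * log2(ch$matrix[pos] / pz[pos[, 2]]))
    expect_lt(abs(mutual_information(pmf, "X", "Z") - tensor_form), 1e-12)
  }
})

test_that("chain rule and the multivariate bound hold on random systems", {
  for (pmf in systems_3[1:200]) {
    v <- pmf$variables
    i_xy_z <- mutual_information(pmf, v[1:2], v[3])
    expect_lt(abs(i_xy_z -
                  (mutual_information(pmf, v[1], v[3]) +
                   conditional_mutual_information(pmf, v[2], v[3], v[1]))),
              1e-9)
    expect_gte(i_xy_z + 1e-9, max(mutual_information(pmf, v[1], v[3]),
                                  mutual_information(pmf, v[2], v[3])))
  }
})

test_that("Shannon measures agree with the loop oracle", {
  for (pmf in systems_3[1:50]) {
    df <- o_table(pmf)
    v <- pmf$variables
    expect_lt(abs(entropy(pmf) - o_H(df, v)), 1e-12)
    expect_lt(abs(mutual_information(pmf, v[1], v[2]) -
                  o_mi(df, v[1], v[2])), 1e-12)
    expect_lt(abs(conditional_mutual_information(pmf, v[1], v[2], v[3]) -
                  o_cmi(df, v[1], v[2], v[3])), 1e-12)
  }
})
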