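# Redundancy, unique, synergy, Imin, the Eq-25-style diagnostic and axioms.

t3a <- named_distribution("common_cause_3var")

test_that("path_redundancy reproduces the worked values", {
  expect_equal(path_redundancy(named_distribution("two_bit_copy"),
                               c("X", "Y"), "Z"), 0)
  expect_equal(path_redundancy(t3a, c("X", "Y"), "Z"), 0.027119,
               tolerance = 1e-6)
  # the quoted value is the binding minimum of the two permutation paths
  expect_equal(path_mutual_information(t3a, c("Y", "X", "Z")), 0.1225562,
               tolerance = 1e-6)
  expect_equal(path_redundancy(named_distribution("triadic"),
                               c("X", "Y"), "Z"), 1, tolerance = 1e-9)
  # single source: self-redundancy via the noiseless self-path
  expect_equal(path_redundancy(t3a, list("X"), "Z"),
               mutual_information(t3a, "X", "Z"), tolerance = 1e-12)
})

test_that("unique information follows I = U + R", {
  pw <- named_distribution("pwunq")
  expect_equal(unique_information(pw, "X", list("Y"), "Z"), 0.5,
               tolerance = 1e-9)
  b5 <- named_distribution("5b")
  expect_equal(unique_information(b5, "Y", list("X"), "Z"), 1,
               tolerance = 1e-9)
  expect_equal(unique_information(b5, "X", list("Y"), "Z"), 0.5,
               tolerance = 1e-9)
  # distal source of a chain has no unique information under strict pruning
  mk <- chains_3[[2]]
  expect_equal(unique_information(mk, "X", list("Y"), "Z", strict = TRUE), 0,
               tolerance = 1e-9)
})

test_that("synergy is the additivity remainder", {
  expect_equal(synergy(named_distribution("xor"), c("X", "Y"), "Z"), 1,
               tolerance = 1e-9)
  expect_equal(synergy(named_distribution("and"), c("X", "Y"), "Z"),
               0.1887219, tolerance = 1e-6)
  expect_lt(synergy(t3a, c("X", "Y"), "Z"), 0)
  expect_error(synergy(t3a, list("X"), "Z"), "exactly two")
})

test_that("decompose orchestrates the full two-source decomposition", {
  d <- decompose(named_distribution("reduced_or"), c("X", "Y"), "Z")
  expect_equal(round(d$S, 2), 0.40)
  expect_equal(d$R + sum(d$U) + d$S, d$total, tolerance = 1e-9)
  tb <- decompose(named_distribution("two_bit_copy"), c("X", "Y"), "Z")
  expect_equal(tb$R, 0)
  expect_equal(unname(tb$U), c(1, 1))
  expect_equal(tb$S, 0, tolerance = 1e-9)
  expect_equal(nrow(tb$paths_used), 0L)
  # identity property: target = join of the sources
  did <- decompose(t3a, c("X", "Y"), c("X", "Y"))
  expect_equal(did$R, mutual_information(t3a, "X", "Y"), tolerance = 1e-9)
  expect_error(decompose(t3a, c("X", "Z"), "Z"), "target")
})

test_that("negative synergy is flagged, not raised", {
  d <- decompose(t3a, c("X", "Y"), "Z")
  expect_true(d$negative_synergy)
  expect_equal(d$S - d$R, interaction_information(t3a, "X", "Y", "Z"),
               tolerance = 1e-9)
})

test_that("the divergence diagnostic separates indirect and copy cases", {
  # Y-Z is cascade-explained through X in the common-cause system
  diag1 <- unique_eq25_diagnostic(t3a, "Y", "Z")
  expect_equal(unname(diag1["indirect_path"]), 0, tolerance = 1e-9)
  # Y an exact relabeling of X: the copy divergence vanishes, and B = C
  cp <- copy_system()
  diag2 <- unique_eq25_diagnostic(cp, "Y", "Z")
  expect_equal(unname(diag2["copy"]), 0, tolerance = 1e-9)
  expect_equal(unname(diag2["indirect_path"]), 0, tolerance = 1e-9)
  expect_error(unique_eq25_diagnostic(systems_4_full[[1]], "X", "Z"),
               "three-variable")
})

test_that("imin matches the classical reference values", {
  expect_equal(imin(named_distribution("two_bit_copy"), c("X", "Y"), "Z"), 1,
               tolerance = 1e-9)
  expect_equal(imin(named_distribution("xor"), c("X", "Y"), "Z"), 0,
               tolerance = 1e-12)
  expect_equal(imin(t3a, list("X"), "Z"), mutual_information(t3a, "X", "Z"),
               tolerance = 1e-12)
})

test_that("redundancy lattices have the right shape", {
  l2 <- build_lattice(2)
  expect_length(l2$nodes, 4L)
  expect_setequal(l2$labels, c("{1}{2}", "{1}", "{2}", "{12}"))
  bottom <- l2$labels[l2$order[1]]
  expect_equal(bottom, "{1}{2}")
  expect_true(l2$leq["{1}{2}", "{1}"])
  expect_true(l2$leq["{1}", "{12}"])
  expect_false(l2$leq["{1}", "{2}"])
  expect_length(build_lattice(3)$nodes, 18L)
  expect_error(build_lattice(4), "supported")
})

test_that("Moebius inversion reproduces the printed atom tables", {
  l2 <- build_lattice(2)
  expect_equal(unname(moebius_atoms(l2, c("{1}{2}" = 0, "{1}" = 0, "{2}" = 0,
                                          "{12}" = 1))[c("{1}{2}", "{1}",
                                                         "{2}", "{12}")]),
               c(0, 0, 0, 1))
  expect_equal(unname(moebius_atoms(l2, c("{1}{2}" = 0, "{1}" = 0.5,
                                          "{2}" = 0.5, "{12}" = 1))[
                 c("{1}{2}", "{1}", "{2}", "{12}")]),
               c(0, 0.5, 0.5, 0))
  # constant cumulative values collapse onto the bottom atom
  at <- moebius_atoms(l2, rep(0.3, 4))
  expect_equal(unname(at["{1}{2}"]), 0.3)
  expect_equal(sum(abs(at)) - 0.3, 0)
})

test_that("Moebius re-summation is exact on random values for both lattices", {
  for (n in 2:3) {
    lat <- build_lattice(n)
    set.seed(42 + n)
    for (rep in 1:20) {
      vals <- runif(length(lat$nodes))
      atoms <- moebius_atoms(lat, vals)
      resum <- vapply(seq_along(lat$nodes), function(i)
        sum(atoms[lat$leq[, i]]), numeric(1))
      expect_lt(max(abs(resum - unname(vals))), 1e-12)
    }
  }
})

test_that("lattice cumulative values are monotone along the order", {
  lat <- build_lattice(2)
  for (pmf in systems_3[1:50]) {
    v <- pmf$variables
    vals <- lattice_values(pmf, list(v[1], v[2]), v[3], lattice = lat)
    for (i in seq_along(vals)) for (j in seq_along(vals))
      if (lat$leq[i, j]) expect_lte(vals[i], vals[j] + 1e-9)
  }
})

test_that("verify_axioms passes on the benchmark fixtures", {
  for (nm in c("common_cause_3var", "reduced_or", "pwunq", "and", "xor",
               "dyadic", "triadic", "5b")) {
    rep <- verify_axioms(named_distribution(nm), c("X", "Y"), "Z")
    expect_true(all(rep$holds), label = nm)
  }
})

test_that("generalized self-redundancy holds for relabeled sources", {
  cp <- copy_system() # Y is a bijective relabeling of X
  expect_equal(path_redundancy(cp, c("X", "Y"), "Z"),
               mutual_information(cp, "X", "Z"), tolerance = 1e-9)
  # Corollary: with equivalent X and Y the two mixed redundancies agree
  expect_equal(path_redundancy(cp, c("Z", "Y"), "X"),
               path_redundancy(cp, c("Z", "X"), "Y"), tolerance = 1e-9)
})
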