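test_that("structural reduction handles full-rank, moiety and cycle cases", {
  # plain chain: no conservation, L = identity
  N <- matrix(c(-1, 1, 0, 0, -1, 1), nrow = 3,
              dimnames = list(c("X0", "A", "X1"), c("R1", "R2")))
  net <- stm_network(N, external = c("X0", "X1"))
  red <- reduce_network(net)
  expect_equal(red$L, diag(1), ignore_attr = TRUE)
  expect_equal(red$N_ind, red$N_int)
  expect_equal(nrow(red$G), 0)

  # ATP/ADP moiety pair: one conservation relation, G proportional to (1,1)
  fm <- make_fixture("moiety_cycle")
  redm <- reduce_network(fm$network)
  expect_equal(nrow(redm$N_ind), 1)
  expect_equal(nrow(redm$G), 1)
  expect_equal(unname(redm$G[1, 1] / redm$G[1, 2]), 1, tolerance = 1e-12)
  expect_lt(max(abs(redm$G %*% redm$N_int)), 1e-12)

  # bypass network: 5 reactions, 3 internal metabolites -> kernel dim 2
  fb <- make_fixture("bypass")
  redb <- reduce_network(fb$network)
  expect_equal(nrow(redb$N_ind), 3)
  expect_equal(ncol(redb$K), 2)
  expect_lt(max(abs(redb$N_int %*% redb$K)), 1e-12)
})

test_that("L N_ind reproduces N_int and rank-nullity holds for random stoichiometries", {
  set.seed(11)
  for (rep in 1:20) {
    n_m <- sample(2:6, 1); n_r <- sample(2:8, 1)
    N <- matrix(sample(-2:2, n_m * n_r, replace = TRUE), n_m, n_r)
    keep <- colSums(abs(N)) > 0
    if (sum(keep) < 1) next
    N <- N[, keep, drop = FALSE]
    ext <- rep(FALSE, n_m)
    net <- stm_network(N, external = ext)
    red <- reduce_network(net)
    expect_lt(max(abs(red$L %*% red$N_ind - red$N_int)), 1e-12)
    # brute-force rank via base qr on the exact integer matrix
    r <- qr(N)$rank
    expect_equal(nrow(red$N_ind), r)
    expect_equal(nrow(red$G), n_m - r)
    expect_equal(ncol(red$K), ncol(N) - r)
  }
})

test_that("reduction refuses a network without dynamic metabolites", {
  N <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  net <- stm_network(N, external = c("A", "B"))
  expect_error(reduce_network(net), "no dynamic metabolites")
})

test_that("Wegscheider check detects inconsistent cycles", {
  # triangle A->B->C->A: kernel is (1,1,1)
  N <- matrix(c(-1, 1, 0, 0, -1, 1, 1, 0, -1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("R1", "R2", "R3")))
  net <- stm_network(N)
  ok <- wegscheider_check(net, log(c(2, 3, 1 / 6)))
  expect_true(ok$pass)
  expect_lt(ok$max_violation, 1e-12)
  bad <- wegscheider_check(net, log(c(2, 3, 1)))
  expect_false(bad$pass)
  expect_equal(bad$max_violation, log(6), tolerance = 1e-10)

  # acyclic chain: empty kernel, trivially consistent
  fc <- make_fixture("linear_chain", n = 2)
  res <- wegscheider_check(fc$network, c(5, -3))
  expect_true(res$pass)
  expect_equal(res$max_violation, 0)
})

test_that("equilibrium constants from chemical potentials are consistent", {
  N <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  net <- stm_network(N)
  expect_equal(unname(keq_from_mu0(net, c(A = 0, B = 0))), 0)
  expect_equal(unname(keq_from_mu0(net, c(A = 10, B = 7.521), RT = 2.479)), 1,
               tolerance = 1e-12)
  expect_error(keq_from_mu0(net, c(A = 1, B = NA)), "B")

  # gradient fields have zero circulation: always Wegscheider-consistent
  set.seed(4)
  for (rep in 1:10) {
    fx <- make_fixture("random", n_met = 4, n_rxn = 6, seed = rep)
    mu0 <- rnorm(length(fx$network$metabolites), 0, 20)
    lk <- keq_from_mu0(fx$network, mu0)
    expect_true(wegscheider_check(fx$network, lk)$pass)
  }
})

test_that("network validation rejects malformed inputs", {
  N <- matrix(c(-1, 1, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("R1", "R2")))
  expect_error(stm_network(N), "all-zero reaction column")
  N2 <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  expect_error(stm_network(N2, external = "C"), "unknown external")
  expect_error(
    stm_network(N2, regulation = data.frame(reaction = "R9", metabolite = "A",
                                            kind = "inhibitor")),
    "unknown reaction")
  expect_error(
    stm_network(N2, regulation = data.frame(reaction = "R1", metabolite = "A",
                                            kind = "blocker")),
    "activator")
})
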