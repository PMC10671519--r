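test_that("block probabilities match the reference table at mu = 1.56 and 1.5", {
  bp <- block_probabilities(1.56)
  expect_equal(round(bp$probability, 3), c(0.153, 0.238, 0.238, 0.371),
               tolerance = 0)
  bp15 <- block_probabilities(monomer_ratio(1.5, exact = "3/2"))
  expect_equal(round(bp15$probability, 2), c(0.16, 0.24, 0.24, 0.36))
  expect_equal(sum(bp15$probability), 1)
  expect_equal(bp15$num / bp15$den, c(4, 6, 6, 9) / 25)
})

test_that("cell-class probabilities match the reference table", {
  cp <- cell_probabilities(1.56)
  expect_equal(round(cp$probability, 4),
               c(0.0233, 0.1453, 0.1133, 0.1133, 0.1133, 0.3536, 0.1379))
  cp15 <- cell_probabilities(monomer_ratio(1.5, exact = "3/2"))
  expect_equal(round(cp15$probability, 4),
               c(0.0256, 0.1536, 0.1152, 0.1152, 0.1152, 0.3456, 0.1296))
  # exact fraction for the nucleation cell
  expect_equal(unname(cp15$num[1]), 16)
  expect_equal(unname(cp15$den[1]), 625)
  expect_identical(cell_classes()$multiplicity, c(1L, 4L, 2L, 2L, 2L, 4L, 1L))
  expect_equal(sum(cell_classes()$multiplicity), 16)
})

test_that("limits behave: mu -> 0 gives pure-G blocks; mu <= 0 errors", {
  bp <- block_probabilities(1e-12)
  expect_equal(bp$probability[bp$block == "GG"], 1, tolerance = 1e-9)
  expect_error(monomer_ratio(0), "mu")
  expect_error(monomer_ratio(-1), "mu")
})

test_that("occupancy reproduces the closed-form predictions at mu = 1.56", {
  mu <- 1.56
  expect_equal(round_half_up(occupancy(mu, preference_sets("Ba"))), 0.63)
  expect_equal(round_half_up(occupancy(mu, preference_sets("Sr"))), 0.64)
  expect_equal(round_half_up(occupancy(mu, preference_sets("Ca"))), 0.28)
  expect_equal(round_half_up(100 * occupancy(mu, preference_sets()$GG_only), 1),
               2.3)
  # closed forms as polynomials in mu
  expect_equal(occupancy(mu, preference_sets("Ba")),
               (1 + 2 * mu^2 + 4 * mu^3 + mu^4) / (1 + mu)^4)
  expect_equal(occupancy(mu, preference_sets("Sr")),
               (1 + 4 * mu + 2 * mu^2 + 4 * mu^3) / (1 + mu)^4)
  expect_equal(occupancy(mu, preference_sets("Ca")),
               (1 + 4 * mu + 2 * mu^2) / (1 + mu)^4)
  # all seven classes -> 1; empty set -> 0; unknown label -> error
  expect_equal(occupancy(mu, cell_classes()$label), 1)
  expect_equal(occupancy(mu, character(0)), 0)
  expect_error(occupancy(mu, "GG-XX"), "unknown cell class")
})

test_that("shared preference sets give identical occupancies for all mu", {
  # Zn uses the Ba set and Ni the Ca set: the printed closed forms repeat
  for (mu in c(0.3, 0.8, 1.5, 1.56, 4.2)) {
    expect_identical(occupancy(mu, preference_sets("Zn")),
                     occupancy(mu, preference_sets("Ba")))
    expect_identical(occupancy(mu, preference_sets("Ni")),
                     occupancy(mu, preference_sets("Ca")))
  }
})

test_that("occupancy is monotone under preference-set inclusion (property)", {
  set.seed(7)
  labels <- cell_classes()$label
  for (i in 1:20) {
    mu <- stats::runif(1, 0.1, 10)
    sub <- sample(labels, sample(0:6, 1))
    extra <- sample(setdiff(labels, sub), 1)
    expect_lt(occupancy(mu, sub), occupancy(mu, c(sub, extra)))
  }
})

test_that("enumeration oracle equals closed forms exactly in rational mode", {
  set.seed(11)
  for (i in 1:50) {
    p <- sample(1:30, 1); q <- sample(1:30, 1)
    ratio <- monomer_ratio(p / q, exact = c(p, q))
    or <- enumerate_cells_oracle(ratio)
    cf <- cell_probabilities(ratio)
    expect_identical(or$num, cf$num)
    expect_identical(or$den, cf$den)
    expect_identical(or$multiplicity, cf$multiplicity)
    # normalization is exact: sum of unreduced numerators = (p + q)^4
    expect_equal(sum(or$probability), 1, tolerance = 1e-12)
  }
})

test_that("oracle at mu = 1 gives the uniform multiplicity split", {
  or <- enumerate_cells_oracle(monomer_ratio(1, exact = c(1, 1)))
  expect_equal(or$num / or$den, c(1, 4, 2, 2, 2, 4, 1) / 16)
})

test_that("cell probabilities factor over ordered block pairs (consistency)", {
  # each class mass equals the sum over its ordered configurations of the
  # product of single-chain block probabilities
  for (mu in c(0.37, 1.56, 2.5)) {
    bp <- block_probabilities(mu)
    p <- stats::setNames(bp$probability, bp$block)
    expected <- c(
      "GG-GG" = p[["GG"]]^2,
      "GG-GM/GG-MG" = 2 * p[["GG"]] * p[["GM"]] + 2 * p[["GG"]] * p[["MG"]],
      "GG-MM" = 2 * p[["GG"]] * p[["MM"]],
      "GM-GM" = p[["GM"]]^2 + p[["MG"]]^2,
      "GM-MG" = 2 * p[["GM"]] * p[["MG"]],
      "MM-GM/MM-MG" = 2 * p[["MM"]] * p[["GM"]] + 2 * p[["MM"]] * p[["MG"]],
      "MM-MM" = p[["MM"]]^2
    )
    cp <- cell_probabilities(mu)
    expect_equal(stats::setNames(cp$probability, cp$label), expected,
                 tolerance = 1e-12)
  }
})

test_that("probabilities normalize for arbitrary mu (property)", {
  set.seed(3)
  for (mu in stats::runif(25, 0.05, 20)) {
    expect_equal(sum(block_probabilities(mu)$probability), 1, tolerance = 1e-12)
    expect_equal(sum(cell_probabilities(mu)$probability), 1, tolerance = 1e-12)
  }
})

test_that("rationalize_mu returns continued-fraction best approximations", {
  expect_equal(rationalize_mu(1.56, 2), c(num = 3, den = 2))
  expect_equal(rationalize_mu(1.56, 25), c(num = 39, den = 25))
  expect_equal(rationalize_mu(2.0, 10), c(num = 2, den = 1))
  expect_equal(rationalize_mu(pi, 7), c(num = 22, den = 7))
  expect_equal(rationalize_mu(0.5, 10), c(num = 1, den = 2))
  # optimality: no fraction with denominator <= N is closer
  for (mu in c(1.56, exp(1), 0.7321)) {
    for (N in c(3, 10, 40)) {
      best <- rationalize_mu(mu, N)
      errs <- abs(outer(1:(ceiling(mu) * N + 1), 1:N, "/") - mu)
      expect_lte(abs(best["num"] / best["den"] - mu), min(errs) + 1e-12)
    }
  }
})

test_that("monomer_ratio validates its exact fraction", {
  expect_error(monomer_ratio(1.56, exact = "3/2"), "does not equal")
  r <- monomer_ratio(1.56, exact = "39/25")
  expect_equal(r$p_m + r$p_g, 1)
  expect_equal(r$p_m, 1.56 / 2.56)
})
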