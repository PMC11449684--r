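test_that("pointwise values match the defining formulas", {
  expect_equal(activate(activation_spec("relu"), -2), 0)
  expect_equal(activate(activation_spec("relu"), 3.5), 3.5)
  expect_equal(activate(activation_spec("softsign"), 1), 0.5)
  expect_equal(activate(activation_spec("softsign"), -1), -0.5)
  rs <- activation_spec("rectified_softsign")
  expect_equal(activate(rs, c(-3, 1, 3)), c(0, 0.5, 0.75))
  expect_equal(activate(activation_spec("swish"), 0), 0)
  expect_equal(activate(activation_spec("elu"), -1), exp(-1) - 1)
  expect_equal(activate(activation_spec("leaky_relu", slope = 0.2), -5), -1)
  cl <- activation_spec("clipped_relu", ceiling = 6)
  expect_equal(activate(cl, c(-1, 3, 100)), c(0, 3, 6))
  expect_equal(activate(activation_spec("tanh"), 0.7), tanh(0.7))
})

test_that("gelu agrees with an independent erf evaluation", {
  skip_if_not_installed("pracma")
  # default: exact Gaussian-CDF form with erf(x / sqrt(2))
  g <- activation_spec("gelu")
  for (x in c(-2, -0.5, 0.3, 1, 2.7)) {
    expect_equal(activate(g, x),
                 0.5 * x * (1 + pracma::erf(x / sqrt(2))), tolerance = 1e-12)
  }
  # literal truncated-constant variant
  g707 <- activation_spec("gelu", gelu_constant = 0.707)
  expect_equal(activate(g707, 1), 0.5 * (1 + pracma::erf(0.707)),
               tolerance = 1e-12)
})

test_that("rectified softsign equals softsign composed with relu, both ways", {
  rs <- activation_spec("rectified_softsign")
  ss <- activation_spec("softsign")
  re <- activation_spec("relu")
  x <- seq(-20, 20, length.out = 4001)
  expect_equal(activate(rs, x), activate(ss, activate(re, x)))
  expect_equal(activate(rs, x), activate(re, activate(ss, x)))
})

test_that("every activation fixes zero and respects its range", {
  x <- seq(-30, 30, length.out = 6001)
  for (nm in list_activations()) {
    s <- activation_spec(nm)
    expect_identical(activate(s, 0), 0, info = nm)
    y <- activate(s, x)
    expect_false(anyNA(y), info = nm)
  }
  expect_true(all(activate(activation_spec("rectified_softsign"), x) >= 0))
  expect_true(all(activate(activation_spec("rectified_softsign"), x) < 1))
  ss <- activate(activation_spec("softsign"), x)
  expect_true(all(ss > -1 & ss < 1))
  cl <- activate(activation_spec("clipped_relu", ceiling = 4), x)
  expect_true(all(cl >= 0 & cl <= 4))
  expect_true(all(activate(activation_spec("swish"), x) >= -0.279))
})

test_that("the monotone family is non-decreasing on a dense grid", {
  x <- seq(-25, 25, length.out = 5001)
  for (nm in c("relu", "leaky_relu", "clipped_relu", "elu", "tanh",
               "softsign", "rectified_softsign")) {
    y <- activate(activation_spec(nm), x)
    expect_true(all(diff(y) >= 0), info = nm)
  }
})

test_that("limit behavior: softsign saturates at +-1, rectified softsign at 1", {
  ss <- activation_spec("softsign")
  expect_gt(activate(ss, 1e6), 1 - 1e-5)
  expect_lt(activate(ss, -1e6), -1 + 1e-5)
  expect_gt(activate(activation_spec("rectified_softsign"), 1e6), 1 - 1e-5)
})

test_that("closed-form derivatives match central finite differences", {
  h <- 1e-6
  for (nm in list_activations()) {
    s <- activation_spec(nm)
    for (x in kink_free_grid) {
      fd <- (activate(s, x + h) - activate(s, x - h)) / (2 * h)
      an <- activate_grad(s, x)
      expect_equal(an, fd, tolerance = 1e-5, info = paste(nm, "at", x))
    }
  }
})

test_that("kink conventions are the documented right-hand limits", {
  expect_equal(activate_grad(activation_spec("relu"), 0), 1)
  expect_equal(activate_grad(activation_spec("clipped_relu"), 0), 1)
  expect_equal(activate_grad(activation_spec("clipped_relu", ceiling = 5), 5), 0)
  expect_equal(activate_grad(activation_spec("rectified_softsign"), 0), 1)
  expect_equal(activate_grad(activation_spec("rectified_softsign"), 2), 1 / 9)
  expect_equal(activate_grad(activation_spec("relu"), 5), 1)
})

test_that("shapes are preserved and invalid input is rejected", {
  s <- activation_spec("swish")
  x <- array(rnorm(24), dim = c(2, 3, 4))
  expect_identical(dim(activate(s, x)), dim(x))
  expect_identical(dim(activate_grad(s, x)), dim(x))
  expect_error(activation_spec("prelu"), "unknown activation")
  expect_error(activate(s, c(1, NaN)), "finite")
  expect_error(activate(s, Inf), "finite")
  expect_error(activation_spec("elu", alpha = -1), "alpha")
  expect_error(activation_spec("clipped_relu", ceiling = 0), "ceiling")
})
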