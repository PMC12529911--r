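# Exact least-absolute-deviation fitting of the scaling parameters.

test_that("noiseless data generated from known parameters is recovered", {
  sp <- gen_species(40, seed = 11)
  truth <- preset_params("cd4")
  rset <- gen_reactions(sp, truth, 60, sigma = 0, seed = 12)
  fit <- fit_scaling_params(rset, free = c("a", "ap", "b", "bp"))
  expect_equal(fit$params$a, 0, tolerance = 1e-6)
  expect_equal(fit$params$ap, 0.42, tolerance = 1e-6)
  expect_equal(fit$params$b, 0.47, tolerance = 1e-6)
  expect_equal(fit$params$bp, 0.79, tolerance = 1e-6)
  expect_lt(fit$achieved, 1e-8)
})

test_that("the fixed-coefficient pattern recovers b and b'", {
  sp <- gen_species(30, seed = 31)
  rset <- gen_reactions(sp, preset_params("scs-star"), 50, sigma = 0,
                        seed = 32)
  fit <- fit_scaling_params(rset, free = c("b", "bp"), fixed = c(a = 0,
                                                                 ap = 0))
  expect_equal(fit$params$b, 0.44, tolerance = 1e-6)
  expect_equal(fit$params$bp, 1.13, tolerance = 1e-6)
  expect_equal(fit$params$a, 0)
  expect_equal(fit$params$ap, 0)
})

test_that("the two-parameter pattern recovers a and a'", {
  sp <- gen_species(35, seed = 41)
  rset <- gen_reactions(sp, preset_params("cd2"), 55, sigma = 0, seed = 42)
  fit <- fit_scaling_params(rset, free = c("a", "ap"), fixed = c(b = 0,
                                                                 bp = 0))
  expect_equal(fit$params$a, 2.89, tolerance = 1e-6)
  expect_equal(fit$params$ap, 1.38, tolerance = 1e-6)
})

test_that("an underdetermined training set interpolates with a warning", {
  sp <- gen_species(6, seed = 51)
  rset <- gen_reactions(sp, preset_params("cd4"), 1, sigma = 2, seed = 52)
  w <- capture_warnings(fit <- fit_scaling_params(rset, free = c("b",
                                                                 "bp")))
  expect_true(any(grepl("interpolating|rank", w)))
  expect_lt(fit$achieved, 1e-10)
})

test_that("a flat direction triggers a rank-deficiency warning", {
  # all species share r_D = 1, r_ND = 0: the 'a' column vanishes
  sp <- gen_species(20, seed = 61, r_d_range = c(1, 1))
  rset <- gen_reactions(sp, preset_params("scs"), 30, sigma = 0, seed = 62)
  expect_warning(fit <- fit_scaling_params(rset, free = c("a", "b", "bp")),
                 "rank")
  expect_false(is.null(fit$null_direction))
})

test_that("the solver agrees with multi-start Nelder-Mead", {
  sp <- gen_species(25, seed = 71)
  rset <- gen_reactions(sp, preset_params("cd4"), 80, sigma = 1.5, seed = 72)
  fit <- fit_scaling_params(rset, free = c("a", "ap", "b", "bp"))
  des <- cdscs:::fit_design(rset)
  obj <- function(th) mean(abs(des$X %*% th + des$const))
  set.seed(73)
  best <- Inf
  for (k in 1:6) {
    r <- optim(rnorm(4, c(0, 0.4, 0.5, 0.8), 0.5), obj,
               method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  expect_lte(fit$achieved, best + 1e-4)
  expect_equal(fit$achieved, best, tolerance = 1e-3)
})

test_that("objective surfaces are convex and bounded by the optimum", {
  sp <- gen_species(25, seed = 81)
  rset <- gen_reactions(sp, preset_params("scs-star"), 60, sigma = 1,
                        seed = 82)
  fit <- fit_scaling_params(rset, free = c("b", "bp"), fixed = c(a = 0,
                                                                 ap = 0))
  surf <- profile_objective(rset, "b", "bp", seq(0, 1, 0.1),
                            seq(0.8, 1.5, 0.1), fixed = c(a = 0, ap = 0))
  expect_true(all(surf >= fit$achieved - 1e-10))
  # midpoint convexity along random segments
  des <- cdscs:::fit_design(rset)
  obj <- function(th) mean(abs(des$X %*% th + des$const))
  set.seed(83)
  for (k in 1:25) {
    t1 <- rnorm(4); t2 <- rnorm(4)
    expect_lte(obj((t1 + t2) / 2), (obj(t1) + obj(t2)) / 2 + 1e-12)
  }
  expect_error(profile_objective(rset, "b", "b", 0:1, 0:1), "configuration")
})

test_that("estimates converge toward truth as the set grows", {
  sp <- gen_species(60, seed = 91)
  errs <- vapply(c(30, 100, 300), function(n) {
    rset <- gen_reactions(sp, preset_params("cd4"), n, sigma = 0.4,
                          seed = 92)
    fit <- fit_scaling_params(rset, free = c("ap", "b", "bp"),
                              fixed = c(a = 0))
    abs(fit$params$ap - 0.42) + abs(fit$params$b - 0.47) +
      abs(fit$params$bp - 0.79)
  }, 0)
  expect_lt(errs[3], errs[1])
})

test_that("the fit is invariant under reaction relabeling", {
  sp <- gen_species(20, seed = 95)
  rset <- gen_reactions(sp, preset_params("cd4"), 40, sigma = 1, seed = 96)
  fit1 <- fit_scaling_params(rset, free = c("b", "bp"), fixed = c(a = 0,
                                                                  ap = 0))
  rset2 <- rset
  rset2$reactions <- rev(rset2$reactions)
  fit2 <- fit_scaling_params(rset2, free = c("b", "bp"), fixed = c(a = 0,
                                                                   ap = 0))
  expect_equal(fit1$achieved, fit2$achieved, tolerance = 1e-10)
  expect_equal(fit1$params$b, fit2$params$b, tolerance = 1e-8)
})
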