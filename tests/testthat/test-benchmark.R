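# Reaction energies, error statistics and the multireference screen.

test_that("reaction energies convert stoichiometric sums to kcal/mol", {
  rx <- reaction("form", c(H2 = 1, H = -2), reference_energy = 0)
  e <- c(H = -0.5, H2 = -1.2)
  expect_equal(reaction_energy(rx, e), -0.2 * 627.509474, tolerance = 1e-10)
  expect_equal(reaction_energy(rx, e), -125.5018948, tolerance = 1e-6)
  # permutation of stoichiometry entries changes nothing
  rx2 <- reaction("form", c(H = -2, H2 = 1), 0)
  expect_equal(reaction_energy(rx2, e), reaction_energy(rx, e))
  expect_error(reaction_energy(rx, c(H = -0.5)), "lookup error.*H2")
  # identity reaction is not representable (needs both signs), but a single
  # species entry is allowed
  expect_silent(reaction("atom", c(H = 1), 10))
  expect_error(reaction("bad", c(A = 1, B = 2), 0), "positive and negative")
})

test_that("error statistics match hand evaluation", {
  r <- error_stats(c(1, -1, 2, -2, 2), subsets = c("A", "A", "B", "B", "B"),
                   dEavg = c(A = 28.42, B = 113.68))
  expect_equal(r$MAD, 1.6)
  expect_equal(r$MAX, 2)
  expect_equal(r$RMSD, sqrt(mean(c(1, 1, 4, 4, 4))))
  # (2*2*1 + 3*0.5*2)/5 = 1.4
  expect_equal(r$WTMAD2, 1.4, tolerance = 1e-12)
  # single subset at the reference weight: WTMAD2 equals MAD
  r2 <- error_stats(c(0.5, -1.5), subsets = "S", dEavg = c(S = 56.84))
  expect_equal(r2$WTMAD2, r2$MAD, tolerance = 1e-12)
  # constant magnitudes: MAD = MAX = RMSD
  r3 <- error_stats(c(2, -2, 2), subsets = "S", dEavg = c(S = 10))
  expect_equal(r3$MAD, r3$MAX)
  expect_equal(r3$MAD, r3$RMSD)
  expect_error(error_stats(numeric(0)), "empty")
})

test_that("WTMAD2 equals a brute-force double loop on random fixtures", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    errors <- rnorm(n, sd = 3)
    subsets <- sample(letters[1:4], n, replace = TRUE)
    dEavg <- setNames(runif(4, 5, 120), letters[1:4])
    r <- error_stats(errors, subsets, dEavg = dEavg)
    expect_equal(r$WTMAD2, wtmad2_brute(errors, subsets, dEavg),
                 tolerance = 1e-12)
    # invariance under reordering of the data points
    p <- sample(n)
    r2 <- error_stats(errors[p], subsets[p], dEavg = dEavg)
    expect_equal(r2$WTMAD2, r$WTMAD2, tolerance = 1e-12)
    expect_equal(r2$MAD, r$MAD, tolerance = 1e-12)
  }
})

test_that("|dE|avg is computed from the loaded references by default", {
  errors <- c(1, 1, -2)
  refs <- c(10, -30, 50)
  subsets <- c("A", "A", "B")
  r <- error_stats(errors, subsets, reference_energies = refs)
  manual <- (2 * (56.84 / 20) * 1 + 1 * (56.84 / 50) * 2) / 3
  expect_equal(r$WTMAD2, manual, tolerance = 1e-12)
  # supplied averages override computed ones
  r2 <- error_stats(errors, subsets, reference_energies = refs,
                    dEavg = c(A = 56.84, B = 56.84))
  expect_equal(r2$WTMAD2, r2$MAD, tolerance = 1e-12)
})

test_that("the multireference screen drops exactly the flagged reactions", {
  mk_idx <- function(v) list(I_ND_max = v)
  indices <- list(ok1 = mk_idx(0.001), ok2 = mk_idx(0.010),
                  ok3 = mk_idx(0.029), bad1 = mk_idx(0.031),
                  bad2 = mk_idx(0.500))
  rxs <- list(
    reaction("r1", c(ok1 = -1, ok2 = 1), 0),
    reaction("r2", c(ok1 = -1, bad1 = 1), 0),
    reaction("r3", c(ok2 = -2, ok3 = 2), 0),
    reaction("r4", c(bad2 = -1, ok3 = 1), 0),
    reaction("r5", c(ok1 = -1, ok3 = 1), 0))
  flt <- multiref_filter(indices, rxs, threshold = 0.030)
  expect_equal(vapply(flt$kept, `[[`, "", "id"), c("r1", "r3", "r5"))
  expect_setequal(flt$exclusion_log$species, c("bad1", "bad2"))
  # infinite threshold is the identity filter
  expect_length(multiref_filter(indices, rxs, threshold = Inf)$kept, 5)
  # zero threshold with any correlated species empties the set
  expect_length(multiref_filter(indices, rxs, threshold = 0)$kept, 0)
  expect_error(multiref_filter(indices[1:2], rxs), "validation error")
})

test_that("model evaluation recomputes subset sizes after filtering", {
  sp <- gen_species(12, seed = 21, r_d_range = c(0.2, 0.999))
  rset <- gen_reactions(sp, preset_params("cd4"), 30, sigma = 0.5, seed = 22)
  full <- evaluate_model(rset, preset_params("cd4"))
  thr <- 0.030
  filt <- evaluate_model(rset, preset_params("cd4"), filter_multiref = thr)
  expect_lte(filt$n_evaluated, full$n_evaluated)
  expect_equal(sum(filt$report$subset_table$N), filt$n_evaluated)
  # statistics of the generating model vanish at sigma = 0
  rset0 <- gen_reactions(sp, preset_params("scs"), 25, sigma = 0, seed = 23)
  res0 <- evaluate_model(rset0, preset_params("scs"))
  expect_lt(res0$report$MAD, 1e-10)
})
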