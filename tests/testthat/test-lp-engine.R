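test_that("FBA: bound-limited chain and degenerate all-zero model", {
  m <- example_chain_model()
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes[m$objective_id]), sol$objective_value)
  # steady state and bounds hold at the solution
  expect_true(all(abs(as.matrix(stoich_matrix(m)) %*% sol$fluxes) < 1e-8))

  zero <- metabolic_model(
    data.frame(id = "A_c", compartment = "c"),
    list(reaction("R1", c(A_c = 1), 0, 0),
         reaction("R2", c(A_c = -1), 0, 0)),
    c(c = "cytosol"), objective_id = "R2")
  expect_equal(fba(zero)$objective_value, 0)
})

test_that("FVA on the shared-resource toy matches the closed form", {
  m <- shared_resource_model(budget = 10)
  # branch max = 10 * (1 - fraction); no slack at full optimality
  r9 <- fva(m, fraction = 0.9, reactions = "BRANCH")
  expect_equal(r9$min_flux, 0, tolerance = 1e-9)
  expect_equal(r9$max_flux, 1, tolerance = 1e-9)
  r1 <- fva(m, fraction = 1, reactions = "BRANCH")
  expect_equal(r1$max_flux, 0, tolerance = 1e-9)
  r5 <- fva(m, fraction = 0.5, reactions = "BRANCH")
  expect_equal(r5$max_flux, 5, tolerance = 1e-9)
})

test_that("FVA at fraction 0 equals independent per-reaction LPs", {
  m <- random_small_model(seed = 300)
  S <- as.matrix(stoich_matrix(m))
  lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
  r0 <- fva(m, fraction = 0)
  for (k in seq_len(nrow(r0))) {
    cvec <- as.numeric(m$reactions$id == r0$reaction_id[k])
    lo <- fluxko:::lp_solve(cvec, S, rep(0, nrow(S)), "=", lb, ub)
    hi <- fluxko:::lp_solve(cvec, S, rep(0, nrow(S)), "=", lb, ub,
                            maximize = TRUE)
    expect_equal(r0$min_flux[k], lo$objective, tolerance = 1e-9)
    expect_equal(r0$max_flux[k], hi$objective, tolerance = 1e-9)
  }
})

test_that("FVA endpoints match brute-force vertex enumeration", {
  for (seed in 1:12) {
    m <- random_small_model(seed = seed)
    for (f in c(0, 0.5, 0.9, 1)) {
      got <- fva(m, fraction = f)
      ref <- vertex_fva(m, fraction = f)
      expect_equal(got$min_flux, ref$min_flux, tolerance = 1e-6,
                   info = sprintf("seed %d fraction %.1f", seed, f))
      expect_equal(got$max_flux, ref$max_flux, tolerance = 1e-6,
                   info = sprintf("seed %d fraction %.1f", seed, f))
    }
  }
})

test_that("FVA ranges are consistent and nested across fractions", {
  for (seed in c(31, 32)) {
    m <- random_small_model(seed = seed)
    fracs <- c(0, 0.25, 0.5, 0.75, 0.9, 1)
    res <- lapply(fracs, function(f) fva(m, fraction = f))
    for (r in res) expect_true(all(r$min_flux <= r$max_flux + 1e-9))
    for (k in seq_len(length(fracs) - 1)) {
      expect_true(all(res[[k + 1]]$max_flux <= res[[k]]$max_flux + 1e-7))
      expect_true(all(res[[k + 1]]$min_flux >= res[[k]]$min_flux - 1e-7))
    }
  }
})

test_that("FVA endpoints are attainable flux states", {
  m <- shared_resource_model()
  r <- fva(m, fraction = 0.9)
  S <- as.matrix(stoich_matrix(m))
  lb <- m$reactions$lower_bound; ub <- m$reactions$upper_bound
  z <- fba(m)$objective_value
  obj_row <- as.numeric(m$reactions$id == m$objective_id)
  for (k in seq_len(nrow(r))) {
    for (endpoint in c(r$min_flux[k], r$max_flux[k])) {
      pin <- as.numeric(m$reactions$id == r$reaction_id[k])
      chk <- fluxko:::lp_solve(
        numeric(nrow(m$reactions)),
        rbind(S, obj_row, pin),
        c(rep(0, nrow(S)), 0.9 * z, endpoint),
        c(rep("=", nrow(S)), ">=", "="), lb, ub)
      expect_identical(chk$status, "optimal")
    }
  }
})

test_that("infeasible base models are reported, not silently solved", {
  m <- metabolic_model(
    data.frame(id = "A_c", compartment = "c"),
    list(reaction("DEMAND", c(A_c = -1), 5, 10),
         reaction("OBJ", c(A_c = -1), 0, 0)),
    c(c = "cytosol"), objective_id = "OBJ")
  expect_identical(fba(m)$status, "infeasible")
  expect_error(fva(m, 0.9), "infeasible")
})
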