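test_that("knockout disables exactly the gated reactions", {
  gen <- generate_synthetic_model(synthetic_spec(chain_length = 3))
  m <- gen$model
  ko <- apply_knockout(m, "G_FOCAL")
  hit <- ko$reactions$id %in% c("DEG1", "DEG2", "DEG3")
  expect_true(all(ko$reactions$lower_bound[hit] == 0))
  expect_true(all(ko$reactions$upper_bound[hit] == 0))
  # all other constraints untouched, input model unmodified
  expect_identical(ko$reactions[!hit, c("lower_bound", "upper_bound")],
                   m$reactions[!hit, c("lower_bound", "upper_bound")])
  expect_true(any(m$reactions$upper_bound[m$reactions$id == "DEG1"] > 0))
})

test_that("isozyme backup protects a reaction from single knockout", {
  m <- metabolic_model(
    data.frame(id = c("A_c", "B_c"), compartment = "c"),
    list(reaction("EX_A", c(A_c = 1), 0, 10),
         reaction("R_ISO", c(A_c = -1, B_c = 1), 0, 100,
                  gpr = "g1 or g2"),
         reaction("R_CPLX", c(A_c = -1, B_c = 1), 0, 100,
                  gpr = "g1 and g2"),
         reaction("OBJ", c(B_c = -1), 0, 100)),
    c(c = "cytosol"), objective_id = "OBJ")
  expect_identical(disabled_reactions(m, "g1"), "R_CPLX")
  ko <- apply_knockout(m, "g1")
  expect_equal(ko$reactions$upper_bound[ko$reactions$id == "R_ISO"], 100)
  expect_equal(ko$reactions$upper_bound[ko$reactions$id == "R_CPLX"], 0)
})

test_that("unknown gene gives a warning and the identity model", {
  m <- example_chain_model()
  expect_warning(ko <- apply_knockout(m, "G_NONE"), "unchanged")
  expect_identical(ko, m)
})

test_that("perturbation statistic follows the absolute-change formula", {
  mk <- function(lo, hi, id = "R", f = 0.9)
    list(reaction_id = id, min_flux = lo, max_flux = hi, fraction = f)
  expect_equal(delta_range(mk(0, 140), mk(0, 0)), 140)
  expect_equal(delta_range(mk(-3, 7), mk(-3, 7)), 0)
  # |3 - 5| + |-2 - (-5)| = 5
  expect_equal(delta_range(mk(-5, 5), mk(-2, 3)), 5)
  expect_error(delta_range(mk(0, 1), mk(0, 1, id = "S")), "ids differ")
  expect_error(delta_range(mk(0, 1), mk(0, 1, f = 0.5)), "fractions")
  # symmetric under swapping which model is wild type
  set.seed(5)
  for (i in 1:20) {
    a <- mk(runif(1, -9, 0), runif(1, 0, 9))
    b <- mk(runif(1, -9, 0), runif(1, 0, 9))
    expect_equal(delta_range(a, b), delta_range(b, a))
  }
})

test_that("classification conserves totals and handles zero deltas", {
  gen <- generate_synthetic_model(synthetic_spec(n_decoys = 3, seed = 2))
  res <- knockout_analysis(gen$model, "G_FOCAL", fraction = 0.9)
  tab <- table(factor(res$records$classification,
                      c("unchanged", "affected", "numerical_noise")))
  expect_equal(sum(tab), nrow(res$records))
  # identical WT and KO ranges are all unchanged
  wt <- fva(gen$model, 0.9)
  rec <- perturbation_records(gen$model, wt, wt)
  rec <- classify_records(rec, threshold = 1)
  expect_true(all(rec$classification == "unchanged"))
  expect_length(subsystem_distribution(rec), 0L)
})

test_that("catabolic knockout leaves the growth optimum unchanged", {
  for (seed in 1:4) {
    gen <- generate_synthetic_model(synthetic_spec(
      chain_length = sample(1:4, 1), seed = seed,
      bypass = seed %% 2 == 0))
    res <- knockout_analysis(gen$model, gen$truth$gene, fraction = 0.9)
    expect_equal(res$ko_biomass, res$wt_biomass, tolerance = 1e-9)
    expect_equal(res$relative_growth_change, 0, tolerance = 1e-9)
  }
})

test_that("affected reactions match ground truth and stay local", {
  gen <- generate_synthetic_model(synthetic_spec(
    chain_length = 4, n_decoys = 5, seed = 9))
  res <- knockout_analysis(gen$model, "G_FOCAL", fraction = 0.9)
  expect_setequal(res$affected, gen$truth$expected_affected)
  # confined to the degradation branch: no core/decoy reaction affected
  subs <- res$records$subsystem[res$records$classification == "affected"]
  expect_true(all(subs == "degradation"))
  expect_equal(unname(subsystem_distribution(res$records)["degradation"]),
               length(gen$truth$expected_affected))
})
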