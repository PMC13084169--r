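ranges_df <- function(ids, lo, hi, f = 0.9)
  structure(data.frame(reaction_id = ids, min_flux = lo, max_flux = hi,
                       fraction = f, stringsAsFactors = FALSE),
            class = c("flux_ranges", "data.frame"))

test_that("consumption is decided on attainable flux, not nominal sign", {
  m <- metabolic_model(
    data.frame(id = "M_c", compartment = "c"),
    list(reaction("R1", c(M_c = -1), 0, 5),       # irreversible consumer
         reaction("R2", c(M_c = 1), -3, 4),       # reversible producer
         reaction("R3", c(M_c = 1), 0, 4)),       # pure producer
    c(c = "cytosol"), objective_id = "R1")
  rng <- ranges_df(c("R1", "R2", "R3"),
                   c(0, -3, 0), c(5, 4, 4))
  expect_setequal(consuming_reactions(m, "M_c", rng), c("R1", "R2"))
  # all touching reactions blocked -> empty set
  blocked <- ranges_df(c("R1", "R2", "R3"), c(0, 0, 0), c(0, 0, 0))
  expect_length(consuming_reactions(m, "M_c", blocked), 0L)
  expect_error(consuming_reactions(m, "nope", rng), "unknown metabolite")
  expect_error(consuming_reactions(m, "M_c", rng[-1, ]), "do not cover")
})

test_that("reversible-consumer classification matches a sign oracle", {
  # enumerate 2-reaction cases: coefficient sign x range position
  cases <- expand.grid(coef = c(-1, 1),
                       lo = c(-3, 0), hi = c(0, 4))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    if (cs$lo > cs$hi) next
    m <- metabolic_model(
      data.frame(id = "M_c", compartment = "c"),
      list(reaction("RX", stats::setNames(cs$coef, "M_c"), cs$lo, cs$hi),
           reaction("RO", c(M_c = -cs$coef), -10, 10)),
      c(c = "cytosol"), objective_id = "RO")
    rng <- ranges_df(c("RX", "RO"), c(cs$lo, -10), c(cs$hi, 10))
    # oracle: some attainable flux v with coef * v < 0
    can_consume <- (cs$coef < 0 && cs$hi > 1e-6) ||
      (cs$coef > 0 && cs$lo < -1e-6)
    expect_identical("RX" %in% consuming_reactions(m, "M_c", rng),
                     can_consume, info = paste(cs, collapse = "/"))
  }
})

test_that("accumulation rule recovers the blocked-chain intermediates", {
  gen <- generate_synthetic_model(synthetic_spec(chain_length = 4,
                                                 n_decoys = 3, seed = 6))
  res <- knockout_analysis(gen$model, "G_FOCAL", fraction = 0.9)
  wt <- ranges_df(res$records$reaction_id, res$records$wt_min,
                  res$records$wt_max)
  ko <- ranges_df(res$records$reaction_id, res$records$ko_min,
                  res$records$ko_max)
  rep <- find_accumulating(gen$model, wt, ko, affected = res$affected,
                           gene = "G_FOCAL")
  expect_setequal(rep$candidates$metabolite_id,
                  gen$truth$expected_accumulating)
  # candidates are a subset of metabolites touching affected reactions
  affected_mets <- unique(unlist(
    lapply(res$affected, function(r) names(gen$model$stoichiometry[[r]]))))
  expect_true(all(rep$candidates$metabolite_id %in% affected_mets))
  # category totals sum to the candidate count
  expect_equal(sum(rep$totals), nrow(rep$candidates))
})

test_that("a surviving bypass consumer suppresses the false positive", {
  gen <- generate_synthetic_model(synthetic_spec(chain_length = 3,
                                                 bypass = TRUE))
  res <- knockout_analysis(gen$model, "G_FOCAL", fraction = 0.9)
  wt <- ranges_df(res$records$reaction_id, res$records$wt_min,
                  res$records$wt_max)
  ko <- ranges_df(res$records$reaction_id, res$records$ko_min,
                  res$records$ko_max)
  rep <- find_accumulating(gen$model, wt, ko, scope = "all")
  # polymer head keeps its bypass consumer in the KO: never a candidate
  expect_false("gag0_l" %in% rep$candidates$metabolite_id)
  expect_setequal(rep$candidates$metabolite_id,
                  gen$truth$expected_accumulating)
})

test_that("a model compared against itself yields no candidates", {
  gen <- generate_synthetic_model(synthetic_spec())
  wt <- fva(gen$model, 0.9)
  rep <- find_accumulating(gen$model, wt, wt, scope = "all")
  expect_equal(nrow(rep$candidates), 0L)
  expect_equal(nrow(compartment_summary(rep)), 0L)
})

test_that("compartment summary counts and integer percentages", {
  gen <- generate_synthetic_model(synthetic_spec(chain_length = 3))
  res <- knockout_analysis(gen$model, "G_FOCAL", fraction = 0.9)
  wt <- ranges_df(res$records$reaction_id, res$records$wt_min,
                  res$records$wt_max)
  ko <- ranges_df(res$records$reaction_id, res$records$ko_min,
                  res$records$ko_max)
  rep <- find_accumulating(gen$model, wt, ko, affected = res$affected)
  cs <- compartment_summary(rep)
  expect_equal(sum(cs$count), nrow(rep$candidates))
  # 3 of 4 chain metabolites are lysosomal
  expect_equal(cs$count[cs$compartment == "l"], 3L)
  expect_equal(cs$percent[cs$compartment == "l"], 75L)
  # single-candidate report reads 100%
  one <- rep; one$candidates <- one$candidates[1, , drop = FALSE]
  expect_equal(compartment_summary(one)$percent, 100L)
})
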