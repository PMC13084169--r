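test_that("reaction constructor enforces its invariants", {
  expect_error(reaction("R1", c(A = 0)), "nonzero")
  expect_error(reaction("R1", c(1, 2)), "named")
  expect_error(reaction("R1", c(A = -1), lower_bound = 5, upper_bound = 1),
               "exceeds")
  # exchange reactions may touch a single metabolite
  ex <- reaction("EX_A", c(A = 1), 0, 10)
  expect_length(ex$stoichiometry, 1L)
  # non-finite bounds stored as the finite +/-1000 proxy
  r <- reaction("R2", c(A = -1, B = 1), -Inf, Inf)
  expect_equal(r$lower_bound, -1000)
  expect_equal(r$upper_bound, 1000)
})

test_that("model validation rejects structural defects", {
  mets <- data.frame(id = c("A_c", "B_c"), compartment = "c")
  rxns <- list(reaction("R1", c(A_c = -1, B_c = 1), 0, 10))
  comp <- c(c = "cytosol")
  expect_s3_class(metabolic_model(mets, rxns, comp, objective_id = "R1"),
                  "metabolic_model")
  expect_error(metabolic_model(mets, rxns, comp, objective_id = "nope"),
               "objective_id")
  expect_error(metabolic_model(rbind(mets, mets[1, ]), rxns, comp,
                               objective_id = "R1"), "duplicated")
  expect_error(metabolic_model(mets,
                               list(reaction("R1", c(Z_c = -1), 0, 1)),
                               comp, objective_id = "R1"),
               "unknown metabolite")
  expect_error(metabolic_model(data.frame(id = "A_c", compartment = "x"),
                               list(reaction("R1", c(A_c = -1), 0, 1)),
                               comp, objective_id = "R1"),
               "undeclared compartment")
  # reaction and metabolite id spaces must be disjoint
  expect_error(metabolic_model(data.frame(id = "R1", compartment = "c"),
                               list(reaction("R1", c(R1 = -1), 0, 1)),
                               comp, objective_id = "R1"), "overlap")
  expect_error(metabolic_model(mets, list(), comp, objective_id = "R1"),
               "no reactions")
})

test_that("stoichiometric matrix is an exact derived view", {
  for (seed in 1:5) {
    gen <- generate_synthetic_model(synthetic_spec(
      chain_length = 3, n_decoys = 2, seed = seed))
    m <- gen$model
    S <- stoich_matrix(m)
    expect_identical(dim(S), c(nrow(m$metabolites), nrow(m$reactions)))
    for (rid in m$reactions$id) {
      col <- S[, rid]
      nz <- col[col != 0]
      st <- m$stoichiometry[[rid]]
      expect_equal(nz[order(names(nz))], st[order(names(st))])
    }
  }
})

test_that("reactions_for_gene returns exactly the gated reactions", {
  gen <- generate_synthetic_model(synthetic_spec(chain_length = 3))
  m <- gen$model
  expect_setequal(reactions_for_gene(m, "G_FOCAL"),
                  c("DEG1", "DEG2", "DEG3"))
  expect_message(out <- reactions_for_gene(m, "G_ABSENT"),
                 "not referenced")
  expect_length(out, 0L)
})

test_that("JSON dialect round-trips a model field by field", {
  gen <- generate_synthetic_model(synthetic_spec(
    chain_length = 2, bypass = TRUE, n_decoys = 2, seed = 3))
  m <- gen$model
  path <- withr::local_tempfile(fileext = ".json")
  write_json_model(m, path)
  m2 <- read_json_model(path)
  for (fld in c("id", "metabolites", "reactions", "stoichiometry",
                "genes", "compartments", "objective_id"))
    expect_equal(m2[[fld]], m[[fld]], info = fld)
  # writing is deterministic
  path2 <- withr::local_tempfile(fileext = ".json")
  write_json_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("JSON reader reports schema violations precisely", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema": 1, "id": "x"}', path)
  expect_error(read_json_model(path), "missing field")
  gen <- generate_synthetic_model(synthetic_spec())
  ok <- withr::local_tempfile(fileext = ".json")
  write_json_model(gen$model, ok)
  doc <- jsonlite::fromJSON(ok, simplifyVector = FALSE)
  doc$reactions[[1]]$lower_bound <- 50
  doc$reactions[[1]]$upper_bound <- -50
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), bad)
  expect_error(read_json_model(bad), "exceeds upper_bound")
  doc$reactions <- list()
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA), bad2)
  expect_error(read_json_model(bad2), "no reactions")
})
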