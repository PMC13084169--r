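# Toy models built in code, shared across the suite.

# Shared-resource trade-off toy: uptake capped at `budget`; the growth
# objective and a catabolic branch each consume one resource unit per
# unit flux, so the branch maximum at optimality fraction f is
# budget * (1 - f).
shared_resource_model <- function(budget = 10) {
  metabolic_model(
    metabolites = data.frame(id = "res_c", name = "resource",
                             compartment = "c"),
    reactions = list(
      reaction("EX_res", c(res_c = 1), 0, budget, subsystem = "exchange"),
      reaction("GROWTH", c(res_c = -1), 0, 1000, subsystem = "core"),
      reaction("BRANCH", c(res_c = -1), 0, 1000, subsystem = "branch",
               gpr = "G1")),
    compartments = c(c = "cytosol"),
    objective_id = "GROWTH", id = "shared_resource_toy")
}

# Random small networks with integer bounds, for oracle comparisons.
# Guaranteed feasible (v = 0 always works) and bounded.
random_small_model <- function(seed, n_rxn = NULL) {
  set.seed(seed)
  if (is.null(n_rxn)) n_rxn <- sample(3:6, 1)
  n_met <- sample(1:3, 1)
  mets <- data.frame(id = sprintf("m%d_c", seq_len(n_met)),
                     name = sprintf("met %d", seq_len(n_met)),
                     compartment = "c")
  rxns <- vector("list", n_rxn)
  for (j in seq_len(n_rxn)) {
    nz <- sample(seq_len(n_met), sample(1:min(2, n_met), 1))
    coef <- sample(c(-2, -1, 1, 2), length(nz), replace = TRUE)
    lo <- sample(c(-5L, -2L, 0L), 1)
    hi <- sample(0:8, 1)
    rxns[[j]] <- reaction(sprintf("r%d", j),
                          stats::setNames(coef, mets$id[nz]),
                          lo, hi, subsystem = "core")
  }
  obj <- sprintf("r%d", sample(n_rxn, 1))
  metabolic_model(mets, rxns, compartments = c(c = "cytosol"),
                  objective_id = obj,
                  id = sprintf("random_%d", seed))
}
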