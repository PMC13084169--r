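#' Specification for a synthetic knockout-analysis test network
#'
#' The generated network emulates the topology the knockout pipeline
#' assumes: a growth objective drawing on a shared, bounded resource;
#' a polymer-degradation branch of gene-gated steps (a lysosomal
#' catabolic chain) drawing on the same resource, which creates the
#' growth/degradation trade-off; optional non-gated bypass and decoy
#' reactions. All ground-truth quantities are analytic in the
#' parameters, so every pipeline stage can be checked exactly.
#'
#' Each gated step consumes `degradation_cost / chain_length` resource
#' units per unit flux, so one unit of branch throughput costs
#' `degradation_cost` in total and the branch capacity at optimality
#' fraction f is `resource_budget * (1 - f) / degradation_cost`.
#'
#' @param chain_length number of gene-gated degradation steps (>= 1).
#' @param n_intermediates metabolites strictly inside the chain; must
#'   equal `chain_length - 1`.
#' @param resource_budget shared-resource uptake ceiling (> 0).
#' @param biomass_yield resource units consumed per unit biomass flux.
#' @param degradation_cost resource units consumed per unit branch
#'   throughput.
#' @param bypass add a non-gated shortcut consuming the polymer head
#'   directly to the terminal product (same resource cost).
#' @param n_decoys resource-independent decoy pathways (2 reactions
#'   each) untouched by the knockout.
#' @param seed integer; randomizes decoy ids/capacities and
#'   reaction/metabolite ordering only, never the topology that
#'   defines ground truth.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(chain_length = 3,
                           n_intermediates = chain_length - 1,
                           resource_budget = 100, biomass_yield = 1,
                           degradation_cost = 1, bypass = FALSE,
                           n_decoys = 0, seed = 1) {
  stopifnot(chain_length >= 1, chain_length == round(chain_length),
            n_decoys >= 0, n_decoys == round(n_decoys))
  if (n_intermediates != chain_length - 1)
    stop("n_intermediates must equal chain_length - 1 (",
         chain_length - 1, "), got ", n_intermediates)
  if (resource_budget <= 0 || biomass_yield <= 0 || degradation_cost <= 0)
    stop("resource_budget, biomass_yield and degradation_cost must be ",
         "strictly positive; an infeasible parameter combination ",
         "cannot yield a growing model")
  structure(list(chain_length = as.integer(chain_length),
                 n_intermediates = as.integer(n_intermediates),
                 resource_budget = resource_budget,
                 biomass_yield = biomass_yield,
                 degradation_cost = degradation_cost,
                 bypass = isTRUE(bypass),
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic model with machine-readable ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (a `metabolic_model`) and `truth`, a
#'   `"ground_truth"` list carrying `gene`, `gated_reactions`,
#'   `expected_affected` (nonzero perturbation at any fraction < 1),
#'   `expected_accumulating`, `expected_biomass`
#'   (`resource_budget / biomass_yield`), and
#'   `expected_branch_capacity(fraction)` =
#'   `resource_budget * (1 - fraction) / degradation_cost`.
#' @export
#' @examples
#' gen <- generate_synthetic_model(synthetic_spec(chain_length = 3,
#'   resource_budget = 10, biomass_yield = 1, degradation_cost = 1))
#' fba(gen$model)$objective_value                    # 10
#' gen$truth$expected_branch_capacity(0.9)           # 1
generate_synthetic_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$chain_length
  budget <- spec$resource_budget
  gene <- "G_FOCAL"
  big <- 10 * (budget / spec$biomass_yield +
                 budget / spec$degradation_cost + 1)
  step_cost <- spec$degradation_cost / L

  mets <- data.frame(
    id = c("resource_c", "gag0_l",
           if (L > 1) sprintf("gag%d_l", seq_len(L - 1)),
           "degprod_c"),
    name = c("shared resource",
             "GAG polymer",
             if (L > 1) sprintf("GAG intermediate %d", seq_len(L - 1)),
             "terminal degradation product"),
    compartment = c("c", rep("l", L), "c"),
    stringsAsFactors = FALSE)
  chain_mets <- c("gag0_l", if (L > 1) sprintf("gag%d_l", seq_len(L - 1)),
                  "degprod_c")

  rxns <- list(
    reaction("EX_resource", c(resource_c = 1), 0, budget,
             name = "resource uptake", subsystem = "core"),
    reaction("BIOMASS", stats::setNames(-spec$biomass_yield, "resource_c"),
             0, big, name = "growth objective", subsystem = "core"),
    reaction("SRC_gag", c(gag0_l = 1), 0, big,
             name = "polymer influx", subsystem = "degradation"),
    reaction("SINK_degprod", c(degprod_c = -1), 0, big,
             name = "product drain", subsystem = "degradation"))
  for (i in seq_len(L)) {
    st <- stats::setNames(c(-1, 1, -step_cost),
                          c(chain_mets[i], chain_mets[i + 1], "resource_c"))
    rxns[[length(rxns) + 1L]] <-
      reaction(sprintf("DEG%d", i), st, 0, big,
               name = sprintf("gated degradation step %d", i),
               subsystem = "degradation", gpr = gene)
  }
  if (spec$bypass) {
    st <- stats::setNames(c(-1, 1, -spec$degradation_cost),
                          c("gag0_l", "degprod_c", "resource_c"))
    rxns[[length(rxns) + 1L]] <-
      reaction("BYPASS", st, 0, big, name = "non-gated shortcut",
               subsystem = "degradation")
  }

  # seed-dependent dressing: decoys and ordering, never topology
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)
  if (spec$n_decoys > 0) {
    tags <- sprintf("%04d", sample.int(9999, spec$n_decoys))
    for (k in seq_len(spec$n_decoys)) {
      met <- sprintf("dec%s_c", tags[k])
      mets <- rbind(mets, data.frame(id = met,
                                     name = sprintf("decoy metabolite %s",
                                                    tags[k]),
                                     compartment = "c"))
      cap <- round(stats::runif(1, 1, 50), 2)
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("EX_dec%s", tags[k]),
                 stats::setNames(1, met), 0, cap,
                 name = "decoy uptake", subsystem = "core")
      rxns[[length(rxns) + 1L]] <-
        reaction(sprintf("USE_dec%s", tags[k]),
                 stats::setNames(-1, met), 0, big,
                 name = "decoy drain", subsystem = "core")
    }
  }
  mets <- mets[sample.int(nrow(mets)), , drop = FALSE]
  rownames(mets) <- NULL
  rxns <- rxns[sample.int(length(rxns))]

  model <- metabolic_model(
    metabolites = mets, reactions = rxns,
    compartments = c(c = "cytosol", l = "lysosome", e = "extracellular"),
    objective_id = "BIOMASS",
    id = sprintf("synthetic_chain%d_seed%d", L, spec$seed))

  gated <- sprintf("DEG%d", seq_len(L))
  affected <- if (spec$bypass) gated
              else c(gated, "SRC_gag", "SINK_degprod")
  accumulating <- if (spec$bypass) {
    if (L > 1) sprintf("gag%d_l", seq_len(L - 1)) else character(0)
  } else chain_mets
  truth <- structure(list(
    gene = gene,
    gated_reactions = gated,
    expected_affected = sort(affected),
    expected_accumulating = sort(accumulating),
    expected_biomass = budget / spec$biomass_yield,
    expected_branch_capacity = function(fraction)
      budget * (1 - fraction) / spec$degradation_cost,
    spec = spec), class = "ground_truth")
  list(model = model, truth = truth)
}

#' Write a synthetic model plus ground-truth sidecar
#'
#' Writes the model in the package JSON dialect at `path` and the
#' ground truth at `path` with extension `.truth.json`. Regenerating
#' with the same spec yields byte-identical files.
#'
#' @param model,truth a [generate_synthetic_model()] pair.
#' @param path model JSON path (`*.json`).
#' @return character vector of the two file paths, invisibly.
#' @export
write_fixture <- function(model, truth, path) {
  write_json_model(model, path)
  sidecar <- sub("\\.json$", ".truth.json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".truth.json")
  doc <- list(schema = 1L, gene = truth$gene,
              gated_reactions = truth$gated_reactions,
              expected_affected = truth$expected_affected,
              expected_accumulating = truth$expected_accumulating,
              expected_biomass = truth$expected_biomass,
              resource_budget = truth$spec$resource_budget,
              degradation_cost = truth$spec$degradation_cost,
              spec = unclass(truth$spec))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), sidecar)
  invisible(c(path, sidecar))
}

#' Read a synthetic fixture written by [write_fixture()]
#'
#' @param path model JSON path; the `.truth.json` sidecar must sit
#'   next to it.
#' @return list with `model` and `truth` (capacity formula
#'   reconstructed from the stored parameters).
#' @export
read_fixture <- function(path) {
  model <- read_json_model(path)
  sidecar <- sub("\\.json$", ".truth.json", path)
  if (!file.exists(sidecar)) stop("missing ground-truth sidecar: ", sidecar)
  doc <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  need <- c("schema", "gene", "gated_reactions", "expected_affected",
            "expected_accumulating", "expected_biomass",
            "resource_budget", "degradation_cost")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("corrupt ground-truth sidecar '", sidecar,
         "': missing field(s) ", paste(missing, collapse = ", "))
  budget <- doc$resource_budget; cost <- doc$degradation_cost
  truth <- structure(list(
    gene = doc$gene,
    gated_reactions = doc$gated_reactions,
    expected_affected = doc$expected_affected,
    expected_accumulating = as.character(doc$expected_accumulating),
    expected_biomass = doc$expected_biomass,
    expected_branch_capacity = function(fraction)
      budget * (1 - fraction) / cost,
    spec = do.call(synthetic_spec, doc$spec[c(
      "chain_length", "n_intermediates", "resource_budget",
      "biomass_yield", "degradation_cost", "bypass", "n_decoys",
      "seed")])), class = "ground_truth")
  list(model = model, truth = truth)
}
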