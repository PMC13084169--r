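#' Analysis configuration for the knockout pipeline
#'
#' @param model_path path to a model file (`.json` dialect or SBML
#'   `.xml`/`.sbml`).
#' @param gene gene id to knock out.
#' @param fraction optimality fraction for the per-reaction
#'   perturbation and accumulation tables (default 0.9).
#' @param fractions sweep grid for the capacity and robustness tables
#'   (default `c(1, 0.9, 0.75, 0.5)`).
#' @param significance_threshold perturbation significance threshold
#'   (default 1).
#' @param feasibility_tol,blocked_tol LP and blocked-range tolerances.
#' @param scope metabolite universe for the accumulation analysis:
#'   `"affected_universe"` (participants of affected reactions,
#'   default) or `"all_metabolites"`.
#' @param output_dir directory for the report bundle.
#' @return object of class `"analysis_config"`.
#' @export
analysis_config <- function(model_path, gene, fraction = 0.9,
                            fractions = c(1, 0.9, 0.75, 0.5),
                            significance_threshold = 1,
                            feasibility_tol = 1e-9, blocked_tol = 1e-6,
                            scope = c("affected_universe",
                                      "all_metabolites"),
                            output_dir = "fluxko_report") {
  scope <- match.arg(scope)
  stopifnot(all(fractions >= 0), all(fractions <= 1),
            fraction >= 0, fraction <= 1,
            significance_threshold > 0,
            feasibility_tol > 0, blocked_tol > 0)
  structure(list(model_path = model_path, gene = gene,
                 fraction = fraction, fractions = sort(fractions),
                 significance_threshold = significance_threshold,
                 feasibility_tol = feasibility_tol,
                 blocked_tol = blocked_tol, scope = scope,
                 output_dir = output_dir),
            class = "analysis_config")
}

read_model_auto <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_json_model(path)
  else read_sbml(path)
}

round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full knockout analysis pipeline and write the report bundle
#'
#' Loads the model, knocks out the gene, and writes five tables plus a
#' provenance manifest to the output directory:
#' `growth_table.tsv` (WT/KO biomass and relative change),
#' `capacity_table.tsv` (FVA maxima of the disabled reactions over the
#' fraction grid, wild type), `range_table.tsv` (per-reaction WT/KO
#' ranges, perturbation statistic and classification at the analysis
#' fraction), `robustness_table.tsv` (affected counts and set identity
#' across fractions), `accumulation_table.tsv` (potentially
#' accumulating metabolites) with per-metabolite detail in
#' `accumulation_detail.tsv`, full-precision records in
#' `range_detail.tsv`, and `manifest.json` (config, model checksum,
#' solver, versions). Table numbers are rounded to 2 decimals; detail
#' files keep full precision.
#'
#' If the gene resolves to no reaction the perturbation tables are
#' empty and the function returns status 2 with a warning; any stage
#' failure writes a `FAILED` marker next to the partial outputs and
#' rethrows the error.
#'
#' @param config an [analysis_config()].
#' @return invisibly, a list with `status` (0 ok, 2 completed with
#'   warnings), the in-memory tables and the `knockout_result`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$output_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  status <- 0L
  tryCatch({
    model <- read_model_auto(config$model_path)
    targets <- suppressMessages(reactions_for_gene(model, config$gene))
    if (length(targets) == 0L) {
      warning("gene '", config$gene, "' resolves to no reaction; ",
              "emitting empty perturbation tables", call. = FALSE)
      status <- 2L
      empty <- data.frame()
      for (f in c("growth_table.tsv", "capacity_table.tsv",
                  "range_table.tsv", "robustness_table.tsv",
                  "accumulation_table.tsv"))
        utils::write.table(empty, file.path(config$output_dir, f),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      write_manifest(config, model, config$output_dir)
      return(invisible(list(status = status)))
    }

    res <- knockout_analysis(model, config$gene,
                             fraction = config$fraction,
                             threshold = config$significance_threshold,
                             tol = config$feasibility_tol)

    growth <- data.frame(
      model = c("wild-type", paste0(config$gene, " knockout")),
      maximum_biomass_flux = c(res$wt_biomass, res$ko_biomass),
      relative_change_pct = c(NA, 100 * res$relative_growth_change))
    utils::write.table(round_df(growth),
                       file.path(config$output_dir, "growth_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    cap <- write_capacity_tsv(model, res$disabled_reactions,
                              config$fractions,
                              file.path(config$output_dir,
                                        "capacity_table.tsv"),
                              tol = config$feasibility_tol)

    write_perturbation_tsv(res$records,
                           file.path(config$output_dir,
                                     "range_detail.tsv"))
    write_perturbation_tsv(round_df(res$records),
                           file.path(config$output_dir,
                                     "range_table.tsv"))

    sweep_fracs <- setdiff(config$fractions, 1)
    rob <- threshold_robustness(model, config$gene,
                                fractions = sweep_fracs,
                                threshold = config$significance_threshold,
                                tol = config$feasibility_tol)
    rob_tab <- data.frame(
      fraction = as.numeric(names(rob$per_fraction)),
      affected_count = vapply(rob$per_fraction, `[[`, 0L,
                              "affected_count"),
      identical_to_first = lengths(rob$set_differences) == 0L,
      subsystems = vapply(rob$per_fraction, function(p)
        paste(sprintf("%s:%d", names(p$subsystems), p$subsystems),
              collapse = "; "), ""))
    utils::write.table(rob_tab,
                       file.path(config$output_dir,
                                 "robustness_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    wt_ranges <- structure(
      data.frame(reaction_id = res$records$reaction_id,
                 min_flux = res$records$wt_min,
                 max_flux = res$records$wt_max,
                 fraction = config$fraction),
      class = c("flux_ranges", "data.frame"))
    ko_ranges <- structure(
      data.frame(reaction_id = res$records$reaction_id,
                 min_flux = res$records$ko_min,
                 max_flux = res$records$ko_max,
                 fraction = config$fraction),
      class = c("flux_ranges", "data.frame"))
    rep <- find_accumulating(
      model, wt_ranges, ko_ranges,
      affected = if (config$scope == "affected_universe") res$affected,
      scope = if (config$scope == "affected_universe") "affected"
              else "all",
      gene = config$gene, tol = config$blocked_tol)
    acc_tab <- if (nrow(rep$candidates)) {
      agg <- stats::aggregate(
        list(count = rep$candidates$metabolite_id),
        by = list(category = rep$candidates$category),
        FUN = length)
      agg$compartments <- vapply(agg$category, function(ct)
        paste(sort(unique(
          rep$candidates$compartment[rep$candidates$category == ct])),
          collapse = ", "), "")
      agg[order(-agg$count), ]
    } else data.frame(category = character(0), count = integer(0),
                      compartments = character(0))
    utils::write.table(acc_tab,
                       file.path(config$output_dir,
                                 "accumulation_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_accumulation_tsv(rep, file.path(config$output_dir,
                                          "accumulation_detail.tsv"))
    write_manifest(config, model, config$output_dir)

    invisible(list(status = status, growth = growth, capacity = cap,
                   records = res$records, robustness = rob_tab,
                   accumulation = acc_tab, report = rep,
                   knockout = res))
  }, error = function(e) {
    writeLines(paste("FAILED:", conditionMessage(e)), marker)
    stop(e)
  })
}

write_manifest <- function(config, model, dir) {
  manifest <- list(
    config = unclass(config),
    model = list(id = model$id,
                 md5 = unname(tools::md5sum(config$model_path)),
                 reactions = nrow(model$reactions),
                 metabolites = nrow(model$metabolites),
                 genes = length(model$genes)),
    solver = "fluxko bounded-variable two-phase simplex",
    package_version = as.character(utils::packageVersion("fluxko")),
    r_version = as.character(getRversion()))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
}

#' Tiny linear-chain demonstration model
#'
#' Uptake (capacity 10) -> A -> B -> growth objective; the FBA optimum
#' is 10, limited by the uptake bound. Used in examples and smoke
#' tests.
#'
#' @return a `metabolic_model`.
#' @export
example_chain_model <- function() {
  metabolic_model(
    metabolites = data.frame(id = c("A_c", "B_c"),
                             name = c("A", "B"), compartment = "c"),
    reactions = list(
      reaction("EX_A", c(A_c = 1), 0, 10, subsystem = "exchange"),
      reaction("R1", c(A_c = -1, B_c = 1), 0, 1000, subsystem = "core"),
      reaction("GROWTH", c(B_c = -1), 0, 1000, subsystem = "core")),
    compartments = c(c = "cytosol"),
    objective_id = "GROWTH", id = "chain_demo")
}
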