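#' Simulate a single-gene knockout
#'
#' Every reaction whose GPR rule evaluates to inactive when `gene` is
#' deleted gets both flux bounds set to zero; all other constraints are
#' untouched and the input model is not modified. Reactions with an
#' isozyme backup (`"g1 or g2"`) survive; reactions without a GPR are
#' never disabled.
#'
#' @param model a `metabolic_model`.
#' @param gene gene id to delete.
#' @return a new `metabolic_model` mimicking complete loss of the gene
#'   product. If the gene is referenced by no GPR, the model is
#'   returned unchanged with a warning.
#' @export
apply_knockout <- function(model, gene) {
  stopifnot(is.character(gene), length(gene) == 1L)
  carriers <- suppressMessages(reactions_for_gene(model, gene))
  if (length(carriers) == 0L) {
    warning("gene '", gene, "' is not referenced by any GPR rule; ",
            "returning the model unchanged", call. = FALSE)
    return(model)
  }
  disabled <- carriers[!vapply(model$gpr_ast[carriers], rule_active,
                               TRUE, deleted = gene)]
  ko <- model
  hit <- ko$reactions$id %in% disabled
  ko$reactions$lower_bound[hit] <- 0
  ko$reactions$upper_bound[hit] <- 0
  ko$id <- paste0(model$id, "_ko_", gene)
  ko
}

#' Reactions disabled by deleting a gene
#'
#' The gene's carrier reactions whose GPR rule evaluates false under
#' the single-gene deletion.
#'
#' @inheritParams apply_knockout
#' @return character vector of reaction ids.
#' @export
disabled_reactions <- function(model, gene) {
  carriers <- suppressMessages(reactions_for_gene(model, gene))
  carriers[!vapply(model$gpr_ast[carriers], rule_active,
                   TRUE, deleted = gene)]
}

#' Flux-range perturbation statistic
#'
#' The per-reaction perturbation between wild-type and knockout flux
#' ranges:
#' \deqn{\Delta_{range} = |max_{KO} - max_{WT}| + |min_{KO} - min_{WT}|.}
#' Symmetric under swapping which model is called wild type.
#'
#' @param wt,ko single rows of a [fva()] result (or any list with
#'   `reaction_id`, `min_flux`, `max_flux`, `fraction`) for the same
#'   reaction at the same optimality fraction.
#' @return non-negative numeric.
#' @export
#' @examples
#' wt <- list(reaction_id = "R", min_flux = 0, max_flux = 140, fraction = 0.9)
#' ko <- list(reaction_id = "R", min_flux = 0, max_flux = 0, fraction = 0.9)
#' delta_range(wt, ko)  # 140
delta_range <- function(wt, ko) {
  if (!identical(as.character(wt$reaction_id), as.character(ko$reaction_id)))
    stop("delta_range: reaction ids differ ('", wt$reaction_id, "' vs '",
         ko$reaction_id, "')")
  if (!is.null(wt$fraction) && !is.null(ko$fraction) &&
      !isTRUE(all.equal(wt$fraction, ko$fraction)))
    stop("delta_range: ranges computed at different optimality fractions")
  abs(ko$max_flux - wt$max_flux) + abs(ko$min_flux - wt$min_flux)
}

#' Build perturbation records from paired WT/KO flux ranges
#'
#' @param model a `metabolic_model` (source of subsystem labels).
#' @param wt_ranges,ko_ranges [fva()] results over the same reactions
#'   at the same fraction.
#' @return data.frame of class `"perturbation_records"`: `reaction_id`,
#'   `subsystem`, `wt_min`, `wt_max`, `ko_min`, `ko_max`,
#'   `delta_range`, `classification` (initialized `NA`; see
#'   [classify_records()]), plus a `fraction` attribute.
#' @export
perturbation_records <- function(model, wt_ranges, ko_ranges) {
  stopifnot(identical(wt_ranges$reaction_id, ko_ranges$reaction_id))
  if (!isTRUE(all.equal(unique(wt_ranges$fraction),
                        unique(ko_ranges$fraction))))
    stop("WT and KO ranges computed at different optimality fractions")
  d <- abs(ko_ranges$max_flux - wt_ranges$max_flux) +
    abs(ko_ranges$min_flux - wt_ranges$min_flux)
  rec <- data.frame(
    reaction_id = wt_ranges$reaction_id,
    subsystem = model$reactions$subsystem[match(wt_ranges$reaction_id,
                                                model$reactions$id)],
    wt_min = wt_ranges$min_flux, wt_max = wt_ranges$max_flux,
    ko_min = ko_ranges$min_flux, ko_max = ko_ranges$max_flux,
    delta_range = d, classification = NA_character_,
    stringsAsFactors = FALSE)
  attr(rec, "fraction") <- unique(wt_ranges$fraction)
  class(rec) <- c("perturbation_records", "data.frame")
  rec
}

#' Classify perturbation records: unchanged, affected, numerical noise
#'
#' Records with `delta_range <= threshold` are `unchanged`. Records
#' above the threshold are, when the WT and KO models are supplied,
#' re-evaluated with a tightened solver tolerance; if the recomputed
#' `delta_range` falls to or below the threshold the original excess is
#' attributed to numerical noise (`numerical_noise`), otherwise the
#' reaction is genuinely `affected`. Without the models no re-test is
#' possible and above-threshold records are labeled `affected`.
#'
#' @param records a [perturbation_records()] data.frame.
#' @param threshold significance threshold on `delta_range`
#'   (default 1, chosen against the bimodal perturbation distribution).
#' @param wt_model,ko_model optional models for the noise re-test.
#' @param retest_tol tightened LP tolerance for the re-test.
#' @return `records` with `classification` filled; re-tested rows keep
#'   their recomputed `delta_range`.
#' @export
classify_records <- function(records, threshold = 1,
                             wt_model = NULL, ko_model = NULL,
                             retest_tol = 1e-10) {
  stopifnot(threshold > 0)
  cls <- ifelse(records$delta_range <= threshold, "unchanged", NA)
  flag <- which(is.na(cls))
  if (length(flag) && !is.null(wt_model) && !is.null(ko_model)) {
    fr <- attr(records, "fraction")
    ids <- records$reaction_id[flag]
    wt2 <- fva(wt_model, fraction = fr, reactions = ids, tol = retest_tol)
    ko2 <- fva(ko_model, fraction = fr, reactions = ids, tol = retest_tol)
    d2 <- abs(ko2$max_flux - wt2$max_flux) + abs(ko2$min_flux - wt2$min_flux)
    cls[flag] <- ifelse(d2 <= threshold, "numerical_noise", "affected")
    records$delta_range[flag] <- d2
    records$wt_min[flag] <- wt2$min_flux; records$wt_max[flag] <- wt2$max_flux
    records$ko_min[flag] <- ko2$min_flux; records$ko_max[flag] <- ko2$max_flux
  } else {
    cls[flag] <- "affected"
  }
  records$classification <- cls
  records
}

#' Subsystem distribution of affected reactions
#'
#' @param records classified [perturbation_records()].
#' @return named integer vector, subsystem -> count of
#'   `classification == "affected"`, sorted decreasing. Empty when no
#'   reaction is affected.
#' @export
subsystem_distribution <- function(records) {
  aff <- records[records$classification %in% "affected", , drop = FALSE]
  if (nrow(aff) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(aff$subsystem)
  cnt <- sort(stats::setNames(as.integer(tab), names(tab)),
              decreasing = TRUE)
  cnt
}

#' Full single-gene knockout perturbation analysis
#'
#' Runs the complete perturbation pipeline: disable the gene's
#' reactions, compute WT and KO biomass optima, run paired FVA at the
#' chosen optimality fraction, compute the per-reaction perturbation
#' statistic, classify against the significance threshold (with the
#' tightened-tolerance noise re-test), and aggregate by subsystem.
#'
#' @param model wild-type `metabolic_model`.
#' @param gene gene id to knock out.
#' @param fraction optimality fraction for FVA (default 0.9, the
#'   near-optimal growth state).
#' @param threshold significance threshold on the perturbation
#'   statistic (default 1).
#' @param reactions FVA scope; default all reactions (genome-wide).
#' @param tol LP tolerance.
#' @return object of class `"knockout_result"`: list with `gene`,
#'   `disabled_reactions`, `wt_biomass`, `ko_biomass`,
#'   `relative_growth_change`, `fraction`, `threshold`, `records`
#'   (classified [perturbation_records()]), `affected` (reaction ids),
#'   `subsystems` ([subsystem_distribution()]), and the `wt`/`ko`
#'   models.
#' @export
knockout_analysis <- function(model, gene, fraction = 0.9, threshold = 1,
                              reactions = NULL, tol = 1e-9) {
  ko_model <- apply_knockout(model, gene)
  wt_sol <- fba(model, tol = tol)
  ko_sol <- fba(ko_model, tol = tol)
  if (wt_sol$status != "optimal")
    stop("wild-type FBA is ", wt_sol$status)
  rel <- if (wt_sol$objective_value > 0 && ko_sol$status == "optimal")
    (ko_sol$objective_value - wt_sol$objective_value) /
      wt_sol$objective_value
  else NA_real_
  wt_ranges <- fva(model, fraction = fraction, reactions = reactions,
                   tol = tol)
  ko_ranges <- fva(ko_model, fraction = fraction, reactions = reactions,
                   tol = tol)
  rec <- perturbation_records(model, wt_ranges, ko_ranges)
  rec <- classify_records(rec, threshold = threshold,
                          wt_model = model, ko_model = ko_model)
  structure(list(
    gene = gene,
    disabled_reactions = disabled_reactions(model, gene),
    wt_biomass = wt_sol$objective_value,
    ko_biomass = if (ko_sol$status == "optimal")
      ko_sol$objective_value else NA_real_,
    relative_growth_change = rel,
    fraction = fraction, threshold = threshold,
    records = rec,
    affected = rec$reaction_id[rec$classification == "affected"],
    subsystems = subsystem_distribution(rec),
    wt_model = model, ko_model = ko_model),
    class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat("<knockout_result> gene ", x$gene, "\n",
      "  disabled reactions: ", length(x$disabled_reactions), "\n",
      "  biomass WT/KO: ", format(x$wt_biomass), " / ",
      format(x$ko_biomass),
      " (", format(100 * x$relative_growth_change), "% change)\n",
      "  affected reactions (fraction ", x$fraction, ", |delta| > ",
      x$threshold, "): ", length(x$affected), "\n", sep = "")
  invisible(x)
}

#' Percentage loss of maximal flux capacity
#'
#' Capacity loss of a reaction between wild type and knockout, as a
#' percentage of the wild-type FVA maximum:
#' \eqn{100 (max_{WT} - max_{KO}) / max_{WT}}. A fully blocked
#' knockout range yields 100.
#'
#' @inheritParams delta_range
#' @param tol wild-type capacity below which the loss is undefined.
#' @return percentage on the 0-100 scale (`NA` if the wild-type
#'   capacity is below `tol`).
#' @export
capacity_loss_pct <- function(wt, ko, tol = 1e-9) {
  if (!identical(as.character(wt$reaction_id), as.character(ko$reaction_id)))
    stop("capacity_loss_pct: reaction ids differ")
  if (abs(wt$max_flux) <= tol) return(NA_real_)
  100 * (wt$max_flux - ko$max_flux) / wt$max_flux
}

#' Affected reactions as a percentage of the network
#'
#' @param n_affected number of significantly affected reactions.
#' @param n_reactions total reactions in the model.
#' @return percentage on the 0-100 scale.
#' @export
affected_fraction_pct <- function(n_affected, n_reactions) {
  stopifnot(n_reactions > 0, n_affected >= 0, n_affected <= n_reactions)
  100 * n_affected / n_reactions
}

#' Write perturbation records as TSV
#'
#' Columns: reaction_id, subsystem, wt_min, wt_max, ko_min, ko_max,
#' delta_range, classification.
#'
#' @param records classified [perturbation_records()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_perturbation_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
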