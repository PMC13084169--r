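#' Reactions able to consume a metabolite under given flux ranges
#'
#' Consumption is decided on attainable flux, not nominal direction: a
#' reaction consumes the metabolite if its coefficient is negative and
#' the range allows forward flux (`max_flux > tol`), or the coefficient
#' is positive and the range allows reverse flux (`min_flux < -tol`).
#' This keeps reversible reactions classified correctly.
#'
#' @param model a `metabolic_model`.
#' @param metabolite metabolite id.
#' @param ranges [fva()] result covering every reaction that touches
#'   the metabolite (an error otherwise).
#' @param tol flux magnitude below which a direction counts as closed.
#' @return character vector of reaction ids (possibly empty).
#' @export
consuming_reactions <- function(model, metabolite, ranges, tol = 1e-6) {
  if (!metabolite %in% model$metabolites$id)
    stop("unknown metabolite: ", metabolite)
  touch <- model$reactions$id[vapply(model$reactions$id, function(rid)
    metabolite %in% names(model$stoichiometry[[rid]]), TRUE)]
  missing <- setdiff(touch, ranges$reaction_id)
  if (length(missing))
    stop("ranges do not cover reaction(s) touching '", metabolite,
         "': ", paste(missing, collapse = ", "))
  keep <- vapply(touch, function(rid) {
    coef <- model$stoichiometry[[rid]][[metabolite]]
    i <- match(rid, ranges$reaction_id)
    (coef < 0 && ranges$max_flux[i] > tol) ||
      (coef > 0 && ranges$min_flux[i] < -tol)
  }, TRUE)
  touch[keep]
}

#' Identify metabolites predicted to accumulate after a knockout
#'
#' A metabolite is flagged as potentially accumulating when it has at
#' least one reaction able to consume it in the wild type and every
#' one of those consuming reactions is fully blocked in the knockout
#' (entire KO flux range within `[-tol, tol]`). Each candidate is
#' labeled with its compartment and a pathway category derived from
#' the majority subsystem of its wild-type consuming reactions (ties
#' are labeled `"other"`).
#'
#' @param model a `metabolic_model`.
#' @param wt_ranges,ko_ranges genome-wide (or universe-covering) [fva()]
#'   results for the wild-type and knockout models at the same
#'   optimality fraction.
#' @param affected reaction ids of the significantly affected set; with
#'   `scope = "affected"` the metabolite universe is restricted to
#'   participants of these reactions.
#' @param scope `"affected"` (default when `affected` is given) scans
#'   only metabolites touching affected reactions; `"all"` scans every
#'   metabolite in the model.
#' @param gene gene id recorded in the report (optional bookkeeping).
#' @param tol blocked/active flux tolerance.
#' @return object of class `"accumulation_report"`: list with `gene`,
#'   `scope`, `universe` (metabolite ids scanned), `candidates`
#'   (data.frame: `metabolite_id`, `name`, `compartment`, `category`,
#'   `consuming` comma-separated reaction ids) and `totals` (counts
#'   per category).
#' @export
find_accumulating <- function(model, wt_ranges, ko_ranges,
                              affected = NULL,
                              scope = if (!is.null(affected)) "affected"
                                      else "all",
                              gene = NA_character_, tol = 1e-6) {
  scope <- match.arg(scope, c("affected", "all"))
  stopifnot(identical(wt_ranges$reaction_id, ko_ranges$reaction_id))
  if (!isTRUE(all.equal(unique(wt_ranges$fraction),
                        unique(ko_ranges$fraction))))
    stop("WT and KO ranges computed at different optimality fractions")
  universe <- if (scope == "affected") {
    if (is.null(affected))
      stop("scope = 'affected' requires the affected reaction set")
    unique(unlist(lapply(affected, function(rid)
      names(model$stoichiometry[[rid]]))))
  } else model$metabolites$id

  blocked_ko <- function(rid) {
    i <- match(rid, ko_ranges$reaction_id)
    abs(ko_ranges$min_flux[i]) <= tol && abs(ko_ranges$max_flux[i]) <= tol
  }
  rows <- list()
  for (met in universe) {
    cons <- consuming_reactions(model, met, wt_ranges, tol = tol)
    if (length(cons) == 0L) next
    if (!all(vapply(cons, blocked_ko, TRUE))) next
    subs <- model$reactions$subsystem[match(cons, model$reactions$id)]
    tab <- sort(table(subs), decreasing = TRUE)
    category <- if (length(tab) > 1L && tab[1] == tab[2]) "other"
                else names(tab)[1]
    i <- match(met, model$metabolites$id)
    rows[[length(rows) + 1L]] <- data.frame(
      metabolite_id = met,
      name = model$metabolites$name[i],
      compartment = model$metabolites$compartment[i],
      category = category,
      consuming = paste(cons, collapse = ","),
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(metabolite_id = character(0), name = character(0),
               compartment = character(0), category = character(0),
               consuming = character(0), stringsAsFactors = FALSE)
  totals <- if (nrow(candidates))
    sort(table(candidates$category), decreasing = TRUE) else table(character(0))
  structure(list(gene = gene, scope = scope, universe = universe,
                 candidates = candidates,
                 totals = stats::setNames(as.integer(totals),
                                          names(totals))),
            class = "accumulation_report")
}

#' @export
print.accumulation_report <- function(x, ...) {
  cat("<accumulation_report>",
      if (!is.na(x$gene)) paste0(" gene ", x$gene), "\n",
      "  metabolites scanned: ", length(x$universe),
      " (scope: ", x$scope, ")\n",
      "  potentially accumulating: ", nrow(x$candidates), "\n", sep = "")
  if (length(x$totals))
    for (k in seq_along(x$totals))
      cat("    ", names(x$totals)[k], ": ", x$totals[k], "\n", sep = "")
  invisible(x)
}

#' Compartment summary of an accumulation report
#'
#' @param report an [find_accumulating()] result.
#' @return data.frame with columns `compartment`, `count`, `percent`
#'   (percent of candidates, rounded to the nearest integer), sorted by
#'   decreasing count. Empty report yields a zero-row frame.
#' @export
compartment_summary <- function(report) {
  cand <- report$candidates
  if (nrow(cand) == 0L)
    return(data.frame(compartment = character(0), count = integer(0),
                      percent = integer(0)))
  tab <- sort(table(cand$compartment), decreasing = TRUE)
  data.frame(compartment = names(tab), count = as.integer(tab),
             percent = as.integer(round(100 * as.integer(tab) /
                                          nrow(cand))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write an accumulation report as TSV
#'
#' Per-metabolite detail: metabolite, name, compartment, category, and
#' consuming reactions.
#'
#' @param report an [find_accumulating()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_accumulation_tsv <- function(report, path) {
  utils::write.table(report$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
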