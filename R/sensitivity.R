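#' Capacity curve of a reaction over optimality fractions
#'
#' The FVA maximum of one reaction at each requested optimality
#' fraction: how much flux the reaction can carry while the objective
#' keeps at least that fraction of its optimum. Because the feasible
#' regions are nested, the curve is monotone non-increasing in the
#' fraction; this is asserted (within `mono_tol`) on every curve
#' produced.
#'
#' @param model a `metabolic_model`.
#' @param reaction reaction id.
#' @param fractions numeric vector in `[0, 1]`; duplicates are dropped
#'   and the points are returned in increasing fraction order.
#' @param tol LP tolerance.
#' @param mono_tol numeric slack allowed on the monotonicity assertion.
#' @return data.frame of class `"capacity_curve"` with columns
#'   `fraction`, `max_capacity` and a `reaction_id` attribute.
#' @export
capacity_curve <- function(model, reaction, fractions,
                           tol = 1e-9, mono_tol = 1e-6) {
  stopifnot(all(fractions >= 0), all(fractions <= 1),
            length(fractions) >= 1)
  fractions <- sort(unique(fractions))
  caps <- vapply(fractions, function(f)
    fva(model, fraction = f, reactions = reaction, tol = tol)$max_flux,
    numeric(1))
  if (any(diff(caps) > mono_tol))
    stop("capacity curve for '", reaction,
         "' is not non-increasing in the optimality fraction; ",
         "this indicates a solver failure")
  out <- data.frame(fraction = fractions, max_capacity = caps)
  attr(out, "reaction_id") <- reaction
  class(out) <- c("capacity_curve", "data.frame")
  out
}

#' Robustness of the affected-reaction set across optimality fractions
#'
#' Re-runs the full knockout perturbation pipeline at each optimality
#' fraction and compares the resulting affected-reaction sets. The
#' headline claim this supports is set identity, not merely equal
#' counts, so the symmetric differences between consecutive fractions
#' are reported alongside the indicator.
#'
#' @inheritParams knockout_analysis
#' @param fractions optimality fractions to sweep
#'   (default `c(0.9, 0.75, 0.5)`).
#' @return object of class `"robustness_sweep"`: list with `per_fraction`
#'   (named list per fraction: `affected_count`, `affected`,
#'   `subsystems`), `identical_sets` (logical), and `set_differences`
#'   (list of symmetric differences vs the first fraction's set).
#' @export
threshold_robustness <- function(model, gene,
                                 fractions = c(0.9, 0.75, 0.5),
                                 threshold = 1, reactions = NULL,
                                 tol = 1e-9) {
  stopifnot(length(fractions) >= 1, all(fractions >= 0),
            all(fractions <= 1))
  per <- lapply(fractions, function(f) {
    res <- knockout_analysis(model, gene, fraction = f,
                             threshold = threshold,
                             reactions = reactions, tol = tol)
    list(affected_count = length(res$affected),
         affected = sort(res$affected),
         subsystems = res$subsystems)
  })
  names(per) <- as.character(fractions)
  ref <- per[[1]]$affected
  diffs <- lapply(per, function(p)
    union(setdiff(p$affected, ref), setdiff(ref, p$affected)))
  structure(list(per_fraction = per,
                 identical_sets = all(lengths(diffs) == 0L),
                 set_differences = diffs),
            class = "robustness_sweep")
}

#' @export
print.robustness_sweep <- function(x, ...) {
  cat("<robustness_sweep>\n")
  for (f in names(x$per_fraction))
    cat("  fraction ", f, ": ", x$per_fraction[[f]]$affected_count,
        " affected\n", sep = "")
  cat("  identical sets across fractions: ", x$identical_sets, "\n",
      sep = "")
  invisible(x)
}

#' Write a capacity sweep table as TSV
#'
#' One row per optimality fraction, one column per reaction (the shape
#' of a capacity table over a reaction panel).
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids (columns).
#' @param fractions optimality fractions (rows).
#' @param path output file.
#' @param tol LP tolerance.
#' @return the table, invisibly.
#' @export
write_capacity_tsv <- function(model, reactions, fractions, path,
                               tol = 1e-9) {
  curves <- lapply(reactions, function(r)
    capacity_curve(model, r, fractions, tol = tol))
  tab <- data.frame(fraction = sort(unique(fractions)))
  for (k in seq_along(reactions))
    tab[[reactions[k]]] <- curves[[k]]$max_capacity
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
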