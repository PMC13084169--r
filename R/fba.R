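#' Flux balance analysis
#'
#' Maximizes the objective (biomass) reaction's flux subject to
#' steady-state mass balance (\eqn{S v = 0}) and the reaction bounds.
#'
#' @param model a `metabolic_model`.
#' @param tol optimality/feasibility tolerance passed to the LP solver.
#' @return an object of class `"flux_solution"`: list with
#'   `objective_value`, `fluxes` (named numeric over reaction ids) and
#'   `status` (`"optimal"`, `"infeasible"`, `"unbounded"`). For
#'   non-optimal status `fluxes` is `NULL` and `objective_value` `NA`.
#' @export
#' @examples
#' m <- example_chain_model()
#' fba(m)$objective_value
fba <- function(model, tol = 1e-9) {
  validate_model(model)
  S <- as.matrix(stoich_matrix(model))
  obj <- as.numeric(model$reactions$id == model$objective_id)
  res <- lp_solve(obj, S, rep(0, nrow(S)), "=",
                  lb = model$reactions$lower_bound,
                  ub = model$reactions$upper_bound,
                  maximize = TRUE, tol = tol)
  fluxes <- if (res$status == "optimal")
    stats::setNames(res$x, model$reactions$id) else NULL
  structure(list(objective_value = if (res$status == "optimal")
    res$objective else NA_real_,
    fluxes = fluxes, status = res$status),
    class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status,
      if (x$status == "optimal")
        paste0(", objective: ", format(x$objective_value)), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux
#' subject to steady state, the bounds, and (for `fraction > 0`) an
#' optimality floor \eqn{v_{obj} \ge fraction \cdot Z_{opt}}, where
#' \eqn{Z_{opt}} is the model's own FBA optimum. At `fraction = 0` the
#' floor constraint is dropped entirely, so the result equals
#' independent per-reaction min/max LPs.
#'
#' @param model a `metabolic_model`.
#' @param fraction optimality fraction in `[0, 1]` (the decimal of the
#'   printed percentage: 90\% -> 0.9).
#' @param reactions reaction ids to analyse; default all reactions.
#' @param tol LP tolerance.
#' @return a data.frame of class `"flux_ranges"` with columns
#'   `reaction_id`, `min_flux`, `max_flux`, `fraction`. A reaction
#'   whose endpoint LP fails is reported with `NA` endpoints and a
#'   warning; the run continues.
#' @export
fva <- function(model, fraction = 0.9, reactions = NULL, tol = 1e-9) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  base <- fba(model, tol = tol)
  if (base$status != "optimal")
    stop("base FBA is ", base$status, "; cannot run FVA")
  z_opt <- base$objective_value
  rxn_ids <- model$reactions$id
  if (is.null(reactions)) reactions <- rxn_ids
  unknown <- setdiff(reactions, rxn_ids)
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))

  S <- as.matrix(stoich_matrix(model))
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  obj_row <- as.numeric(rxn_ids == model$objective_id)
  if (fraction > 0) {
    A <- rbind(S, obj_row)
    rhs <- c(rep(0, nrow(S)), fraction * z_opt)
    sense <- c(rep("=", nrow(S)), ">=")
  } else {
    A <- S
    rhs <- rep(0, nrow(S))
    sense <- rep("=", nrow(S))
  }

  n <- length(reactions)
  mins <- maxs <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    j <- match(reactions[k], rxn_ids)
    cvec <- numeric(length(rxn_ids)); cvec[j] <- 1
    for (dir in c(FALSE, TRUE)) {
      r <- tryCatch(lp_solve(cvec, A, rhs, sense, lb, ub,
                             maximize = dir, tol = tol),
                    error = function(e) list(status = "error",
                                             message = conditionMessage(e)))
      if (r$status == "optimal") {
        if (dir) maxs[k] <- r$objective else mins[k] <- r$objective
      } else {
        warning("FVA ", if (dir) "max" else "min", " LP for reaction '",
                reactions[k], "' returned ", r$status, call. = FALSE)
      }
    }
  }
  structure(data.frame(reaction_id = reactions, min_flux = mins,
                       max_flux = maxs, fraction = fraction,
                       stringsAsFactors = FALSE),
            class = c("flux_ranges", "data.frame"))
}
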