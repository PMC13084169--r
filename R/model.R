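#' Construct a reaction
#'
#' A reaction is a signed stoichiometry over metabolite ids (negative =
#' consumed left-to-right), flux bounds, a pathway (subsystem) label and
#' an optional gene-protein-reaction (GPR) boolean rule string.
#' Non-finite bounds are stored as the conventional finite proxy
#' \eqn{\pm 1000}.
#'
#' @param id reaction identifier (unique within a model).
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#'   Exchange reactions may touch a single metabolite.
#' @param lower_bound,upper_bound flux bounds; `lower_bound <= upper_bound`.
#' @param name free-text name.
#' @param subsystem pathway label; defaults to `"unassigned"`.
#' @param gpr GPR rule string (see [parse_gpr()]), `""` if the reaction
#'   is not gene-associated.
#' @return an object of class `"fk_reaction"`.
#' @export
#' @examples
#' reaction("R1", c(A = -1, B = 1), 0, 10, subsystem = "core")
reaction <- function(id, stoichiometry, lower_bound = -1000,
                     upper_bound = 1000, name = id,
                     subsystem = "unassigned", gpr = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("reaction '", id, "': stoichiometry must be a named numeric vector")
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  if (all(stoichiometry == 0))
    stop("reaction '", id, "': stoichiometry has no nonzero coefficient")
  lower_bound <- clamp_bound(lower_bound)
  upper_bound <- clamp_bound(upper_bound)
  if (lower_bound > upper_bound)
    stop("reaction '", id, "': lower_bound (", lower_bound,
         ") exceeds upper_bound (", upper_bound, ")")
  st <- stoichiometry[stoichiometry != 0]
  st <- st[order(names(st))]           # canonical order for round-trips
  structure(list(id = unname(id), name = unname(name),
                 stoichiometry = st,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 subsystem = unname(subsystem), gpr = unname(gpr)),
            class = "fk_reaction")
}

clamp_bound <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x))
  if (!is.finite(x)) x <- sign(x) * 1000
  as.numeric(x)
}

#' Construct a genome-scale (or toy) metabolic model
#'
#' Bundles metabolites, reactions, genes and a growth objective into a
#' validated container. The stoichiometric matrix is a derived view
#' ([stoich_matrix()]), not stored.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of [reaction()] objects.
#' @param compartments named character vector mapping compartment codes
#'   to display names; defaults to the codes used by `metabolites`.
#' @param genes character vector of gene ids. Defaults to the genes
#'   referenced by the reactions' GPR rules; if supplied it must cover
#'   them.
#' @param objective_id id of the objective (biomass) reaction.
#' @param id model identifier.
#' @return an object of class `"metabolic_model"` with elements
#'   `metabolites` (data.frame), `reactions` (data.frame of id, name,
#'   bounds, subsystem, gpr), `stoichiometry` (named list of named
#'   numeric vectors), `gpr_ast` (parsed rules), `genes`,
#'   `compartments`, `objective_id`, `id`.
#' @export
metabolic_model <- function(metabolites, reactions, compartments = NULL,
                            genes = NULL, objective_id, id = "model") {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "compartment") %in% names(metabolites)))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  metabolites <- as.data.frame(metabolites)[, c("id", "name", "compartment")]
  metabolites$id <- as.character(metabolites$id)
  if (length(reactions) == 0L) stop("model has no reactions")
  if (inherits(reactions, "fk_reaction")) reactions <- list(reactions)
  stopifnot(all(vapply(reactions, inherits, TRUE, "fk_reaction")))

  rxn_df <- do.call(rbind, lapply(reactions, function(r)
    data.frame(id = r$id, name = r$name, lower_bound = r$lower_bound,
               upper_bound = r$upper_bound, subsystem = r$subsystem,
               gpr = r$gpr, stringsAsFactors = FALSE)))
  rownames(rxn_df) <- NULL
  stoich <- lapply(reactions, `[[`, "stoichiometry")
  names(stoich) <- rxn_df$id

  if (is.null(compartments)) {
    comps <- unique(metabolites$compartment)
    compartments <- stats::setNames(comps, comps)
  }
  gpr_ast <- lapply(rxn_df$gpr, function(s)
    if (nzchar(s)) parse_gpr(s) else NULL)
  names(gpr_ast) <- rxn_df$id
  used_genes <- unique(unlist(lapply(gpr_ast, function(a)
    if (is.null(a)) character(0) else gpr_genes(a))))
  if (is.null(genes)) genes <- used_genes
  genes <- sort(unique(as.character(genes)))

  model <- structure(list(
    id = id, metabolites = metabolites, reactions = rxn_df,
    stoichiometry = stoich, gpr_ast = gpr_ast, genes = genes,
    compartments = compartments, objective_id = objective_id),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness and disjointness, compartment membership,
#' bound ordering, stoichiometry resolution, GPR gene coverage and the
#' objective reference. Called by every constructor and reader.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (any(!nzchar(met_ids))) stop("empty metabolite id")
  if (anyDuplicated(met_ids))
    stop("duplicated metabolite id: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  if (anyDuplicated(rxn_ids))
    stop("duplicated reaction id: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  overlap <- intersect(met_ids, rxn_ids)
  if (length(overlap))
    stop("reaction and metabolite id spaces overlap: ",
         paste(overlap, collapse = ", "))
  bad_comp <- setdiff(model$metabolites$compartment, names(model$compartments))
  if (length(bad_comp))
    stop("undeclared compartment(s): ", paste(bad_comp, collapse = ", "))
  if (any(model$reactions$lower_bound > model$reactions$upper_bound))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxn_ids[model$reactions$lower_bound >
                         model$reactions$upper_bound], collapse = ", "))
  for (rid in rxn_ids) {
    unknown <- setdiff(names(model$stoichiometry[[rid]]), met_ids)
    if (length(unknown))
      stop("reaction '", rid, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  used <- unique(unlist(lapply(model$gpr_ast, function(a)
    if (is.null(a)) character(0) else gpr_genes(a))))
  missing_genes <- setdiff(used, model$genes)
  if (length(missing_genes))
    stop("GPR references gene(s) absent from the model gene set: ",
         paste(missing_genes, collapse = ", "))
  if (length(model$objective_id) != 1L ||
      !model$objective_id %in% rxn_ids)
    stop("objective_id '", model$objective_id,
         "' is not a reaction in the model")
  invisible(model)
}

#' Derived stoichiometric matrix
#'
#' One row per metabolite, one column per reaction; column `j`'s
#' nonzeros equal reaction `j`'s stoichiometry exactly.
#'
#' @param model a `metabolic_model`.
#' @return a sparse [Matrix::dgCMatrix-class] with dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[j]]]
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Reactions gated by a gene
#'
#' Exactly the reactions whose GPR rule mentions `gene`; an empty set
#' (with a message) if the gene is absent from every rule.
#'
#' @param model a `metabolic_model`.
#' @param gene gene id.
#' @return character vector of reaction ids.
#' @export
reactions_for_gene <- function(model, gene) {
  hit <- vapply(model$gpr_ast, function(a)
    !is.null(a) && gene %in% gpr_genes(a), TRUE)
  out <- model$reactions$id[hit]
  if (length(out) == 0L)
    message("gene '", gene, "' is not referenced by any GPR rule")
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  reactions:   ", nrow(x$reactions), "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  genes:       ", length(x$genes), "\n",
      "  objective:   ", x$objective_id, "\n", sep = "")
  invisible(x)
}

#' @export
format.fk_reaction <- function(x, ...) {
  st <- x$stoichiometry
  lhs <- st[st < 0]; rhs <- st[st > 0]
  side <- function(v, s) paste(ifelse(abs(v) == 1, "", paste0(abs(v), " ")),
                               names(v), sep = "", collapse = paste0(" ", s, " "))
  arrow <- if (x$lower_bound < 0) "<=>" else "-->"
  paste0(x$id, ": ", side(lhs, "+"), " ", arrow, " ", side(rhs, "+"),
         "  [", x$lower_bound, ", ", x$upper_bound, "]")
}

#' @export
print.fk_reaction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
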