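#' Read a metabolic model from the package JSON dialect
#'
#' The dialect (versioned `"schema": 1`) is a plain serialization of
#' [metabolic_model()]: top-level fields `schema`, `id`, `objective`,
#' `compartments` (code -> name map), `metabolites` (objects with `id`,
#' `name`, `compartment`), `reactions` (objects with `id`, `name`,
#' `stoichiometry` map, `lower_bound`, `upper_bound`, `subsystem`,
#' `gpr`) and `genes`. Stoichiometric coefficients are signed, negative
#' = consumed left-to-right.
#'
#' @param path file path.
#' @return a validated `metabolic_model`.
#' @seealso [write_json_model()], [read_sbml()]
#' @export
read_json_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  required <- c("schema", "id", "objective", "compartments",
                "metabolites", "reactions", "genes")
  missing <- setdiff(required, names(doc))
  extra <- setdiff(names(doc), required)
  if (length(missing) || length(extra))
    stop("model JSON schema violation in '", path, "':",
         if (length(missing)) paste0(" missing field(s) ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0(" unknown field(s) ",
                                   paste(extra, collapse = ", ")))
  if (!identical(as.integer(doc$schema), 1L))
    stop("unsupported model JSON schema version: ", doc$schema)
  if (length(doc$reactions) == 0L)
    stop("model JSON '", path, "' declares no reactions")

  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    need_fields(m, c("id", "compartment"), "metabolite")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment, stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    need_fields(r, c("id", "stoichiometry", "lower_bound", "upper_bound"),
                "reaction")
    reaction(id = r$id,
             stoichiometry = unlist(r$stoichiometry),
             lower_bound = r$lower_bound, upper_bound = r$upper_bound,
             name = r$name %||% r$id,
             subsystem = r$subsystem %||% "unassigned",
             gpr = r$gpr %||% "")
  })
  metabolic_model(metabolites = mets, reactions = rxns,
                  compartments = unlist(doc$compartments),
                  genes = unlist(doc$genes),
                  objective_id = doc$objective, id = doc$id)
}

need_fields <- function(x, fields, what) {
  missing <- setdiff(fields, names(x))
  if (length(missing))
    stop(what, " entry missing field(s): ", paste(missing, collapse = ", "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic model to the package JSON dialect
#'
#' `read_json_model(write_json_model(m, f))` reproduces `m` field by
#' field, and writing the same model twice yields byte-identical files.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_json_model <- function(model, path) {
  validate_model(model)
  doc <- list(
    schema = 1L,
    id = model$id,
    objective = model$objective_id,
    compartments = as.list(model$compartments),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           compartment = model$metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(model$reactions)), function(i) {
      rid <- model$reactions$id[i]
      list(id = rid,
           name = model$reactions$name[i],
           stoichiometry = as.list(model$stoichiometry[[rid]]),
           lower_bound = model$reactions$lower_bound[i],
           upper_bound = model$reactions$upper_bound[i],
           subsystem = model$reactions$subsystem[i],
           gpr = model$reactions$gpr[i])
    }),
    genes = as.list(model$genes))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
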