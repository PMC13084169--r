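#' Read a metabolic model from SBML Level 3 with the FBC extension
#'
#' Supports the subset of SBML used by constraint-based genome-scale
#' reconstructions (e.g. Human-GEM): species with compartments,
#' reactions with stoichiometry, flux bounds through FBC v2 bound
#' parameters, gene associations through `fbc:geneProductAssociation`,
#' the active FBC objective, and subsystems through the groups package
#' (falling back to a `SUBSYSTEM:` note, else `"unassigned"`). Species
#' flagged `boundaryCondition="true"` are dropped from the mass
#' balance, the usual convention for boundary pools.
#'
#' Level 2 files are rejected outright: they carry bounds in kinetic-law
#' parameters and guessing them silently would corrupt downstream flux
#' variability results. Missing FBC bounds are an error, never a default.
#'
#' @param path SBML file path.
#' @return a validated `metabolic_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  level <- xml2::xml_attr(doc, "level")
  if (is.na(level) || level != "3")
    stop("unsupported SBML level '", level,
         "': this reader requires Level 3 with the FBC v2 extension")
  one <- function(node, xp) xml2::xml_find_first(node, xp)
  all_of <- function(node, xp) xml2::xml_find_all(node, xp)
  lname <- function(nm) paste0("*[local-name()='", nm, "']")
  model_node <- one(doc, paste0("./", lname("model")))
  if (is.na(model_node)) stop("SBML file has no <model> element")
  attr_any <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hit <- at[names(at) == name | endsWith(names(at), paste0(":", name))]
    if (length(hit)) hit[[1]] else NA_character_
  }

  comps <- all_of(model_node, paste0("./", lname("listOfCompartments"),
                                     "/", lname("compartment")))
  compartments <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comps, "name")),
           xml2::xml_attr(comps, "id"), xml2::xml_attr(comps, "name")),
    xml2::xml_attr(comps, "id"))

  sp <- all_of(model_node, paste0("./", lname("listOfSpecies"),
                                  "/", lname("species")))
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)[!boundary, , drop = FALSE]
  boundary_ids <- xml2::xml_attr(sp, "id")[boundary]

  params <- all_of(model_node, paste0("./", lname("listOfParameters"),
                                      "/", lname("parameter")))
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  gps <- all_of(model_node, paste0(".//", lname("listOfGeneProducts"),
                                   "/", lname("geneProduct")))
  gp_id <- vapply(gps, attr_any, "", name = "id")
  gp_label <- vapply(gps, attr_any, "", name = "label")
  gene_of <- stats::setNames(ifelse(is.na(gp_label) | !nzchar(gp_label),
                                    gp_id, gp_label), gp_id)

  # subsystems via the groups extension
  subsystem_of <- character(0)
  for (g in all_of(model_node, paste0(".//", lname("listOfGroups"),
                                      "/", lname("group")))) {
    gname <- attr_any(g, "name")
    if (is.na(gname)) gname <- attr_any(g, "id")
    for (mem in all_of(g, paste0(".//", lname("member")))) {
      ref <- attr_any(mem, "idRef")
      if (!is.na(ref)) subsystem_of[ref] <- gname
    }
  }

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(node, "geneProduct")
      gene <- gene_of[ref]
      if (is.na(gene)) stop("geneProductRef to undeclared gene product '",
                            ref, "'")
      return(unname(gene))
    }
    if (nm %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      return(list(op = nm, args = lapply(kids, parse_assoc)))
    }
    stop("unsupported element <", nm, "> in geneProductAssociation")
  }

  rx_nodes <- all_of(model_node, paste0("./", lname("listOfReactions"),
                                        "/", lname("reaction")))
  if (length(rx_nodes) == 0L) stop("SBML model declares no reactions")
  rxns <- lapply(rx_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    lb_ref <- attr_any(rn, "lowerFluxBound")
    ub_ref <- attr_any(rn, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref))
      stop("reaction '", rid, "' lacks FBC flux bound attributes; ",
           "refusing to guess bounds")
    if (is.na(pvals[lb_ref]) || is.na(pvals[ub_ref]))
      stop("reaction '", rid, "' references undefined bound parameter(s)")
    st <- numeric(0)
    for (sr in all_of(rn, paste0("./", lname("listOfReactants"),
                                 "/", lname("speciesReference")))) {
      sid <- xml2::xml_attr(sr, "species")
      st[sid] <- (st[sid] %|na|% 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
    }
    for (sr in all_of(rn, paste0("./", lname("listOfProducts"),
                                 "/", lname("speciesReference")))) {
      sid <- xml2::xml_attr(sr, "species")
      st[sid] <- (st[sid] %|na|% 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry") %|na|% "1")
    }
    st <- st[!names(st) %in% boundary_ids]
    if (length(st) == 0L)
      stop("reaction '", rid, "' touches no non-boundary species")
    assoc <- one(rn, paste0("./", lname("geneProductAssociation"), "/*"))
    gpr <- if (!is.na(assoc)) {
      tree <- parse_assoc(assoc)
      if (is.character(tree)) tree else gpr_to_string(tree)
    } else ""
    sub <- subsystem_of[rid]
    if (is.na(sub) || !length(sub)) {
      note <- one(rn, paste0("./", lname("notes"), "//",
                             "*[contains(text(), 'SUBSYSTEM:')]"))
      sub <- if (!is.na(note))
        trimws(sub("^.*SUBSYSTEM:", "", xml2::xml_text(note)))
      else "unassigned"
    }
    reaction(id = rid,
             name = xml2::xml_attr(rn, "name") %|na|% rid,
             stoichiometry = st,
             lower_bound = pvals[[lb_ref]], upper_bound = pvals[[ub_ref]],
             subsystem = sub, gpr = gpr)
  })

  objectives <- all_of(model_node, paste0(".//", lname("listOfObjectives")))
  if (length(objectives) == 0L) stop("SBML model has no FBC objective")
  active <- attr_any(objectives[[1]], "activeObjective")
  obj_xpath <- paste0(".//", lname("objective"))
  obj_nodes <- all_of(objectives[[1]], obj_xpath)
  obj_node <- obj_nodes[[max(1L, which(vapply(obj_nodes, attr_any, "",
                                              name = "id") == active)[1])]]
  fo <- all_of(obj_node, paste0(".//", lname("fluxObjective")))
  if (length(fo) == 0L) stop("active FBC objective lists no flux objective")
  objective_id <- attr_any(fo[[1]], "reaction")

  metabolic_model(metabolites = mets, reactions = rxns,
                  compartments = compartments,
                  objective_id = objective_id,
                  id = xml2::xml_attr(model_node, "id") %|na|% "model")
}

`%|na|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a metabolic model as SBML Level 3 + FBC v2
#'
#' Emits the same subset [read_sbml()] consumes (bound parameters, gene
#' products keyed by gene id, groups for subsystems), so that
#' `read_sbml(write_sbml(m, f))` reproduces `m`.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- xml_escape
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
           " level=\"3\" version=\"1\"",
           " xmlns:fbc=\"http://www.sbml.org/sbml/level3/version1/fbc/version2\"",
           " fbc:required=\"false\"",
           " xmlns:groups=\"http://www.sbml.org/sbml/level3/version1/groups/version1\"",
           " groups:required=\"false\">"),
    paste0("  <model id=\"", esc(model$id), "\" fbc:strict=\"true\">"),
    "    <listOfCompartments>",
    sprintf("      <compartment id=\"%s\" name=\"%s\" constant=\"true\"/>",
            esc(names(model$compartments)), esc(unname(model$compartments))),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf(paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\"",
                   " hasOnlySubstanceUnits=\"false\"",
                   " boundaryCondition=\"false\" constant=\"false\"/>"),
            esc(model$metabolites$id), esc(model$metabolites$name),
            esc(model$metabolites$compartment)),
    "    </listOfSpecies>",
    "    <listOfParameters>")
  rx <- model$reactions
  for (i in seq_len(nrow(rx))) {
    out <- c(out, sprintf(
      "      <parameter id=\"lb_%d\" value=\"%s\" constant=\"true\"/>",
      i, num(rx$lower_bound[i])), sprintf(
      "      <parameter id=\"ub_%d\" value=\"%s\" constant=\"true\"/>",
      i, num(rx$upper_bound[i])))
  }
  out <- c(out, "    </listOfParameters>")
  if (length(model$genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
             sprintf(paste0("      <fbc:geneProduct fbc:id=\"GP_%d\"",
                            " fbc:label=\"%s\"/>"),
                     seq_along(model$genes), esc(model$genes)),
             "    </fbc:listOfGeneProducts>")
  }
  gp_id <- stats::setNames(sprintf("GP_%d", seq_along(model$genes)),
                           model$genes)
  assoc_xml <- function(expr, indent) {
    pad <- strrep(" ", indent)
    if (is.character(expr))
      return(sprintf("%s<fbc:geneProductRef fbc:geneProduct=\"%s\"/>",
                     pad, gp_id[[expr]]))
    c(sprintf("%s<fbc:%s>", pad, expr$op),
      unlist(lapply(expr$args, assoc_xml, indent = indent + 2)),
      sprintf("%s</fbc:%s>", pad, expr$op))
  }
  out <- c(out, "    <listOfReactions>")
  for (i in seq_len(nrow(rx))) {
    rid <- rx$id[i]
    st <- model$stoichiometry[[rid]]
    out <- c(out, sprintf(
      paste0("      <reaction id=\"%s\" name=\"%s\" reversible=\"%s\"",
             " fast=\"false\" fbc:lowerFluxBound=\"lb_%d\"",
             " fbc:upperFluxBound=\"ub_%d\">"),
      esc(rid), esc(rx$name[i]),
      if (rx$lower_bound[i] < 0) "true" else "false", i, i))
    side <- function(coefs, tag) {
      if (!length(coefs)) return(character(0))
      c(sprintf("        <listOf%s>", tag),
        sprintf(paste0("          <speciesReference species=\"%s\"",
                       " stoichiometry=\"%s\" constant=\"true\"/>"),
                esc(names(coefs)), num(abs(unname(coefs)))),
        sprintf("        </listOf%s>", tag))
    }
    out <- c(out, side(st[st < 0], "Reactants"), side(st[st > 0], "Products"))
    ast <- model$gpr_ast[[rid]]
    if (!is.null(ast)) {
      out <- c(out, "        <fbc:geneProductAssociation>",
               assoc_xml(ast$expression, 10),
               "        </fbc:geneProductAssociation>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>",
           "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
           "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
           "        <fbc:listOfFluxObjectives>",
           sprintf(paste0("          <fbc:fluxObjective fbc:reaction=\"%s\"",
                          " fbc:coefficient=\"1\"/>"),
                   esc(model$objective_id)),
           "        </fbc:listOfFluxObjectives>",
           "      </fbc:objective>",
           "    </fbc:listOfObjectives>")
  subs <- split(rx$id, rx$subsystem)
  subs <- subs[names(subs) != "unassigned"]
  if (length(subs)) {
    out <- c(out, "    <groups:listOfGroups>")
    for (k in seq_along(subs)) {
      out <- c(out, sprintf(
        paste0("      <groups:group groups:id=\"sub_%d\"",
               " groups:kind=\"partonomy\" groups:name=\"%s\">"),
        k, esc(names(subs)[k])),
        "        <groups:listOfMembers>",
        sprintf("          <groups:member groups:idRef=\"%s\"/>",
                esc(subs[[k]])),
        "        </groups:listOfMembers>",
        "      </groups:group>")
    }
    out <- c(out, "    </groups:listOfGroups>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}
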