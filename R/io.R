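#' Load a metabolic model from file
#'
#' Reads either SBML Level 3 with the FBC extension or the BiGG-style JSON
#' model dialect. The format is inferred from the file extension unless
#' given explicitly. GPR strings are retained verbatim.
#'
#' @param path model file.
#' @param format `"auto"` (default), `"sbml"` or `"json"`.
#' @return a validated [metabolic_network()].
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xml = "sbml", sbml = "sbml", json = "json",
                     stop("cannot infer model format from extension '.", ext,
                          "'; pass format explicitly"))
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Read a model in the BiGG-style JSON dialect
#'
#' @param path JSON file with `metabolites`, `reactions`, `genes` arrays.
#' @return a [metabolic_network()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("malformed JSON model '", path, "': missing metabolites or reactions")
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id %||% stop("metabolite without id"),
                character(1)),
    formula = vapply(doc$metabolites, function(m) as.character(m$formula %||% NA),
                     character(1)),
    compartment = vapply(doc$metabolites, function(m) as.character(m$compartment %||% ""),
                         character(1)),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = vapply(doc$reactions, function(r) r$id %||% stop("reaction without id"),
                character(1)),
    lower_bound = vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% -1000),
                         numeric(1)),
    upper_bound = vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% 1000),
                         numeric(1)),
    subsystem = vapply(doc$reactions, function(r) as.character(r$subsystem %||% ""),
                       character(1)),
    gpr = vapply(doc$reactions, function(r) as.character(r$gene_reaction_rule %||% ""),
                 character(1)),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) stop("reaction '", r$id, "' has no metabolites")
    st
  })
  genes <- vapply(doc$genes %||% list(), function(g)
    if (is.list(g)) g$id else as.character(g), character(1))
  objective <- doc$objective %||% NULL
  metabolic_network(mets, rx, genes = genes,
                    objective = if (is.null(objective)) NULL else as.character(objective))
}

#' Write a model in the BiGG-style JSON dialect
#'
#' @param net a [metabolic_network()].
#' @param path output file.
#' @param provenance optional named list stored under a `provenance` key
#'   (e.g. extraction method and parent model id).
#' @return `path`, invisibly.
#' @export
write_model_json <- function(net, path, provenance = NULL) {
  doc <- list(
    metabolites = lapply(seq_len(nrow(net$metabolites)), function(i) list(
      id = net$metabolites$id[i],
      formula = if (is.na(net$metabolites$formula[i])) NULL else net$metabolites$formula[i],
      compartment = net$metabolites$compartment[i])),
    reactions = lapply(seq_len(nrow(net$reactions)), function(i) list(
      id = net$reactions$id[i],
      metabolites = as.list(net$reactions$stoichiometry[[i]]),
      lower_bound = net$reactions$lower_bound[i],
      upper_bound = net$reactions$upper_bound[i],
      subsystem = net$reactions$subsystem[i],
      gene_reaction_rule = net$reactions$gpr[i])),
    genes = lapply(net$genes, function(g) list(id = g)))
  if (!is.null(net$objective)) doc$objective <- net$objective
  if (!is.null(provenance)) doc$provenance <- provenance
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# strip BiGG SBML id prefixes (R_/M_/G_)
strip_sbml_prefix <- function(id, prefix) sub(paste0("^", prefix, "_"), "", id)

# render an fbc:geneProductAssociation subtree to a GPR string
sbml_gpa_to_rule <- function(node, labels) {
  name <- xml2::xml_name(node)
  if (name == "geneProductRef") {
    gp <- xml2::xml_attr(node, "geneProduct")
    lab <- labels[gp]
    return(if (length(lab) && !is.na(lab)) unname(lab) else strip_sbml_prefix(gp, "G"))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpa_to_rule, character(1), labels = labels)
  op <- if (name == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

#' Read an SBML Level 3 FBC model
#'
#' A minimal reader for the flux-balance subset of SBML used by genome-scale
#' reconstructions: species with chemical formulas, reactions with
#' stoichiometry, flux bounds referenced through global parameters, gene
#' product associations, and (optionally) subsystem groups. BiGG id prefixes
#' (`M_`, `R_`, `G_`) are stripped.
#'
#' @param path SBML file.
#' @return a [metabolic_network()].
#' @export
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
          g = "http://www.sbml.org/sbml/level3/version1/groups/version1")

  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  glabels <- stats::setNames(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id"))

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("malformed SBML '", path, "': no species found")
  mets <- data.frame(
    id = strip_sbml_prefix(xml2::xml_attr(sp, "id"), "M"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rxn_nodes)) stop("malformed SBML '", path, "': no reactions found")
  n <- length(rxn_nodes)
  rx <- data.frame(id = character(n), lower_bound = numeric(n),
                   upper_bound = numeric(n), subsystem = "", gpr = "",
                   stringsAsFactors = FALSE)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rxn_nodes[[i]]
    rid <- xml2::xml_attr(node, "id")
    rx$id[i] <- strip_sbml_prefix(rid, "R")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rx$lower_bound[i] <- if (!is.na(lb_ref)) pval[[lb_ref]] else -1000
    rx$upper_bound[i] <- if (!is.na(ub_ref)) pval[[ub_ref]] else 1000
    st <- numeric(0)
    add_refs <- function(xpath, sign) {
      for (ref in xml2::xml_find_all(node, xpath, ns)) {
        mid <- strip_sbml_prefix(xml2::xml_attr(ref, "species"), "M")
        coef <- xml2::xml_attr(ref, "stoichiometry")
        coef <- if (is.na(coef)) 1 else as.numeric(coef)
        cur <- if (mid %in% names(st)) st[[mid]] else 0
        st[mid] <<- cur + sign * coef
      }
    }
    add_refs("./s:listOfReactants/s:speciesReference", -1)
    add_refs("./s:listOfProducts/s:speciesReference", +1)
    if (!length(st)) stop("malformed SBML: reaction '", rid, "' has no participants")
    stoich[[i]] <- st
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    if (!inherits(gpa, "xml_missing")) {
      rule <- sbml_gpa_to_rule(gpa, glabels)
      rx$gpr[i] <- sub("^\\((.*)\\)$", "\\1", rule)
    }
  }
  rx$stoichiometry <- stoich

  groups <- xml2::xml_find_all(doc, ".//g:listOfGroups/g:group", ns)
  for (gr in groups) {
    label <- xml2::xml_attr(gr, "name")
    if (is.na(label)) label <- xml2::xml_attr(gr, "id")
    members <- xml2::xml_find_all(gr, ".//g:member", ns)
    ids <- strip_sbml_prefix(xml2::xml_attr(members, "idRef"), "R")
    rx$subsystem[rx$id %in% ids] <- label
  }

  genes <- unname(glabels[!is.na(glabels)])
  metabolic_network(mets, rx, genes = genes)
}
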