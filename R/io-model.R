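#' Read a genome-scale metabolic model
#'
#' Supports the community COBRA-style JSON dialect (as distributed for
#' Human1/HumanGem-class models) and an SBML Level-3 + FBC subset
#' (species/reactions/bounds/objective/gene-product associations). GPR
#' strings are parsed into expression trees and infinite bounds are capped
#' at `bound_cap` so downstream mixed-integer constraints are well-posed.
#'
#' @param path Path to the model file.
#' @param format `"json"` or `"sbml"`; `NULL` guesses from the extension.
#' @param bound_cap Finite replacement for infinite bounds (default 1000).
#' @return A [metabolic_network()].
#' @export
read_metabolic_model <- function(path, format = NULL, bound_cap = 1000) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else {
      "json"
    }
  }
  format <- match.arg(format, c("json", "sbml"))
  switch(format,
    json = read_model_json(path, bound_cap),
    sbml = read_model_sbml(path, bound_cap)
  )
}

read_model_json <- function(path, bound_cap) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("malformed JSON model: missing 'metabolites' or 'reactions' list",
         call. = FALSE)
  }
  mets <- tibble::tibble(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(doc$metabolites, function(m) {
      as.character(m$name %||% m$id)
    }, character(1)),
    compartment = vapply(doc$metabolites, function(m) {
      as.character(m$compartment %||% "")
    }, character(1)),
    tag = vapply(doc$metabolites, function(m) {
      t <- m$notes$tag
      if (is.null(t)) NA_real_ else as.numeric(t)
    }, numeric(1))
  )
  num_or <- function(x, default) {
    if (is.null(x)) return(default)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x)) default else x
  }
  rxns <- tibble::tibble(
    id = vapply(doc$reactions, function(r) as.character(r$id), character(1)),
    name = vapply(doc$reactions, function(r) {
      as.character(r$name %||% r$id)
    }, character(1)),
    lower_bound = vapply(doc$reactions, function(r) {
      num_or(r$lower_bound, -bound_cap)
    }, numeric(1)),
    upper_bound = vapply(doc$reactions, function(r) {
      num_or(r$upper_bound, bound_cap)
    }, numeric(1)),
    subsystem = vapply(doc$reactions, function(r) {
      s <- r$subsystem
      if (is.null(s) || length(s) == 0L) NA_character_ else as.character(s[[1]])
    }, character(1)),
    gpr_text = vapply(doc$reactions, function(r) {
      as.character(r$gene_reaction_rule %||% "")
    }, character(1)),
    stoichiometry = lapply(doc$reactions, function(r) {
      s <- unlist(r$metabolites)
      stats::setNames(as.numeric(s), names(s))
    }),
    objective_coefficient = vapply(doc$reactions, function(r) {
      num_or(r$objective_coefficient, 0)
    }, numeric(1))
  )
  obj <- rxns$id[rxns$objective_coefficient != 0]
  if (length(obj) == 0L) {
    stop("model declares no objective reaction (no nonzero ",
         "objective_coefficient)", call. = FALSE)
  }
  rxns$objective_coefficient <- NULL
  metabolic_network(
    id = as.character(doc$id %||% basename(path)),
    metabolites = mets, reactions = rxns,
    objective = obj[1], bound_cap = bound_cap
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metabolic network as COBRA-style JSON
#'
#' Inverse of the JSON branch of [read_metabolic_model()]; a
#' read-write-read round-trip reproduces the network.
#'
#' @param net A `metabolic_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metabolic_model <- function(net, path) {
  mets <- lapply(seq_len(nrow(net$metabolites)), function(i) {
    m <- net$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.null(m$tag) && !is.na(m$tag)) out$notes <- list(tag = m$tag)
    out
  })
  rxns <- lapply(seq_len(nrow(net$reactions)), function(i) {
    r <- net$reactions[i, ]
    list(
      id = r$id,
      name = r$name,
      metabolites = as.list(r$stoichiometry[[1]]),
      lower_bound = r$lower_bound,
      upper_bound = r$upper_bound,
      subsystem = if (is.na(r$subsystem)) NULL else r$subsystem,
      gene_reaction_rule = r$gpr_text,
      objective_coefficient = if (r$id == net$objective) 1 else 0
    )
  })
  doc <- list(
    id = net$id,
    metabolites = mets,
    reactions = rxns,
    genes = lapply(
      sort(unique(unlist(lapply(net$reactions$gpr, gpr_genes)))),
      function(g) list(id = g)
    ),
    compartments = as.list(stats::setNames(
      net$compartments, net$compartments
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# --- SBML L3 + FBC subset ---------------------------------------------------

sbml_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
  v
}

read_model_sbml <- function(path, bound_cap) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    stop("malformed SBML: no <model> element", call. = FALSE)
  }

  params <- xml2::xml_find_all(model, ".//*[local-name()='parameter']")
  pval <- stats::setNames(
    as.numeric(xml2::xml_attr(params, "value")),
    xml2::xml_attr(params, "id")
  )

  gps <- xml2::xml_find_all(model, ".//*[local-name()='geneProduct']")
  glabel <- stats::setNames(
    vapply(gps, function(g) {
      lbl <- sbml_attr(g, "label")
      if (is.na(lbl)) sbml_attr(g, "id") else lbl
    }, character(1)),
    vapply(gps, function(g) sbml_attr(g, "id"), character(1))
  )

  species <- xml2::xml_find_all(model, ".//*[local-name()='species']")
  mets <- tibble::tibble(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    tag = NA_real_
  )
  boundary <- xml2::xml_attr(species, "boundaryCondition") %in% "true"
  mets <- mets[!boundary, , drop = FALSE]

  gpa_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- sbml_attr(node, "geneProduct")
      lbl <- glabel[ref]
      return(if (is.na(lbl)) ref else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_text, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rnodes <- xml2::xml_find_all(model,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  met_ids <- mets$id
  parse_side <- function(rn, xpath, sign) {
    refs <- xml2::xml_find_all(rn, xpath)
    if (length(refs) == 0L) return(numeric(0))
    sp <- xml2::xml_attr(refs, "species")
    st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    st[is.na(st)] <- 1
    stats::setNames(sign * st, sp)
  }
  rows <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    st <- c(parse_side(rn,
      "./*[local-name()='listOfReactants']/*[local-name()='speciesReference']",
      -1),
            parse_side(rn,
      "./*[local-name()='listOfProducts']/*[local-name()='speciesReference']",
      +1))
    unknown <- setdiff(names(st), xml2::xml_attr(species, "id"))
    if (length(unknown) > 0) {
      stop(sprintf("SBML reaction '%s' references undeclared species '%s'",
                   rid, unknown[1]), call. = FALSE)
    }
    # boundary-condition species are dropped; reactions touching only them
    # become exchange-style boundary reactions
    st_known <- st[names(st) %in% met_ids]
    lb_ref <- sbml_attr(rn, "lowerFluxBound")
    ub_ref <- sbml_attr(rn, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pval)) {
      pval[[lb_ref]]
    } else if (rev) {
      -bound_cap
    } else {
      0
    }
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pval)) {
      pval[[ub_ref]]
    } else {
      bound_cap
    }
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']")
    gpr_text <- if (inherits(gpa, "xml_missing")) {
      ""
    } else {
      gpa_to_text(xml2::xml_child(gpa))
    }
    notes <- xml2::xml_find_first(rn, ".//p[contains(text(),'SUBSYSTEM')]")
    subsystem <- if (inherits(notes, "xml_missing")) {
      NA_character_
    } else {
      trimws(sub("^.*SUBSYSTEM:", "", xml2::xml_text(notes)))
    }
    list(id = rid,
         name = ifelse(is.na(xml2::xml_attr(rn, "name")), rid,
                       xml2::xml_attr(rn, "name")),
         lower_bound = lb, upper_bound = ub, subsystem = subsystem,
         gpr_text = gpr_text, stoichiometry = st_known)
  })
  rxns <- tibble::tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    name = vapply(rows, `[[`, character(1), "name"),
    lower_bound = vapply(rows, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(rows, `[[`, numeric(1), "upper_bound"),
    subsystem = vapply(rows, `[[`, character(1), "subsystem"),
    gpr_text = vapply(rows, `[[`, character(1), "gpr_text"),
    stoichiometry = lapply(rows, `[[`, "stoichiometry")
  )

  fobj <- xml2::xml_find_first(model, ".//*[local-name()='fluxObjective']")
  if (inherits(fobj, "xml_missing")) {
    stop("SBML model declares no FBC objective", call. = FALSE)
  }
  obj <- sbml_attr(fobj, "reaction")

  metabolic_network(
    id = xml2::xml_attr(model, "id") %||% basename(path),
    metabolites = mets, reactions = rxns, objective = obj,
    bound_cap = bound_cap
  )
}
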