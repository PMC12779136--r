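#' Construct a metabolic network object
#'
#' The central container for a constraint-based (stoichiometric) model:
#' metabolites with compartments, reactions with bounds, subsystem
#' annotation and GPR rules, and a biomass objective reaction. Flux units
#' follow the model file (conventionally mmol/gDW/h); stoichiometric
#' coefficients are dimensionless.
#'
#' @param id Model identifier.
#' @param metabolites Tibble/data frame with columns `id`, `name`,
#'   `compartment`, and optionally `tag` (a small integer conservation tag,
#'   e.g. carbon count, used by mass-balance checks on toy models).
#' @param reactions Tibble/data frame with columns `id`, `name`,
#'   `lower_bound`, `upper_bound`, `subsystem`, `gpr_text`, and list-columns
#'   `stoichiometry` (named numeric: metabolite id -> signed coefficient)
#'   and optionally `gpr` (parsed trees; parsed from `gpr_text` if absent),
#'   plus optionally `is_exchange`.
#' @param objective Reaction id of the biomass (objective) reaction.
#' @param bound_cap Finite cap replacing infinite bounds (default 1000,
#'   the community convention), so MILP big-M constraints stay well-posed.
#' @return An object of class `metabolic_network`.
#' @export
metabolic_network <- function(id, metabolites, reactions, objective,
                              bound_cap = 1000) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
  if (!"gpr_text" %in% names(reactions)) reactions$gpr_text <- ""
  reactions$gpr_text[is.na(reactions$gpr_text)] <- ""
  if (!"gpr" %in% names(reactions)) {
    reactions$gpr <- lapply(reactions$gpr_text, parse_gpr)
  }
  reactions$lower_bound <- pmax(as.numeric(reactions$lower_bound), -bound_cap)
  reactions$upper_bound <- pmin(as.numeric(reactions$upper_bound), bound_cap)
  if (!"is_exchange" %in% names(reactions)) {
    reactions$is_exchange <- vapply(
      reactions$stoichiometry, function(s) length(s) == 1L, logical(1)
    )
  }
  net <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      compartments = sort(unique(metabolites$compartment)),
      objective = objective
    ),
    class = "metabolic_network"
  )
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks the structural invariants: stoichiometries reference only
#' declared metabolites, the objective reaction exists, bounds are ordered
#' and finite, and ids are unique.
#'
#' @param net A `metabolic_network`.
#' @return `net`, invisibly; errors describe the offending element.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  mids <- net$metabolites$id
  rids <- net$reactions$id
  if (anyDuplicated(mids)) {
    stop("duplicate metabolite id: ", mids[duplicated(mids)][1], call. = FALSE)
  }
  if (anyDuplicated(rids)) {
    stop("duplicate reaction id: ", rids[duplicated(rids)][1], call. = FALSE)
  }
  for (k in seq_along(rids)) {
    s <- net$reactions$stoichiometry[[k]]
    bad <- setdiff(names(s), mids)
    if (length(bad) > 0) {
      stop(sprintf("reaction '%s' references undeclared metabolite '%s'",
                   rids[k], bad[1]), call. = FALSE)
    }
    if (length(s) == 0L) {
      stop(sprintf("reaction '%s' has empty stoichiometry", rids[k]),
           call. = FALSE)
    }
  }
  if (!net$objective %in% rids) {
    stop(sprintf("objective reaction '%s' not found in model", net$objective),
         call. = FALSE)
  }
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("non-finite reaction bounds after canonicalization", call. = FALSE)
  }
  if (any(lb > ub)) {
    stop(sprintf("reaction '%s' has lower_bound > upper_bound",
                 rids[which(lb > ub)[1]]), call. = FALSE)
  }
  invisible(net)
}

#' Stoichiometric matrix of a network
#'
#' @param net A `metabolic_network`.
#' @return Dense numeric matrix S (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(net) {
  m <- length(net$metabolites$id)
  n <- length(net$reactions$id)
  S <- matrix(0, m, n, dimnames = list(net$metabolites$id, net$reactions$id))
  for (k in seq_len(n)) {
    s <- net$reactions$stoichiometry[[k]]
    S[names(s), k] <- unname(s)
  }
  S
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf(
    "<metabolic_network '%s'> %d metabolites, %d reactions, %d compartments\n",
    x$id, nrow(x$metabolites), nrow(x$reactions), length(x$compartments)
  ))
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' Reactions of a network as a tibble
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @return Tibble of reaction annotations (id, bounds, subsystem, gpr_text,
#'   is_exchange), one row per reaction.
#' @export
tidy.metabolic_network <- function(x, ...) {
  dplyr::select(
    x$reactions, "id", "lower_bound", "upper_bound", "subsystem",
    "gpr_text", "is_exchange"
  )
}

#' One-row summary of a network
#'
#' @param x A `metabolic_network`.
#' @param ... Unused.
#' @export
glance.metabolic_network <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_exchange = sum(x$reactions$is_exchange),
    n_with_gpr = sum(!vapply(x$reactions$gpr, is.null, logical(1))),
    n_compartments = length(x$compartments),
    objective = x$objective
  )
}
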