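#' Flux balance analysis with deterministic flux selection
#'
#' Solves the standard FBA linear program — maximize the biomass
#' (objective) reaction flux subject to steady state `S v = 0` and the
#' reaction bounds — and then, among the alternate optima, returns the
#' flux vector minimizing total absolute flux at the fixed optimal
#' biomass (a parsimonious second stage). The second stage removes the
#' alternate-optimum nondeterminism that otherwise makes downstream flux
#' features solver-order dependent; set `minimize_total_flux = FALSE` for
#' the raw single-stage solution.
#'
#' @param x A `metabolic_network` or a `context_model` (from
#'   [imat_extract()]); for a context model the retained network is used.
#' @param minimize_total_flux Run the parsimonious second stage
#'   (default `TRUE`).
#' @param sample_id Sample identifier recorded on the profile (taken from
#'   a context model automatically).
#' @return A `flux_profile`: list with `sample_id`, `fluxes` (named
#'   numeric, one entry per reaction), and `objective_value`.
#' @export
run_fba <- function(x, minimize_total_flux = TRUE, sample_id = NULL) {
  if (inherits(x, "context_model")) {
    if (is.null(sample_id)) sample_id <- x$sample_id
    net <- x$network
  } else {
    net <- x
  }
  stopifnot(inherits(net, "metabolic_network"))
  S <- stoich_matrix(net)
  n <- ncol(S)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  obj <- as.numeric(net$reactions$id == net$objective)

  s1 <- solve_lp(obj, lb, ub, A_eq = S, b_eq = rep(0, nrow(S)),
                 maximize = TRUE)
  if (s1$status != "optimal") {
    stop("FBA infeasible for sample ",
         if (is.null(sample_id)) "<unnamed>" else sample_id, call. = FALSE)
  }
  v <- s1$x
  opt <- s1$objval

  if (minimize_total_flux) {
    # split v = p - q, p,q >= 0; minimize sum(p + q) at fixed biomass
    p_lb <- pmax(lb, 0); p_ub <- pmax(ub, 0)
    q_lb <- pmax(-ub, 0); q_ub <- pmax(-lb, 0)
    A_eq <- cbind(S, -S)
    b_eq <- rep(0, nrow(S))
    # biomass >= opt - slack (as <= row)
    slack <- 1e-9 * max(1, abs(opt))
    A_le <- matrix(c(-obj, obj), nrow = 1)
    b_le <- -(opt - slack)
    s2 <- solve_lp(rep(1, 2 * n), c(p_lb, q_lb), c(p_ub, q_ub),
                   A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
                   maximize = FALSE)
    if (s2$status == "optimal") {
      v <- s2$x[seq_len(n)] - s2$x[n + seq_len(n)]
      opt <- sum(obj * v)
    }
  }
  v[abs(v) < 1e-11] <- 0
  structure(
    list(
      sample_id = if (is.null(sample_id)) NA_character_ else sample_id,
      fluxes = stats::setNames(v, net$reactions$id),
      objective_value = opt
    ),
    class = "flux_profile"
  )
}

#' @export
print.flux_profile <- function(x, ...) {
  cat(sprintf("<flux_profile '%s'> %d reactions, biomass = %.6g\n",
              x$sample_id, length(x$fluxes), x$objective_value))
  invisible(x)
}

#' Flux profile as a tibble
#'
#' @param x A `flux_profile`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `reaction_id`, `flux`.
#' @export
tidy.flux_profile <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    reaction_id = names(x$fluxes),
    flux = unname(x$fluxes)
  )
}

#' Gross production rate of a metabolite pool
#'
#' Sums, over every reaction and every matching metabolite (across all
#' compartments), the positive part of coefficient x flux. Consumption is
#' not subtracted: this is the total gross production of the pool, the
#' quantity used by the energy-cofactor filtration envelope.
#'
#' @param fp A `flux_profile`.
#' @param net The `metabolic_network` the profile was computed on.
#' @param metabolite_base Base metabolite name, e.g. `"ATP"`, `"NADH"`,
#'   `"NADPH"`. Matched case-insensitively against metabolite names and
#'   against id prefixes of the form `<base>_<compartment>`.
#' @return A single non-negative rate (model flux units).
#' @export
production_rate <- function(fp, net, metabolite_base) {
  stopifnot(inherits(fp, "flux_profile"), inherits(net, "metabolic_network"))
  base <- tolower(metabolite_base)
  ids <- net$metabolites$id
  hits <- ids[tolower(net$metabolites$name) == base |
                grepl(paste0("^", base, "(_|$)"), tolower(ids))]
  if (length(hits) == 0L) {
    stop("no metabolite matches base '", metabolite_base, "'",
         call. = FALSE)
  }
  total <- 0
  for (k in seq_len(nrow(net$reactions))) {
    rid <- net$reactions$id[k]
    if (!rid %in% names(fp$fluxes)) next
    s <- net$reactions$stoichiometry[[k]]
    m <- intersect(names(s), hits)
    if (length(m) == 0L) next
    total <- total + sum(pmax(0, s[m] * fp$fluxes[[rid]]))
  }
  unname(total)
}
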