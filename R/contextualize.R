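# Per-sample context-specific model construction: GPR mapping of
# expression onto reactions, ternary discretization, and iMAT extraction.

#' Map gene expression onto reactions through GPR rules
#'
#' Evaluates each reaction's GPR against one sample's expression values
#' using the standard COBRA convention: `and` (complex) takes the minimum
#' of its operand levels, `or` (isozymes) the maximum. Genes absent from
#' the matrix are treated as missing rather than zero: an `and` node uses
#' the minimum over present operands only, and a reaction whose GPR genes
#' are all absent (or that has no GPR) is unmapped.
#'
#' @param m An [expr_matrix()].
#' @param net A `metabolic_network`.
#' @param sample_id Sample to map.
#' @return Tibble with columns `reaction_id`, `expression` (`NA` when
#'   unmapped), `mapped`; attribute `sample_id`.
#' @export
map_expression_to_reactions <- function(m, net, sample_id) {
  stopifnot(inherits(m, "expr_matrix"), inherits(net, "metabolic_network"))
  if (!sample_id %in% colnames(m$values)) {
    stop("unknown sample id: ", sample_id, call. = FALSE)
  }
  vals <- m$values[, sample_id]
  expr <- vapply(net$reactions$gpr, eval_gpr, numeric(1), values = vals)
  out <- tibble::tibble(
    reaction_id = net$reactions$id,
    expression = expr,
    mapped = !is.na(expr)
  )
  attr(out, "sample_id") <- sample_id
  out
}

#' Discretize reaction expression into ternary states
#'
#' Computes the mean and standard deviation of the mapped reaction
#' expression levels of one sample and assigns state +1 (highly
#' expressed) to reactions above mean + `sd_multiplier` * SD, -1 (lowly
#' expressed) below mean - `sd_multiplier` * SD, and 0 otherwise.
#' Unmapped reactions get state 0 and are left unconstrained by iMAT.
#' The default multiplier of 0.3 produces a split comparable to
#' quartile-based cutoffs on expression-like distributions.
#'
#' @param v Reaction expression tibble from
#'   [map_expression_to_reactions()].
#' @param sd_multiplier Threshold width in SD units (default 0.3).
#' @return Tibble with columns `reaction_id`, `state` (-1, 0, +1);
#'   attribute `sample_id`.
#' @export
discretize <- function(v, sd_multiplier = 0.3) {
  stopifnot(sd_multiplier >= 0)
  mapped <- v$expression[v$mapped]
  if (length(mapped) < 2L) {
    stop("need at least 2 mapped reactions to discretize", call. = FALSE)
  }
  mu <- mean(mapped)
  s <- stats::sd(mapped)
  state <- integer(nrow(v))
  if (s == 0) {
    warning("all mapped reaction expression values identical; ",
            "all states set to 0", call. = FALSE)
  } else {
    hi <- mu + sd_multiplier * s
    lo <- mu - sd_multiplier * s
    state[v$mapped & v$expression > hi] <- 1L
    state[v$mapped & v$expression < lo] <- -1L
  }
  out <- tibble::tibble(reaction_id = v$reaction_id, state = state)
  attr(out, "sample_id") <- attr(v, "sample_id")
  out
}

#' Extract a context-specific model with iMAT
#'
#' Solves the iMAT mixed-integer program: find a steady-state flux
#' distribution maximizing the number of highly expressed reactions
#' carrying flux of magnitude at least `epsilon` (in either direction)
#' plus the number of lowly expressed reactions carrying no flux.
#' Formally, with `R_H` the reactions of state +1 and `R_L` of state -1,
#' maximize `sum(y_plus + y_minus)` over `R_H` plus `sum(y_zero)` over
#' `R_L`, subject to `S v = 0`, bounds, and the indicator constraints
#' `v_i + y_plus_i (lb_i - eps) >= lb_i`,
#' `v_i + y_minus_i (ub_i + eps) <= ub_i` for `R_H`, and
#' `lb_i (1 - y_zero_i) <= v_i <= ub_i (1 - y_zero_i)` for `R_L`.
#'
#' The context model retains reactions with `|v| > activity_tol` in the
#' returned optimum (plus the objective reaction, always); all other
#' reactions have their bounds closed to (0, 0). With
#' `enforce_activity = TRUE` (default) the highly expressed reactions
#' rewarded in the optimum also keep their iMAT activity in the retained
#' network — their bound toward the active direction is tightened to
#' `epsilon` — so that downstream flux prediction reflects the state
#' iMAT selected rather than silently re-zeroing expression-supported
#' fluxes that do not feed the objective.
#'
#' @param net A `metabolic_network`.
#' @param states Ternary state tibble from [discretize()].
#' @param epsilon Activation flux threshold (model units, default 1).
#' @param activity_tol Flux magnitude below which a reaction is inactive
#'   in the solution (default 1e-6). Must be < `epsilon`.
#' @param mip_gap Absolute optimality gap for the branch and bound
#'   (default 1e-6).
#' @param enforce_activity Tighten bounds of rewarded highly expressed
#'   reactions to keep them active (default `TRUE`).
#' @return A `context_model`: list with `sample_id`, `parent_id`,
#'   `active` (character vector of retained reaction ids), `network`
#'   (the bounded network), `imat_objective`, and `imat_fluxes`.
#' @export
imat_extract <- function(net, states, epsilon = 1, activity_tol = 1e-6,
                         mip_gap = 1e-6, enforce_activity = TRUE) {
  stopifnot(inherits(net, "metabolic_network"),
            activity_tol > 0, activity_tol < epsilon)
  st <- stats::setNames(states$state, states$reaction_id)
  rids <- net$reactions$id
  missing <- setdiff(rids, names(st))
  if (length(missing) > 0) st[missing] <- 0L
  st <- st[rids]

  S <- stoich_matrix(net)
  n <- ncol(S)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  iH <- which(st == 1L)
  iL <- which(st == -1L)
  nH <- length(iH)
  nL <- length(iL)
  nv <- n + 2L * nH + nL  # v, y+, y-, y0

  A_eq <- cbind(S, matrix(0, nrow(S), 2L * nH + nL))
  b_eq <- rep(0, nrow(S))

  rows <- list()
  rhs <- numeric(0)
  add_row <- function(r, b) {
    rows[[length(rows) + 1L]] <<- r
    rhs[length(rhs) + 1L] <<- b
  }
  for (k in seq_along(iH)) {
    i <- iH[k]
    # v_i + y+ (lb_i - eps) >= lb_i   ->  -v_i - y+ (lb_i - eps) <= -lb_i
    r <- numeric(nv); r[i] <- -1; r[n + k] <- -(lb[i] - epsilon)
    add_row(r, -lb[i])
    # v_i + y- (ub_i + eps) <= ub_i
    r <- numeric(nv); r[i] <- 1; r[n + nH + k] <- ub[i] + epsilon
    add_row(r, ub[i])
  }
  for (k in seq_along(iL)) {
    i <- iL[k]
    # v_i >= lb_i (1 - y0)  ->  -v_i - lb_i y0 <= -lb_i
    r <- numeric(nv); r[i] <- -1; r[n + 2L * nH + k] <- -lb[i]
    add_row(r, -lb[i])
    # v_i <= ub_i (1 - y0)
    r <- numeric(nv); r[i] <- 1; r[n + 2L * nH + k] <- ub[i]
    add_row(r, ub[i])
  }
  A_le <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  b_le <- if (length(rows) > 0) rhs else NULL

  obj <- c(rep(0, n), rep(1, 2L * nH + nL))
  lbv <- c(lb, rep(0, 2L * nH + nL))
  ubv <- c(ub, rep(1, 2L * nH + nL))
  bin_idx <- if (nH + nL > 0) n + seq_len(2L * nH + nL) else integer(0)

  sol <- solve_milp(obj, lbv, ubv, A_eq = A_eq, b_eq = b_eq,
                    A_le = A_le, b_le = b_le, bin_idx = bin_idx,
                    maximize = TRUE, integral_objective = TRUE,
                    gap = mip_gap)
  if (sol$status != "optimal") {
    stop("iMAT MILP reported infeasible (this indicates inconsistent ",
         "bounds: v = 0 should always be feasible)", call. = FALSE)
  }
  v <- sol$x[seq_len(n)]
  active <- rids[abs(v) > activity_tol]
  active <- union(active, net$objective)

  kept <- net
  closed <- !(rids %in% active)
  kept$reactions$lower_bound[closed] <- 0
  kept$reactions$upper_bound[closed] <- 0
  if (enforce_activity && nH > 0) {
    yplus <- sol$x[n + seq_len(nH)] > 0.5
    yminus <- sol$x[n + nH + seq_len(nH)] > 0.5
    for (k in seq_along(iH)) {
      i <- iH[k]
      if (yplus[k] && v[i] > activity_tol) {
        kept$reactions$lower_bound[i] <- max(kept$reactions$lower_bound[i],
                                             epsilon)
      } else if (yminus[k] && v[i] < -activity_tol) {
        kept$reactions$upper_bound[i] <- min(kept$reactions$upper_bound[i],
                                             -epsilon)
      }
    }
  }

  structure(
    list(
      sample_id = attr(states, "sample_id") %||% NA_character_,
      parent_id = net$id,
      active = active,
      network = kept,
      imat_objective = round(sol$objval),
      imat_fluxes = stats::setNames(v, rids)
    ),
    class = "context_model"
  )
}

#' @export
print.context_model <- function(x, ...) {
  cat(sprintf(
    "<context_model '%s'> %d/%d reactions active (iMAT objective %d)\n",
    x$sample_id, length(x$active), nrow(x$network$reactions),
    x$imat_objective
  ))
  invisible(x)
}

#' Contextualize one sample end to end
#'
#' Convenience wrapper: GPR mapping, discretization, iMAT extraction and
#' two-stage FBA for a single sample.
#'
#' @inheritParams map_expression_to_reactions
#' @inheritParams discretize
#' @inheritParams imat_extract
#' @param minimize_total_flux Passed to [run_fba()].
#' @return List with `context` (the `context_model`) and `profile`
#'   (the `flux_profile`).
#' @export
contextualize_sample <- function(m, net, sample_id, sd_multiplier = 0.3,
                                 epsilon = 1, activity_tol = 1e-6,
                                 mip_gap = 1e-6,
                                 minimize_total_flux = TRUE) {
  rv <- map_expression_to_reactions(m, net, sample_id)
  st <- discretize(rv, sd_multiplier)
  cm <- imat_extract(net, st, epsilon, activity_tol, mip_gap)
  fp <- run_fba(cm, minimize_total_flux = minimize_total_flux)
  list(context = cm, profile = fp)
}
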