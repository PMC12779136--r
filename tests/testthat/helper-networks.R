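# Shared fixtures: tiny hand-built networks, random networks, and the
# brute-force iMAT oracle used to validate the MILP.

# linear chain: R1 (uptake) -> A -> B -> C -> R4 (drain); objective R4
make_chain_net <- function(ub = 10) {
  mets <- tibble::tibble(
    id = c("A", "B", "C"), name = c("A", "B", "C"),
    compartment = "c", tag = NA_real_
  )
  rxns <- tibble::tibble(
    id = c("R1", "R2", "R3", "R4"),
    lower_bound = 0,
    upper_bound = c(ub, 1000, 1000, 1000),
    subsystem = NA_character_,
    gpr_text = "",
    stoichiometry = list(
      c(A = 1), c(A = -1, B = 1), c(B = -1, C = 1), c(C = -1)
    )
  )
  metabolic_network("chain", mets, rxns, objective = "R4")
}

# random small network with a mix of reversible/irreversible reactions
make_random_net <- function(seed, max_rxns = 8) {
  set.seed(seed)
  repeat {
    n <- sample(4:max_rxns, 1)
    m <- sample(2:4, 1)
    S <- matrix(sample(c(-1, 0, 0, 0, 1), m * n, TRUE), m, n)
    keep <- colSums(abs(S)) > 0
    S <- S[, keep, drop = FALSE]
    if (ncol(S) >= 3) break
  }
  n <- ncol(S)
  mets <- tibble::tibble(
    id = paste0("M", seq_len(m)), name = paste0("M", seq_len(m)),
    compartment = "c", tag = NA_real_
  )
  stoich <- lapply(seq_len(n), function(j) {
    s <- S[, j]
    names(s) <- mets$id
    s[s != 0]
  })
  rxns <- tibble::tibble(
    id = paste0("R", seq_len(n)),
    lower_bound = ifelse(stats::runif(n) < 0.5, -10, 0),
    upper_bound = 10,
    subsystem = NA_character_,
    gpr_text = "",
    stoichiometry = stoich
  )
  metabolic_network(paste0("rnd", seed), mets, rxns, objective = rxns$id[1])
}

# Brute-force iMAT oracle: enumerate, per highly expressed reaction,
# {unrewarded, active forward, active backward} and, per lowly expressed
# reaction, {unrewarded, held at zero}; check LP feasibility of each
# assignment and return the best achievable reward count.
imat_oracle <- function(net, states, epsilon = 1) {
  S <- stoich_matrix(net)
  n <- ncol(S)
  lb <- net$reactions$lower_bound
  ub <- net$reactions$upper_bound
  st <- stats::setNames(states$state, states$reaction_id)[net$reactions$id]
  iH <- which(st == 1)
  iL <- which(st == -1)
  opts <- c(rep(list(0:2), length(iH)), rep(list(0:1), length(iL)))
  grid <- if (length(opts) > 0) expand.grid(opts) else data.frame(row.names = 1)
  best <- -1
  for (g in seq_len(max(nrow(grid), 1))) {
    a <- if (ncol(grid) > 0) as.integer(grid[g, ]) else integer(0)
    ha <- a[seq_along(iH)]
    la <- if (length(iL)) a[length(iH) + seq_along(iL)] else integer(0)
    score <- sum(ha > 0) + sum(la)
    if (score <= best) next
    lb2 <- lb
    ub2 <- ub
    bad <- FALSE
    for (k in seq_along(iH)) {
      i <- iH[k]
      if (ha[k] == 1) lb2[i] <- max(lb2[i], epsilon)
      if (ha[k] == 2) ub2[i] <- min(ub2[i], -epsilon)
      if (lb2[i] > ub2[i]) {
        bad <- TRUE
        break
      }
    }
    if (!bad) {
      for (k in seq_along(iL)) {
        if (la[k] == 1) {
          lb2[iL[k]] <- 0
          ub2[iL[k]] <- 0
        }
      }
    }
    if (bad) next
    r <- fluxgan:::solve_lp(rep(0, n), lb2, ub2,
                            A_eq = S, b_eq = rep(0, nrow(S)))
    if (r$status == "optimal") best <- score
  }
  best
}

# hand-built flux profile on a network (for filter tests)
make_profile <- function(net, fluxes, sample_id = "p") {
  v <- stats::setNames(rep(0, nrow(net$reactions)), net$reactions$id)
  v[names(fluxes)] <- fluxes
  structure(
    list(sample_id = sample_id, fluxes = v,
         objective_value = unname(v[net$objective])),
    class = "flux_profile"
  )
}
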