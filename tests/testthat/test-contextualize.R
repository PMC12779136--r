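# Expression-to-reaction mapping, ternary discretization, iMAT
# extraction, FBA, and production rates.

test_that("GPR mapping follows the min/max and present-operand rules", {
  mets <- tibble::tibble(id = "A", name = "A", compartment = "c",
                         tag = NA_real_)
  rxns <- tibble::tibble(
    id = c("Ror", "Rand", "Rabs", "Rnone"),
    lower_bound = 0, upper_bound = 10,
    subsystem = NA_character_,
    gpr_text = c("gA or gB", "gA and gB", "gA and gZ", ""),
    stoichiometry = list(c(A = 1), c(A = 1), c(A = -1), c(A = -1))
  )
  net <- metabolic_network("t", mets, rxns, objective = "Rnone")
  vals <- matrix(c(5, 2), 2, 1, dimnames = list(c("gA", "gB"), "s1"))
  m <- expr_matrix(vals, c(s1 = "healthy"))
  rv <- map_expression_to_reactions(m, net, "s1")
  expect_equal(rv$expression[rv$reaction_id == "Ror"], 5)
  expect_equal(rv$expression[rv$reaction_id == "Rand"], 2)
  # absent operand in an AND: min over present operands only
  expect_equal(rv$expression[rv$reaction_id == "Rabs"], 5)
  expect_true(is.na(rv$expression[rv$reaction_id == "Rnone"]))
  expect_false(rv$mapped[rv$reaction_id == "Rnone"])
})

test_that("discretization thresholds match hand-computed mean +/- 0.3 SD", {
  v <- tibble::tibble(
    reaction_id = paste0("R", 1:6),
    expression = c(1, 2, 3, 4, 10, NA),
    mapped = c(rep(TRUE, 5), FALSE)
  )
  st <- discretize(v, sd_multiplier = 0.3)
  # mu = 4, sample SD = 3.5355; hi = 5.0607, lo = 2.9393
  expect_equal(st$state, c(-1L, -1L, 0L, 0L, 1L, 0L))

  # constant vector: all states 0 with a warning
  vc <- tibble::tibble(reaction_id = paste0("R", 1:3),
                       expression = c(2, 2, 2), mapped = TRUE)
  expect_warning(stc <- discretize(vc), "identical")
  expect_equal(stc$state, c(0L, 0L, 0L))

  # sd_multiplier = 0: strictly above/below the mean
  st0 <- discretize(v, sd_multiplier = 0)
  expect_equal(st0$state, c(-1L, -1L, -1L, 0L, 1L, 0L))
})

test_that("iMAT matches hand-derived optima on the linear chain", {
  net <- make_chain_net(ub = 10)
  allH <- tibble::tibble(reaction_id = paste0("R", 1:4), state = 1L)
  # expected objective computed with the enumeration oracle
  expect_equal(imat_oracle(net, allH, epsilon = 1), 4)
  cm <- imat_extract(net, allH, epsilon = 1)
  expect_equal(cm$imat_objective, 4)
  expect_true(all(abs(cm$imat_fluxes) >= 1 - 1e-9))

  # a lowly expressed reaction on the only path: its silence reward is
  # incompatible with activating the rest
  mixed <- tibble::tibble(reaction_id = paste0("R", 1:4),
                          state = c(1L, -1L, 1L, 1L))
  expect_equal(imat_oracle(net, mixed, epsilon = 1), 3)
  expect_equal(imat_extract(net, mixed, epsilon = 1)$imat_objective, 3)

  # no states: vacuous objective, the objective reaction is retained
  none <- tibble::tibble(reaction_id = paste0("R", 1:4), state = 0L)
  cm0 <- imat_extract(net, none, epsilon = 1)
  expect_equal(cm0$imat_objective, 0)
  expect_true("R4" %in% cm0$active)
})

test_that("iMAT equals the enumeration oracle on random networks", {
  for (s in 1:12) {
    net <- make_random_net(seed = 1000 + s)
    set.seed(2000 + s)
    states <- tibble::tibble(
      reaction_id = net$reactions$id,
      state = sample(c(-1L, 0L, 1L), nrow(net$reactions), TRUE)
    )
    cm <- imat_extract(net, states, epsilon = 1)
    expect_equal(cm$imat_objective, imat_oracle(net, states, epsilon = 1),
                 info = paste("net", s))
  }
})

test_that("FBA solves the capacity-limited chain and is order-invariant", {
  net <- make_chain_net(ub = 10)
  fp <- run_fba(net)
  expect_equal(fp$objective_value, 10, tolerance = 1e-8)
  expect_equal(unname(fp$fluxes[c("R2", "R3")]), c(10, 10),
               tolerance = 1e-8)

  # column permutation leaves the optimum unchanged
  set.seed(5)
  perm <- sample(nrow(net$reactions))
  net2 <- net
  net2$reactions <- net$reactions[perm, ]
  expect_lt(abs(run_fba(net2)$objective_value - fp$objective_value), 1e-8)

  # mass balance of a produced profile
  S <- stoich_matrix(net)
  expect_lt(max(abs(S %*% fp$fluxes)), 1e-6)
})

test_that("two-stage FBA returns the flux-minimal routing", {
  # A can reach the drain directly (R2) or via a 2-step detour (R3+R4)
  mets <- tibble::tibble(id = c("A", "B"), name = c("A", "B"),
                         compartment = "c", tag = NA_real_)
  rxns <- tibble::tibble(
    id = c("IN", "R2", "R3", "R4", "OUT"),
    lower_bound = 0, upper_bound = c(5, 1000, 1000, 1000, 1000),
    subsystem = NA_character_, gpr_text = "",
    stoichiometry = list(c(A = 1), c(A = -1, C = 1), c(A = -1, B = 1),
                         c(B = -1, C = 1), c(C = -1))
  )
  mets <- dplyr::bind_rows(mets, tibble::tibble(
    id = "C", name = "C", compartment = "c", tag = NA_real_
  ))
  net <- metabolic_network("par", mets, rxns, objective = "OUT")
  fp <- run_fba(net)
  expect_equal(fp$objective_value, 5, tolerance = 1e-8)
  # independent check: minimal total flux routes everything through R2
  expect_equal(unname(fp$fluxes[["R2"]]), 5, tolerance = 1e-8)
  expect_equal(unname(fp$fluxes[["R3"]]), 0, tolerance = 1e-8)
  expect_equal(sum(abs(fp$fluxes)), 15, tolerance = 1e-6)
})

test_that("production_rate sums gross production with sign handling", {
  mets <- tibble::tibble(
    id = c("atp_c", "atp_m", "x_c"),
    name = c("atp_c", "atp_m", "x_c"),
    compartment = c("c", "m", "c"), tag = NA_real_
  )
  rxns <- tibble::tibble(
    id = c("P", "CONS", "REV"),
    lower_bound = c(0, 0, -10), upper_bound = 10,
    subsystem = NA_character_, gpr_text = "",
    stoichiometry = list(c(atp_c = 2, x_c = -1), c(atp_c = -1, x_c = 1),
                         c(atp_m = -1, x_c = 1))
  )
  net <- metabolic_network("pr", mets, rxns, objective = "P")
  # producer 2 ATP at flux 3 -> 6; consumption not subtracted
  fp1 <- make_profile(net, c(P = 3))
  expect_equal(production_rate(fp1, net, "ATP"), 6)
  fp2 <- make_profile(net, c(P = 3, CONS = 6))
  expect_equal(production_rate(fp2, net, "ATP"), 6)
  # reversible consumer running backwards produces: -1 * -4 = 4
  fp3 <- make_profile(net, c(REV = -4))
  expect_equal(production_rate(fp3, net, "ATP"), 4)
  expect_error(production_rate(fp1, net, "NADPH"), "no metabolite")
})

test_that("enforce_activity keeps rewarded reactions active downstream", {
  net <- build_toy_network()
  st <- tibble::tibble(reaction_id = net$reactions$id, state = 0L)
  st$state[st$reaction_id == "FAt"] <- 1L
  cm <- imat_extract(net, st, epsilon = 1)
  fp <- run_fba(cm)
  expect_gte(unname(fp$fluxes[["FAt"]]), 1 - 1e-9)
  # without enforcement the parsimonious stage re-zeroes the branch
  cm2 <- imat_extract(net, st, epsilon = 1, enforce_activity = FALSE)
  fp2 <- run_fba(cm2)
  expect_lt(abs(fp2$fluxes[["FAt"]]), 1e-9)
})
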