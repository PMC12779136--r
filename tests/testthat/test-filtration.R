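# Biological filtration: envelope, GDI, gluconeogenesis, and the
# three-stage chain on a constructed candidate battery.

# battery on the toy network: flux profiles with controlled ATP
# production (via TCA flux), lactate secretion, and GNG flux.
battery_profile <- function(net, id, tca = 5, lac = 0, gng = 0,
                            glc_uptake = 10) {
  make_profile(net, c(
    TCA = tca, EX_lac = lac, GNG = gng, EX_glc = -glc_uptake,
    GLYC = 2, PPP = 1
  ), sample_id = id)
}

test_that("envelope is the component-wise min/max and order-invariant", {
  net <- build_toy_network()
  profs <- lapply(seq_along(c(5, 8, 6, 7)), function(i) {
    battery_profile(net, paste0("r", i), tca = c(5, 8, 6, 7)[i])
  })
  env <- build_envelope(profs, net)
  atp <- env[env$metabolite == "ATP", ]
  # ATP rate = 3 (GLYC) + 12 * TCA flux
  expect_equal(atp$min, 6 + 12 * 5)
  expect_equal(atp$max, 6 + 12 * 8)
  env2 <- build_envelope(rev(profs), net)
  expect_equal(env, env2)
  # single profile: degenerate envelope
  env1 <- build_envelope(profs[1], net)
  expect_equal(env1$min, env1$max)
  expect_error(build_envelope(list(), net), "at least one")
})

test_that("energy filter keeps boundary cases and names the failing pool", {
  net <- build_toy_network()
  refs <- lapply(c(5, 8), function(t) battery_profile(net, paste0("r", t),
                                                      tca = t))
  env <- build_envelope(refs, net)
  at_max <- battery_profile(net, "edge", tca = 8)
  inside <- battery_profile(net, "mid", tca = 6)
  # fails only NADPH: PPP flux off the reference range
  bad_nadph <- battery_profile(net, "nadph", tca = 6)
  bad_nadph$fluxes[["PPP"]] <- 50
  r <- filter_energy(list(at_max, inside, bad_nadph), env, net)
  expect_equal(r$report$n_removed, 1)
  expect_equal(r$report$removed[[1]]$sample_id, "nadph")
  expect_equal(r$report$removed[[1]]$reason, "NADPH")
  r2 <- filter_energy(list(inside), env, net)
  expect_equal(r2$report$n_removed, 0)
})

test_that("GDI arithmetic matches hand values and direction conventions", {
  net <- build_toy_network()
  expect_equal(compute_gdi(battery_profile(net, "a", lac = 0,
                                           glc_uptake = 10)), 0)
  expect_equal(compute_gdi(battery_profile(net, "b", lac = 5,
                                           glc_uptake = 10)), 0.5)
  # lactate absorption (negative exchange) is not secretion
  expect_equal(compute_gdi(battery_profile(net, "c", lac = -2,
                                           glc_uptake = 10)), 0)
  expect_error(compute_gdi(battery_profile(net, "d", glc_uptake = 0)),
               "GDI undefined|glucose")
})

test_that("GDI filter applies the zero tolerance", {
  net <- build_toy_network()
  cands <- list(
    battery_profile(net, "zero", lac = 0),
    battery_profile(net, "tiny", lac = 5e-6),   # GDI 5e-7 <= 1e-6
    battery_profile(net, "warburg", lac = 4),
    battery_profile(net, "noglc", glc_uptake = 0)
  )
  r <- filter_gdi(cands)
  kept <- vapply(r$survivors, `[[`, character(1), "sample_id")
  expect_setequal(kept, c("zero", "tiny"))
  expect_equal(r$report$n_removed, 2)
  reasons <- r$report$removed[[1]]
  expect_match(reasons$reason[reasons$sample_id == "noglc"], "glucose")
})

test_that("gluconeogenesis filter uses the marker direction convention", {
  net <- build_toy_network()
  cands <- list(
    battery_profile(net, "off", gng = 0),
    battery_profile(net, "on", gng = 2.3),
    battery_profile(net, "reverse", gng = -1)  # glycolytic direction
  )
  r <- filter_gluconeogenesis(cands, "GNG", net)
  kept <- vapply(r$survivors, `[[`, character(1), "sample_id")
  expect_setequal(kept, c("off", "reverse"))
  expect_error(filter_gluconeogenesis(cands, "NOPE", net), "NOPE")
})

test_that("the 10-candidate battery yields stage reports 10 -> 7 -> 5 -> 4", {
  net <- build_toy_network()
  refs <- lapply(c(5, 8), function(t) battery_profile(net, paste0("ref", t),
                                                      tca = t))
  cands <- c(
    # 3 fail the energy envelope (TCA outside [5, 8])
    lapply(1:3, function(i) battery_profile(net, paste0("e", i), tca = 20)),
    # 2 pass energy, fail GDI
    lapply(1:2, function(i) battery_profile(net, paste0("g", i), tca = 6,
                                            lac = 3)),
    # 1 passes both, fails gluconeogenesis
    list(battery_profile(net, "n1", tca = 6, gng = 2)),
    # 4 clean survivors
    lapply(1:4, function(i) battery_profile(net, paste0("ok", i),
                                            tca = 5 + i * 0.5))
  )
  res <- run_filtration(cands, refs, net)
  expect_equal(res$report$n_in, c(10, 7, 5))
  expect_equal(res$report$n_removed, c(3, 2, 1))
  expect_equal(res$report$n_out, c(7, 5, 4))
  expect_setequal(vapply(res$survivors, `[[`, character(1), "sample_id"),
                  paste0("ok", 1:4))
  # every removed sample carries exactly one first-failure reason
  removed <- dplyr::bind_rows(res$report$removed)
  expect_equal(nrow(removed), 6)
  expect_false(anyDuplicated(removed$sample_id) > 0)

  # the final survivor set is invariant to filter order
  env <- build_envelope(refs, net)
  stages <- list(
    energy = function(x) filter_energy(x, env, net)$survivors,
    gdi = function(x) filter_gdi(x)$survivors,
    gng = function(x) filter_gluconeogenesis(x, "GNG", net)$survivors
  )
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    out <- cands
    for (k in p) out <- stages[[k]](out)
    expect_setequal(vapply(out, `[[`, character(1), "sample_id"),
                    paste0("ok", 1:4))
  }
})

test_that("empty candidate list yields three zero reports", {
  net <- build_toy_network()
  refs <- list(battery_profile(net, "r1"))
  res <- run_filtration(list(), refs, net)
  expect_equal(nrow(res$report), 3)
  expect_true(all(res$report$n_in == 0))
  expect_length(res$survivors, 0)
})

test_that("candidates identical to a reference profile all survive", {
  net <- build_toy_network()
  refs <- lapply(c(5, 8), function(t) battery_profile(net, paste0("r", t),
                                                      tca = t))
  cands <- lapply(1:3, function(i) battery_profile(net, paste0("c", i),
                                                   tca = 5))
  res <- run_filtration(cands, refs, net)
  expect_length(res$survivors, 3)
})
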