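# Biological filtration of candidate (synthetic) flux profiles.
#
# Three screens, applied in sequence, mirror what a physiologically
# plausible healthy tissue model must satisfy: (1) ATP/NADH/NADPH gross
# production inside the envelope spanned by the real healthy profiles;
# (2) a Glycolysis Disorder Index of zero — no aerobic lactate secretion
# relative to glucose uptake (the Warburg signature); (3) no flux through
# gluconeogenesis marker reactions (an ATP-consuming program inactive in
# well-nourished cells).

#' Energy-cofactor production envelope of reference profiles
#'
#' Component-wise minimum and maximum of the gross production rates of
#' ATP, NADH and NADPH over the real reference (healthy) flux profiles.
#'
#' @param real_profiles List of `flux_profile` objects (>= 1).
#' @param net The parent `metabolic_network`.
#' @param bases Metabolite pools to track (default ATP, NADH, NADPH).
#' @return Tibble with columns `metabolite`, `min`, `max` of class
#'   `reference_envelope`.
#' @export
build_envelope <- function(real_profiles, net,
                           bases = c("ATP", "NADH", "NADPH")) {
  if (length(real_profiles) == 0L) {
    stop("need at least one real reference profile", call. = FALSE)
  }
  rates <- vapply(
    real_profiles,
    function(fp) vapply(bases, function(b) production_rate(fp, net, b),
                        numeric(1)),
    numeric(length(bases))
  )
  rates <- matrix(rates, nrow = length(bases))
  out <- tibble::tibble(
    metabolite = bases,
    min = apply(rates, 1, min),
    max = apply(rates, 1, max)
  )
  class(out) <- c("reference_envelope", class(out))
  out
}

filter_report <- function(stage, removed_ids, reasons, n_in) {
  tibble::tibble(
    stage = stage,
    n_in = n_in,
    n_removed = length(removed_ids),
    n_out = n_in - length(removed_ids),
    pct_removed = if (n_in > 0) 100 * length(removed_ids) / n_in else 0,
    removed = list(tibble::tibble(sample_id = removed_ids,
                                  reason = reasons))
  )
}

#' Energy-production envelope filter
#'
#' A candidate survives iff, for every tracked metabolite pool, its gross
#' production rate lies inside the reference envelope (bounds inclusive:
#' a candidate on the boundary is retained).
#'
#' @param cands List of candidate `flux_profile` objects.
#' @param env A `reference_envelope` from [build_envelope()].
#' @param net The parent `metabolic_network`.
#' @return List with `survivors` (list of profiles) and `report`
#'   (one-row filter tibble; `removed` list-column holds ids + reasons).
#' @export
filter_energy <- function(cands, env, net) {
  removed <- character(0)
  reasons <- character(0)
  keep <- logical(length(cands))
  for (i in seq_along(cands)) {
    fp <- cands[[i]]
    fail <- NULL
    for (k in seq_len(nrow(env))) {
      r <- production_rate(fp, net, env$metabolite[k])
      if (r < env$min[k] - 1e-9 || r > env$max[k] + 1e-9) {
        fail <- env$metabolite[k]
        break
      }
    }
    if (is.null(fail)) {
      keep[i] <- TRUE
    } else {
      removed <- c(removed, fp$sample_id)
      reasons <- c(reasons, fail)
    }
  }
  list(survivors = cands[keep],
       report = filter_report("energy", removed, reasons, length(cands)))
}

#' Glycolysis Disorder Index of a flux profile
#'
#' `GDI = max(0, lactate secretion) / |glucose uptake|`, using the COBRA
#' exchange convention: negative exchange flux is uptake, positive is
#' secretion. Lactate absorption (negative lactate exchange) counts as
#' zero secretion. A profile without measurable glucose uptake
#' (|flux| <= `zero_tol`) has no defined GDI and raises an error.
#'
#' @param fp A `flux_profile`.
#' @param lactate_exchange_id,glucose_exchange_id Exchange reaction ids.
#' @param zero_tol Numerical zero for fluxes (default 1e-6).
#' @return A single non-negative dimensionless ratio.
#' @export
compute_gdi <- function(fp, lactate_exchange_id = "EX_lac",
                        glucose_exchange_id = "EX_glc",
                        zero_tol = 1e-6) {
  for (id in c(lactate_exchange_id, glucose_exchange_id)) {
    if (!id %in% names(fp$fluxes)) {
      stop("exchange reaction '", id, "' not in flux profile",
           call. = FALSE)
    }
  }
  glc <- fp$fluxes[[glucose_exchange_id]]
  if (!(glc < 0) || abs(glc) <= zero_tol) {
    stop("no glucose uptake (exchange flux ", signif(glc, 4),
         "); GDI undefined", call. = FALSE)
  }
  lac <- fp$fluxes[[lactate_exchange_id]]
  max(0, lac) / abs(glc)
}

#' Warburg (GDI) filter
#'
#' Retains candidates whose GDI is zero up to `zero_tol` — i.e. models
#' secreting no lactate while taking up glucose, the expected phenotype
#' of healthy oxidative tissue. Candidates with undefined GDI (no glucose
#' uptake) are removed.
#'
#' @inheritParams filter_energy
#' @inheritParams compute_gdi
#' @return As [filter_energy()].
#' @export
filter_gdi <- function(cands, lactate_exchange_id = "EX_lac",
                       glucose_exchange_id = "EX_glc", zero_tol = 1e-6) {
  removed <- character(0)
  reasons <- character(0)
  keep <- logical(length(cands))
  for (i in seq_along(cands)) {
    fp <- cands[[i]]
    gdi <- tryCatch(
      compute_gdi(fp, lactate_exchange_id, glucose_exchange_id, zero_tol),
      error = function(e) NA_real_
    )
    if (is.na(gdi)) {
      removed <- c(removed, fp$sample_id)
      reasons <- c(reasons, "no glucose uptake")
    } else if (gdi > zero_tol) {
      removed <- c(removed, fp$sample_id)
      reasons <- c(reasons, sprintf("GDI = %.4g", gdi))
    } else {
      keep[i] <- TRUE
    }
  }
  list(survivors = cands[keep],
       report = filter_report("gdi", removed, reasons, length(cands)))
}

#' Gluconeogenesis filter
#'
#' Retains candidates with no flux (beyond `flux_tol`, in the
#' gluconeogenic direction) through any marker reaction. Reverse
#' (glycolytic-direction) flux through a reversible marker does not
#' disqualify.
#'
#' @inheritParams filter_energy
#' @param marker_reaction_ids Reaction ids marking gluconeogenesis (for
#'   the toy network, `"GNG"`; for a human genome-scale model, the
#'   glucose-6-phosphatase / fructose-1,6-bisphosphatase / PEPCK
#'   reactions).
#' @param net Parent network (used to validate the marker ids).
#' @param flux_tol Numerical zero for fluxes (default 1e-6).
#' @return As [filter_energy()].
#' @export
filter_gluconeogenesis <- function(cands, marker_reaction_ids = "GNG",
                                   net = NULL, flux_tol = 1e-6) {
  if (!is.null(net)) {
    bad <- setdiff(marker_reaction_ids, net$reactions$id)
    if (length(bad) > 0) {
      stop("unknown gluconeogenesis marker reaction id: ", bad[1],
           call. = FALSE)
    }
  }
  removed <- character(0)
  reasons <- character(0)
  keep <- logical(length(cands))
  for (i in seq_along(cands)) {
    fp <- cands[[i]]
    flux <- vapply(marker_reaction_ids, function(id) {
      if (id %in% names(fp$fluxes)) fp$fluxes[[id]] else 0
    }, numeric(1))
    if (any(flux > flux_tol)) {
      removed <- c(removed, fp$sample_id)
      reasons <- c(reasons,
                   sprintf("gluconeogenesis flux %.4g",
                           max(flux)))
    } else {
      keep[i] <- TRUE
    }
  }
  list(survivors = cands[keep],
       report = filter_report("gluconeogenesis", removed, reasons,
                              length(cands)))
}

#' Run the three-stage filtration chain
#'
#' Applies the energy envelope, GDI and gluconeogenesis screens in order
#' and reports per-stage counts. The three screens are independent
#' predicates, so the final survivor set does not depend on their order
#' (only the intermediate reports do).
#'
#' @param cands List of candidate `flux_profile` objects.
#' @param real_profiles List of reference (real minority) profiles.
#' @param net Parent `metabolic_network`.
#' @param lactate_exchange_id,glucose_exchange_id,zero_tol GDI settings.
#' @param marker_reaction_ids,flux_tol Gluconeogenesis settings.
#' @return List with `survivors` (profiles passing all three) and
#'   `report` (three-row tibble: stage, n_in, n_removed, n_out,
#'   pct_removed, removed).
#' @export
run_filtration <- function(cands, real_profiles, net,
                           lactate_exchange_id = "EX_lac",
                           glucose_exchange_id = "EX_glc",
                           zero_tol = 1e-6,
                           marker_reaction_ids = "GNG",
                           flux_tol = 1e-6) {
  env <- build_envelope(real_profiles, net)
  s1 <- filter_energy(cands, env, net)
  s2 <- filter_gdi(s1$survivors, lactate_exchange_id,
                   glucose_exchange_id, zero_tol)
  s3 <- filter_gluconeogenesis(s2$survivors, marker_reaction_ids, net,
                               flux_tol)
  list(
    survivors = s3$survivors,
    report = dplyr::bind_rows(s1$report, s2$report, s3$report)
  )
}
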