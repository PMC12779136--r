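# Whole-study orchestration: preprocessing, GAN augmentation,
# per-sample contextualization, filtration, balancing, classification
# and multi-level importance, driven by one configuration and one
# master seed.

stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483646 + 1)
}

#' Pipeline configuration
#'
#' Bundles every stage's settings. Defaults reproduce the study design
#' at toy scale: augment the minority class to parity with 251 candidate
#' synthetic profiles, discretize at 0.3 SD, extract iMAT models at
#' epsilon = 1, filter on the ATP/NADH/NADPH envelope, zero GDI and
#' gluconeogenesis silence, classify with a 1000-tree balanced forest,
#' and aggregate importances to pathways and tiered gene families.
#'
#' @param expression An [expr_matrix()] or path to an expression TSV.
#' @param labels Path to a labels TSV (when `expression` is a path).
#' @param network A `metabolic_network` or model file path.
#' @param minority_class,majority_class Class labels (defaults
#'   `"healthy"` / `"cancer"`).
#' @param gan A [gan_config()]; its seed is derived from `seed`.
#' @param n_synthetic Candidate synthetic profiles to draw (default 251,
#'   the study's count).
#' @param sd_multiplier,epsilon,activity_tol,mip_gap Contextualization
#'   settings (see [discretize()], [imat_extract()]).
#' @param lactate_exchange_id,glucose_exchange_id,gdi_zero_tol GDI
#'   filter settings.
#' @param gng_marker_ids Gluconeogenesis marker reaction ids.
#' @param rf An [rf_config()]; its seed is derived from `seed`.
#' @param sigmoid_k,sigmoid_n0,family_map,top_k_genes Importance
#'   settings (see [gene_importance()], [tier_genes()]).
#' @param positive_class Class coded 1 in correlations; defaults to
#'   `majority_class`.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param outdir Output directory for report files (`NULL` = no files).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, network, labels = NULL,
                            minority_class = "healthy",
                            majority_class = "cancer",
                            gan = gan_config(), n_synthetic = 251,
                            sd_multiplier = 0.3, epsilon = 1,
                            activity_tol = 1e-6, mip_gap = 1e-6,
                            lactate_exchange_id = "EX_lac",
                            glucose_exchange_id = "EX_glc",
                            gdi_zero_tol = 1e-6,
                            gng_marker_ids = "GNG",
                            rf = rf_config(),
                            sigmoid_k = 1, sigmoid_n0 = NULL,
                            family_map = NULL, top_k_genes = 15,
                            positive_class = majority_class,
                            seed = 1L, outdir = NULL) {
  if (n_synthetic < 1) {
    stop("n_synthetic must be >= 1", call. = FALSE)
  }
  structure(
    list(expression = expression, labels = labels, network = network,
         minority_class = minority_class,
         majority_class = majority_class,
         gan = gan, n_synthetic = n_synthetic,
         sd_multiplier = sd_multiplier, epsilon = epsilon,
         activity_tol = activity_tol, mip_gap = mip_gap,
         lactate_exchange_id = lactate_exchange_id,
         glucose_exchange_id = glucose_exchange_id,
         gdi_zero_tol = gdi_zero_tol,
         gng_marker_ids = gng_marker_ids, rf = rf,
         sigmoid_k = sigmoid_k, sigmoid_n0 = sigmoid_n0,
         family_map = family_map, top_k_genes = top_k_genes,
         positive_class = positive_class,
         seed = seed, outdir = outdir),
    class = "pipeline_config"
  )
}

#' Class-balance report and qualified-sample selection
#'
#' Reports the minority/majority balance after augmentation and selects
#' the synthetic samples used downstream: when more qualified samples
#' exist than needed, a seeded subsample brings the minority total to
#' exactly the majority count; when too few exist, all are used and the
#' run proceeds unbalanced with a warning.
#'
#' @param real_minority_ids,qualified_ids,majority_ids Sample id
#'   vectors.
#' @param seed Seed for the subsample.
#' @return List with `counts` (tibble: n_real_minority, n_qualified,
#'   n_majority, n_selected, balanced), and `selected` (qualified ids
#'   retained).
#' @export
balance_report <- function(real_minority_ids, qualified_ids,
                           majority_ids, seed = 1L) {
  n_real <- length(real_minority_ids)
  n_q <- length(qualified_ids)
  n_maj <- length(majority_ids)
  need <- n_maj - n_real
  if (n_q > need && need >= 0) {
    set.seed(seed)
    selected <- sort(sample(qualified_ids, need))
  } else {
    selected <- qualified_ids
  }
  balanced <- n_real + length(selected) >= n_maj
  if (!balanced) {
    warning(sprintf(
      "insufficient qualified synthetic samples (%d real + %d qualified < %d majority); proceeding unbalanced",
      n_real, n_q, n_maj), call. = FALSE)
  }
  list(
    counts = tibble::tibble(
      n_real_minority = n_real, n_qualified = n_q, n_majority = n_maj,
      n_selected = length(selected), balanced = balanced
    ),
    selected = selected
  )
}

contextualize_all <- function(m, net, sample_ids, cfg, stage) {
  out <- vector("list", length(sample_ids))
  names(out) <- sample_ids
  for (i in seq_along(sample_ids)) {
    out[[i]] <- contextualize_sample(
      m, net, sample_ids[i],
      sd_multiplier = cfg$sd_multiplier, epsilon = cfg$epsilon,
      activity_tol = cfg$activity_tol, mip_gap = cfg$mip_gap
    )
  }
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order: zero-gene preprocessing; WGAN-GP training on the
#' real minority class and candidate generation (skipped when the
#' classes are already balanced); iMAT contextualization + FBA for every
#' real and synthetic sample; reference envelope from the real minority
#' profiles; three-stage filtration of the synthetic candidates; class
#' balancing; flux feature assembly and imputation; random-forest
#' training and evaluation; multi-level importance analysis. Every
#' stage's seed derives deterministically from the master seed, so a
#' given configuration reproduces byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress per-stage log messages.
#' @return A `pipeline_result`: list with the expression matrix, GAN
#'   fit, per-sample models, filtration report, balance report, feature
#'   matrix, `flux_rf` fit, `importance_ledger`, and (when `outdir` is
#'   set) the written file paths.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  net <- if (inherits(cfg$network, "metabolic_network")) {
    cfg$network
  } else {
    read_metabolic_model(cfg$network)
  }
  m <- if (inherits(cfg$expression, "expr_matrix")) {
    cfg$expression
  } else {
    read_expression_matrix(cfg$expression, cfg$labels)
  }

  m <- filter_zero_genes(m)
  say("preprocess: %d genes x %d samples", nrow(m$values), ncol(m$values))

  min_ids <- m$samples$sample_id[m$samples$label == cfg$minority_class]
  maj_ids <- m$samples$sample_id[m$samples$label == cfg$majority_class]
  if (length(min_ids) == 0 || length(maj_ids) == 0) {
    stop("both classes must be present", call. = FALSE)
  }

  gan_fit <- NULL
  synth <- NULL
  if (length(min_ids) < length(maj_ids)) {
    gcfg <- cfg$gan
    gcfg$seed <- stage_seed(cfg$seed, "gan_train")
    gan_fit <- train_wgan_gp(subset_samples(m, min_ids), gcfg)
    synth <- sample_synthetic(gan_fit, cfg$n_synthetic,
                              seed = stage_seed(cfg$seed, "gan_sample"))
    say("gan: trained on %d minority samples, generated %d candidates",
        length(min_ids), cfg$n_synthetic)
  } else {
    say("gan: classes balanced (%d vs %d), augmentation skipped",
        length(min_ids), length(maj_ids))
  }

  real_models <- contextualize_all(m, net, m$samples$sample_id, cfg)
  say("contextualize: %d real samples", length(real_models))

  filt <- NULL
  selected_syn <- character(0)
  syn_models <- list()
  if (!is.null(synth)) {
    syn_models <- contextualize_all(synth, net, synth$samples$sample_id,
                                    cfg)
    say("contextualize: %d synthetic candidates", length(syn_models))
    real_min_profiles <- lapply(real_models[min_ids], `[[`, "profile")
    syn_profiles <- lapply(syn_models, `[[`, "profile")
    filt <- run_filtration(
      syn_profiles, real_min_profiles, net,
      lactate_exchange_id = cfg$lactate_exchange_id,
      glucose_exchange_id = cfg$glucose_exchange_id,
      zero_tol = cfg$gdi_zero_tol,
      marker_reaction_ids = cfg$gng_marker_ids
    )
    qualified <- vapply(filt$survivors, `[[`, character(1), "sample_id")
    say("filtration: %d -> %d qualified candidates",
        cfg$n_synthetic, length(qualified))
    bal <- balance_report(min_ids, qualified, maj_ids,
                          seed = stage_seed(cfg$seed, "balance"))
    selected_syn <- bal$selected
    say("balance: %d real + %d synthetic minority vs %d majority",
        length(min_ids), length(selected_syn), length(maj_ids))
  } else {
    bal <- balance_report(min_ids, character(0), maj_ids,
                          seed = stage_seed(cfg$seed, "balance"))
  }

  models <- c(real_models, syn_models[selected_syn])
  labels <- c(
    stats::setNames(m$samples$label, m$samples$sample_id),
    stats::setNames(rep(cfg$minority_class, length(selected_syn)),
                    selected_syn)
  )
  origin <- c(
    stats::setNames(m$samples$origin, m$samples$sample_id),
    stats::setNames(rep("synthetic", length(selected_syn)), selected_syn)
  )
  fm <- assemble_features(models, labels, origin)
  fm <- impute_missing(fm, cfg$rf$missing_strategy)
  say("features: %d samples x %d reactions", nrow(fm$values),
      ncol(fm$values))

  rcfg <- cfg$rf
  rcfg$seed <- stage_seed(cfg$seed, "rf")
  fit <- train_rf(fm, rcfg)
  say("rf: test accuracy %.4f, OOB %.4f", fit$report$accuracy,
      fit$report$oob_score)

  ledger <- importance_ledger(
    fit, fm, net, positive_class = cfg$positive_class,
    sigmoid_k = cfg$sigmoid_k, sigmoid_n0 = cfg$sigmoid_n0,
    family_map = cfg$family_map, top_k_genes = cfg$top_k_genes
  )

  result <- structure(
    list(
      expression = m, gan_fit = gan_fit, synthetic = synth,
      models = models, filtration = filt, balance = bal,
      features = fm, rf_fit = fit, ledger = ledger,
      config = cfg, files = NULL
    ),
    class = "pipeline_result"
  )
  if (!is.null(cfg$outdir)) {
    result$files <- write_pipeline_reports(result, cfg$outdir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$balance$counts)
  print(x$rf_fit)
  invisible(x)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  keep <- !vapply(df, is.list, logical(1))
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

#' Write the pipeline report bundle
#'
#' Emits the run manifest (JSON), filtration report (TSV), classifier
#' report (JSON), reaction / pathway / gene-family importance tables
#' (TSV) and the reaction-cluster tree (Newick).
#'
#' @param result A `pipeline_result`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_pipeline_reports <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  paths <- c(
    manifest = file.path(outdir, "manifest.json"),
    filter = file.path(outdir, "filter_report.tsv"),
    classifier = file.path(outdir, "classifier_report.json"),
    reactions = file.path(outdir, "importance_reactions.tsv"),
    pathways = file.path(outdir, "importance_pathways.tsv"),
    families = file.path(outdir, "importance_families.tsv"),
    tree = file.path(outdir, "reaction_tree.nwk")
  )
  if (!is.null(result$filtration)) {
    write_tsv_plain(result$filtration$report, paths[["filter"]])
  } else {
    write_tsv_plain(
      tibble::tibble(stage = character(0), n_in = integer(0),
                     n_removed = integer(0), n_out = integer(0),
                     pct_removed = numeric(0)),
      paths[["filter"]]
    )
  }
  rep <- result$rf_fit$report
  jsonlite::write_json(
    list(
      accuracy = rep$accuracy,
      per_class = rep$per_class,
      confusion = as.data.frame(rep$confusion),
      cv_scores = rep$cv_scores,
      cv_mean = rep$cv_mean,
      cv_sd = rep$cv_sd,
      oob_score = rep$oob_score,
      misclassified = rep$misclassified
    ),
    paths[["classifier"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  write_tsv_plain(result$ledger$reactions, paths[["reactions"]])
  write_tsv_plain(result$ledger$pathways, paths[["pathways"]])
  write_tsv_plain(result$ledger$families, paths[["families"]])
  cl <- cluster_reactions(result$features, result$ledger$reactions,
                          if (inherits(cfg$network, "metabolic_network")) {
                            cfg$network
                          } else {
                            read_metabolic_model(cfg$network)
                          })
  writeLines(cl$newick, paths[["tree"]])
  manifest <- list(
    seed = cfg$seed,
    stage_seeds = list(
      gan_train = stage_seed(cfg$seed, "gan_train"),
      gan_sample = stage_seed(cfg$seed, "gan_sample"),
      balance = stage_seed(cfg$seed, "balance"),
      rf = stage_seed(cfg$seed, "rf")
    ),
    counts = as.list(result$balance$counts),
    accuracy = rep$accuracy,
    files = lapply(paths[-1], function(p) {
      list(name = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE)
  paths
}
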