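# Two-phenotype expression simulator with planted differential gene sets.
#
# The simulator targets the statistical structure the pipeline assumes of
# FPKM-like data — non-negative, right-skewed values; class-dependent
# mean shifts on known genes; independent log-scale noise — without
# attempting to mimic real covariance structure. Decoy genes outside all
# GPR rules are included so that preprocessing and the GAN see
# uninformative features, as real matrices have.

#' Phenotype simulation specification
#'
#' @param n_healthy,n_cancer Sample counts per class (>= 1). The default
#'   40/40 is the balanced study cohort; use e.g. 40/4 to mirror a
#'   heavily imbalanced design.
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of per-gene
#'   baseline expression on the log2 scale (defaults 5 and 0.5 —
#'   typical FPKM around 32 with a roughly one-decade spread, as in a
#'   matrix already reduced to expressed metabolic genes).
#' @param planted_up_genes,planted_down_genes Disjoint gene sets shifted
#'   up / down in the cancer class. Defaults plant up-regulated
#'   fatty-acid transporter genes and down-regulated lysosomal
#'   degradation genes, the toy network's signal-bearing branches.
#' @param effect_size Log2-units class shift for planted genes
#'   (default 2).
#' @param noise_sd Log2-units independent noise SD (default 0.5).
#' @param housekeeping_high_genes Genes pinned modestly above the median
#'   baseline (default: the lumped glycolysis and TCA subunits GAPDH,
#'   PKM, CS, SDHA) — constitutive core catabolism, so reference models
#'   have a functioning energy metabolism.
#' @param housekeeping_low_genes Genes pinned below the median baseline
#'   (default: fermentation and gluconeogenesis genes LDHA, LDHB,
#'   SLC16A1, PCK1, FBP1) — programs inactive in well-nourished aerobic
#'   tissue, so healthy reference models secrete no lactate and run no
#'   gluconeogenesis, giving the biological filters their intended
#'   semantics.
#' @param n_decoys Number of decoy genes outside all GPRs (default 40).
#' @param seed RNG seed.
#' @return List of class `phenotype_spec`.
#' @export
phenotype_spec <- function(n_healthy = 40, n_cancer = 40,
                           baseline_log2_mean = 5, baseline_log2_sd = 0.5,
                           planted_up_genes = c("FABP1", "FABP4",
                                                "SLC27A1", "ACSL1",
                                                "ACSBG1"),
                           planted_down_genes = c("SGSH", "NAGLU",
                                                  "GUSB"),
                           effect_size = 2, noise_sd = 0.5,
                           housekeeping_high_genes = c("GAPDH", "PKM",
                                                       "CS", "SDHA"),
                           housekeeping_low_genes = c("LDHA", "LDHB",
                                                      "SLC16A1", "PCK1",
                                                      "FBP1"),
                           n_decoys = 40, seed = 1L) {
  stopifnot(n_healthy >= 1, n_cancer >= 1, effect_size >= 0,
            noise_sd >= 0, baseline_log2_sd >= 0, n_decoys >= 0)
  if (length(intersect(planted_up_genes, planted_down_genes)) > 0) {
    stop("planted up and down gene sets must be disjoint", call. = FALSE)
  }
  structure(
    list(n_healthy = n_healthy, n_cancer = n_cancer,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         planted_up_genes = planted_up_genes,
         planted_down_genes = planted_down_genes,
         effect_size = effect_size, noise_sd = noise_sd,
         housekeeping_high_genes = housekeeping_high_genes,
         housekeeping_low_genes = housekeeping_low_genes,
         n_decoys = n_decoys, seed = seed),
    class = "phenotype_spec"
  )
}

#' Simulate a phenotype-labelled expression matrix
#'
#' Gene universe = genes appearing in the network's GPR rules plus
#' `n_decoys` decoy genes. Each gene gets a log2 baseline drawn once;
#' expression is `2^(baseline + shift + noise)` where `shift` is
#' `+effect_size` for planted-up genes in cancer samples,
#' `-effect_size` for planted-down genes in cancer samples, and 0
#' otherwise. Values are clipped at zero (a no-op for the log-normal
#' model, kept as an explicit contract). Reproducible from `spec$seed`.
#'
#' Planted genes get deterministic baselines instead of random draws:
#' up-regulated genes straddle the population median symmetrically,
#' half an effect below `baseline_log2_mean` in the healthy state and
#' half an effect above it in cancer (a gained program); down-regulated
#' genes sit at the median in health — an expressed but unexceptional
#' program — and fall a full effect below it in cancer (a lost
#' function). The class contrast therefore
#' acts across the mean +/- 0.3 SD discretization band instead of being
#' buried under a gene's random baseline, which is how a real
#' differential program behaves relative to its own healthy level.
#'
#' @param net A `metabolic_network` whose GPR genes form the informative
#'   part of the universe.
#' @param spec A [phenotype_spec()].
#' @return An [expr_matrix()] with labels `healthy` / `cancer` and
#'   origin `real`.
#' @export
simulate_expression <- function(net, spec = phenotype_spec()) {
  stopifnot(inherits(net, "metabolic_network"),
            inherits(spec, "phenotype_spec"))
  genes <- network_genes(net)
  decoys <- if (spec$n_decoys > 0) {
    sprintf("DECOY%03d", seq_len(spec$n_decoys))
  } else {
    character(0)
  }
  universe <- c(genes, decoys)
  unknown <- setdiff(c(spec$planted_up_genes, spec$planted_down_genes),
                     universe)
  if (length(unknown) > 0) {
    stop("planted gene(s) not in the gene universe: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  n_g <- length(universe)
  n_s <- spec$n_healthy + spec$n_cancer
  baseline <- stats::rnorm(n_g, spec$baseline_log2_mean,
                           spec$baseline_log2_sd)
  baseline[universe %in% spec$housekeeping_high_genes] <-
    spec$baseline_log2_mean + 0.5
  baseline[universe %in% spec$housekeeping_low_genes] <-
    spec$baseline_log2_mean - 1
  baseline[universe %in% spec$planted_up_genes] <-
    spec$baseline_log2_mean - spec$effect_size / 2
  baseline[universe %in% spec$planted_down_genes] <-
    spec$baseline_log2_mean
  shift <- matrix(0, n_g, n_s)
  cancer_cols <- spec$n_healthy + seq_len(spec$n_cancer)
  shift[universe %in% spec$planted_up_genes, cancer_cols] <-
    spec$effect_size
  shift[universe %in% spec$planted_down_genes, cancer_cols] <-
    -spec$effect_size
  noise <- matrix(stats::rnorm(n_g * n_s, 0, spec$noise_sd), n_g, n_s)
  vals <- pmax(2^(baseline + shift + noise), 0)
  sids <- c(sprintf("H%03d", seq_len(spec$n_healthy)),
            sprintf("C%03d", seq_len(spec$n_cancer)))
  dimnames(vals) <- list(universe, sids)
  labels <- stats::setNames(
    c(rep("healthy", spec$n_healthy), rep("cancer", spec$n_cancer)),
    sids
  )
  expr_matrix(vals, labels)
}

#' Write a deterministic fixture bundle
#'
#' Emits the toy network (COBRA-style JSON), a simulated expression
#' matrix (TSV), sample labels (TSV), the simulation configuration
#' (YAML) and the gene universe (TSV) into `outdir`, plus a
#' `manifest.json` listing each file with its MD5 checksum. Identical
#' seeds give byte-identical bundles.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Seed driving the simulation.
#' @param spec Optional [phenotype_spec()]; its seed is overridden by
#'   `seed`.
#' @return The manifest as a list (invisibly writes all files).
#' @export
make_fixture_bundle <- function(outdir, seed = 1L, spec = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  net <- build_toy_network()
  if (is.null(spec)) spec <- phenotype_spec(seed = seed)
  spec$seed <- seed
  m <- simulate_expression(net, spec)

  paths <- c(
    network = file.path(outdir, "network.json"),
    expression = file.path(outdir, "expression.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    config = file.path(outdir, "config.yaml"),
    genes = file.path(outdir, "gene_universe.tsv")
  )
  write_metabolic_model(net, paths[["network"]])
  write_expression_matrix(m, paths[["expression"]], paths[["labels"]])
  cfg <- unclass(spec)
  yaml::write_yaml(cfg, paths[["config"]])
  utils::write.table(
    data.frame(gene_id = rownames(m$values),
               in_gpr = rownames(m$values) %in% network_genes(net)),
    paths[["genes"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  manifest <- list(
    seed = seed,
    files = lapply(names(paths), function(nm) {
      list(name = basename(paths[[nm]]), role = nm,
           md5 = unname(tools::md5sum(paths[[nm]])))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
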