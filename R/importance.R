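# Multi-level importance analysis: reaction-level impurity importances
# and rank correlations, pathway-level averaging, sigmoid-weighted gene
# and gene-family scores with quartile tiers, reaction clustering, and
# per-reaction flux activity summaries.

#' Impurity-based reaction importances
#'
#' Mean-decrease-in-Gini importance per flux feature from a fitted
#' forest, normalized to sum to 1.
#'
#' @param fit A `flux_rf` from [train_rf()].
#' @return Tibble `reaction_id`, `importance` (sums to 1), sorted
#'   decreasing.
#' @export
reaction_importance <- function(fit) {
  stopifnot(inherits(fit, "flux_rf"))
  imp <- ranger::importance(fit$forest)
  total <- sum(imp)
  if (total <= 0) imp[] <- 1 / length(imp) else imp <- imp / total
  tibble::tibble(
    reaction_id = fit$feature_ids,
    importance = unname(imp)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Spearman correlation of each flux feature with the class label
#'
#' Rank correlation (average ranks for ties) between each imputed flux
#' column and the binary phenotype coded 0 (reference class) / 1
#' (positive class). Constant columns get rho = 0 and are flagged.
#'
#' @param fm An imputed `feature_matrix`.
#' @param positive_class Label coded as 1 (e.g. `"cancer"`).
#' @return Tibble `reaction_id`, `rho`, `constant`.
#' @export
spearman_vs_state <- function(fm, positive_class) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- fm$values
  if (anyNA(vals)) {
    stop("feature matrix contains missing values; impute first",
         call. = FALSE)
  }
  ycode <- as.numeric(fm$samples$label == positive_class)
  rho <- apply(vals, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(ycode) == 0) return(NA_real_)
    stats::cor(col, ycode, method = "spearman")
  })
  flag <- unname(is.na(rho))
  tibble::tibble(
    reaction_id = colnames(vals),
    rho = ifelse(flag, 0, unname(rho)),
    constant = flag
  )
}

#' Pathway-level importance by within-pathway averaging
#'
#' The importance of a pathway (reaction subsystem) is the mean
#' importance of its member reactions present in the feature union;
#' shares normalize the means to percentages. Reactions without a
#' subsystem annotation are pooled under "Unassigned". Two
#' normalizations are reported: over all pathways (`share_pct`) and over
#' the top 15 pathways by mean (`share_pct_top15`).
#'
#' @param rimp Reaction importance tibble from [reaction_importance()].
#' @param net The parent `metabolic_network`.
#' @return Tibble `pathway`, `n_reactions`, `mean_importance`,
#'   `share_pct`, `share_pct_top15`, sorted by share.
#' @export
pathway_importance <- function(rimp, net) {
  subs <- stats::setNames(net$reactions$subsystem, net$reactions$id)
  out <- rimp |>
    dplyr::mutate(
      pathway = dplyr::coalesce(subs[.data$reaction_id], "Unassigned")
    ) |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_reactions = dplyr::n(),
      mean_importance = mean(.data$importance),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      share_pct = 100 * .data$mean_importance / sum(.data$mean_importance)
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_importance))
  topn <- utils::head(out$mean_importance, 15)
  out$share_pct_top15 <- ifelse(
    seq_len(nrow(out)) <= 15,
    100 * out$mean_importance / sum(topn),
    NA_real_
  )
  out
}

#' Sigmoid-weighted gene and gene-family importance
#'
#' A gene's raw score is the summed importance of every reaction whose
#' GPR mentions it. Genes catalyzing many reactions get extra weight
#' through a logistic ramp while genes with few reactions keep at least
#' half weight: `weight = 0.5 + 0.5 * plogis(k * (n - n0))`, where `n`
#' is the gene's reaction count, so `weight` is in (0.5, 1) and equals
#' exactly 0.75 at `n = n0`. Family scores aggregate member genes
#' (sum by default, mean optionally).
#'
#' @param rimp Reaction importance tibble.
#' @param net The parent `metabolic_network`.
#' @param sigmoid_k Logistic steepness (default 1).
#' @param sigmoid_n0 Logistic midpoint; defaults to the median reaction
#'   count over genes.
#' @param family_map Named character vector gene -> family (default:
#'   each gene is its own family).
#' @param rollup `"sum"` (default) or `"mean"` over member genes.
#' @return List with `genes` (gene, n_reactions, raw, weight, score) and
#'   `families` (family, score), both sorted decreasing.
#' @export
gene_importance <- function(rimp, net, sigmoid_k = 1, sigmoid_n0 = NULL,
                            family_map = NULL, rollup = c("sum", "mean")) {
  rollup <- match.arg(rollup)
  stopifnot(sigmoid_k > 0)
  imp <- stats::setNames(rimp$importance, rimp$reaction_id)
  gene_rxns <- list()
  for (k in seq_len(nrow(net$reactions))) {
    for (g in gpr_genes(net$reactions$gpr[[k]])) {
      gene_rxns[[g]] <- c(gene_rxns[[g]], net$reactions$id[k])
    }
  }
  if (length(gene_rxns) == 0L) {
    stop("network has no GPR-annotated reactions", call. = FALSE)
  }
  n_rxn <- vapply(gene_rxns, length, integer(1))
  if (is.null(sigmoid_n0)) sigmoid_n0 <- stats::median(n_rxn)
  raw <- vapply(gene_rxns, function(rids) {
    sum(imp[intersect(rids, names(imp))])
  }, numeric(1))
  weight <- 0.5 + 0.5 * stats::plogis(sigmoid_k * (n_rxn - sigmoid_n0))
  genes <- tibble::tibble(
    gene = names(gene_rxns),
    n_reactions = unname(n_rxn),
    raw = unname(raw),
    weight = unname(weight),
    score = unname(raw * weight)
  ) |>
    dplyr::arrange(dplyr::desc(.data$score))

  if (is.null(family_map)) {
    family_map <- stats::setNames(genes$gene, genes$gene)
  }
  extra <- setdiff(names(family_map), genes$gene)
  if (length(extra) > 0) {
    warning("family map gene(s) absent from all GPRs (score 0): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  fam <- genes |>
    dplyr::mutate(
      family = dplyr::coalesce(family_map[.data$gene], .data$gene)
    ) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      score = if (rollup == "sum") sum(.data$score) else mean(.data$score),
      n_genes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$score))
  list(genes = genes, families = fam)
}

#' Quartile tiers over the top-scoring families
#'
#' Takes the `top_k` families by score, computes the quartiles of those
#' scores (type-7 linear interpolation), and assigns tiers: Very High
#' for scores >= Q3, High >= Q2, Medium >= Q1, Low otherwise. Ties on a
#' boundary take the higher tier.
#'
#' @param scores Tibble with columns `family` and `score` (e.g.
#'   `gene_importance()$families`).
#' @param top_k Number of families to tier (default 15).
#' @return Tibble `family`, `score`, `tier` (ordered factor), top_k rows.
#' @export
tier_genes <- function(scores, top_k = 15) {
  if (nrow(scores) < 4L) {
    stop("need at least 4 scored families to form quartile tiers",
         call. = FALSE)
  }
  top_k <- min(top_k, nrow(scores))
  top <- scores |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    utils::head(top_k)
  q <- stats::quantile(top$score, c(0.25, 0.5, 0.75), type = 7)
  tier <- ifelse(top$score >= q[3], "Very High",
                 ifelse(top$score >= q[2], "High",
                        ifelse(top$score >= q[1], "Medium", "Low")))
  top$tier <- factor(tier, levels = c("Low", "Medium", "High", "Very High"),
                     ordered = TRUE)
  top
}

#' Cluster top reactions by flux-correlation distance
#'
#' Agglomerative (average-linkage) clustering of the `top_n` reactions
#' by importance, using distance `1 - |Spearman rho|` between their
#' imputed flux columns. The tree is returned as an `hclust`, an `ape`
#' phylo, and a Newick string with reaction ids as leaf labels; the
#' `annotations` tibble carries each leaf's subsystem.
#'
#' @param fm Imputed `feature_matrix`.
#' @param rimp Reaction importance tibble.
#' @param net Parent network (for subsystem annotations).
#' @param top_n Number of reactions to cluster (default 70, capped at
#'   the feature count).
#' @return List with `hclust`, `phylo`, `newick`, `annotations`.
#' @export
cluster_reactions <- function(fm, rimp, net, top_n = 70) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (anyNA(fm$values)) {
    stop("feature matrix contains missing values; impute first",
         call. = FALSE)
  }
  top_n <- min(top_n, nrow(rimp))
  if (top_n < 2L) stop("need at least 2 reactions to cluster", call. = FALSE)
  ids <- utils::head(rimp$reaction_id, top_n)
  vals <- fm$values[, ids, drop = FALSE]
  cmat <- suppressWarnings(stats::cor(vals, method = "spearman"))
  cmat[is.na(cmat)] <- 0
  diag(cmat) <- 1
  d <- stats::as.dist(1 - abs(cmat))
  hc <- stats::hclust(d, method = "average")
  ph <- ape::as.phylo(hc)
  subs <- stats::setNames(net$reactions$subsystem, net$reactions$id)
  list(
    hclust = hc,
    phylo = ph,
    newick = ape::write.tree(ph),
    annotations = tibble::tibble(
      reaction_id = ids,
      subsystem = dplyr::coalesce(subs[ids], "Unassigned")
    )
  )
}

#' Rolling flux and activity-ratio series for one reaction
#'
#' For each class, samples are taken in stable input order; the flux is
#' smoothed with a trailing rolling mean of width `window` (windows
#' truncated at the start), and the activity ratio is the fraction of
#' samples in the window with `|flux| > activity_tol` — 0 means the
#' reaction is silent across the window, 1 active in every sample.
#'
#' @param fm Imputed `feature_matrix`.
#' @param reaction_id Reaction to summarize.
#' @param window Rolling window width (default 10).
#' @param activity_tol Flux magnitude counted as active (default 1e-6).
#' @return Tibble `label`, `position`, `sample_id`, `flux`,
#'   `rolling_mean`, `activity_ratio`.
#' @export
flux_activity_summary <- function(fm, reaction_id, window = 10,
                                  activity_tol = 1e-6) {
  stopifnot(inherits(fm, "feature_matrix"), window >= 1)
  if (!reaction_id %in% colnames(fm$values)) {
    stop("unknown reaction: ", reaction_id, call. = FALSE)
  }
  col <- fm$values[, reaction_id]
  if (anyNA(col)) {
    stop("feature matrix contains missing values; impute first",
         call. = FALSE)
  }
  roll <- function(x, f) {
    vapply(seq_along(x), function(i) {
      w <- x[max(1L, i - window + 1L):i]
      f(w)
    }, numeric(1))
  }
  fm$samples |>
    dplyr::mutate(flux = unname(col)) |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::mutate(
      rolling_mean = roll(.data$flux, mean),
      activity_ratio = roll(.data$flux,
                            function(w) mean(abs(w) > activity_tol))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("label", "position", "sample_id", "flux",
                  "rolling_mean", "activity_ratio")
}

#' Build the full multi-level importance ledger
#'
#' Combines reaction importances, Spearman correlations, pathway shares
#' and tiered gene-family scores into one object — the analysis result
#' consumed by the reporting and plotting helpers.
#'
#' @param fit A `flux_rf`.
#' @param fm The imputed `feature_matrix` it was trained on.
#' @param net Parent `metabolic_network`.
#' @param positive_class Label coded 1 for correlations (e.g.
#'   `"cancer"`).
#' @param sigmoid_k,sigmoid_n0,family_map,rollup Passed to
#'   [gene_importance()].
#' @param top_k_genes Families to tier (default 15).
#' @return An `importance_ledger`: list of tibbles `reactions`
#'   (reaction_id, importance, rho, subsystem), `pathways`, `genes`,
#'   `families` (tiered).
#' @export
importance_ledger <- function(fit, fm, net, positive_class,
                              sigmoid_k = 1, sigmoid_n0 = NULL,
                              family_map = NULL,
                              rollup = c("sum", "mean"),
                              top_k_genes = 15) {
  rimp <- reaction_importance(fit)
  rho <- spearman_vs_state(fm, positive_class)
  subs <- stats::setNames(net$reactions$subsystem, net$reactions$id)
  reactions <- rimp |>
    dplyr::left_join(rho, by = "reaction_id") |>
    dplyr::mutate(
      subsystem = dplyr::coalesce(subs[.data$reaction_id], "Unassigned")
    )
  gi <- gene_importance(rimp, net, sigmoid_k, sigmoid_n0, family_map,
                        rollup)
  structure(
    list(
      reactions = reactions,
      pathways = pathway_importance(rimp, net),
      genes = gi$genes,
      families = tier_genes(gi$families, top_k_genes)
    ),
    class = "importance_ledger"
  )
}

#' @export
print.importance_ledger <- function(x, ...) {
  cat("<importance_ledger>\n top reactions:\n")
  print(utils::head(x$reactions, 5))
  cat(" top pathways:\n")
  print(utils::head(x$pathways, 5))
  cat(" tiered families:\n")
  print(x$families)
  invisible(x)
}

#' Reaction-level table of an importance ledger
#'
#' @param x An `importance_ledger`.
#' @param ... Unused.
#' @export
tidy.importance_ledger <- function(x, ...) x$reactions
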