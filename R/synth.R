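## Synthetic-data generators with planted ground truth: a perturbation
## compendium (responsive genes carry |z| near a planted effect with
## pathway-consistent per-gene direction; inhibition experiments are
## sign-flipped so the adjustment step must undo them) and a drug-response
## cohort (resistant lines draw AUC in [0.8, 1], sensitive in [0.4, 0.8);
## the dysregulated pathway's responsive genes get a direction-matched mean
## shift in resistant lines).

#' Simulate a perturbation-experiment compendium
#'
#' Per experiment, background genes draw z ~ Normal(0, noise_sd); each
#' pathway's planted responsive genes draw z = sign_g * (effect +
#' Normal(0, 0.25 * noise_sd)), where sign_g is the gene's fixed per-pathway
#' direction, and the whole planted signal is negated in inhibition-type
#' experiments (undone later by \code{\link{adjust_z}}).
#'
#' @param n_pathways Number of pathways; default 5.
#' @param n_experiments_per_pathway Experiments per pathway (>= 2); default 5.
#' @param n_genes Gene universe size; default 2000.
#' @param n_responsive Planted responsive genes per pathway
#'   (< n_genes); default 50.
#' @param effect Planted |z| effect (>= 0; 0 gives a null compendium);
#'   default 4.
#' @param noise_sd Background standard deviation; default 1.
#' @param inhibition_fraction Fraction of experiments that are
#'   inhibition-type; default 0.5.
#' @param seed Integer seed.
#' @return List with \code{psets} (named list of
#'   \code{pathway_experiment_set}) and \code{truth} (list with
#'   \code{responsive_genes}: per pathway a named sign vector over the planted
#'   genes; \code{genes}: the universe; \code{effect}; \code{seed}).
#' @export
simulate_perturbation_experiments <- function(n_pathways = 5L,
                                              n_experiments_per_pathway = 5L,
                                              n_genes = 2000L,
                                              n_responsive = 50L,
                                              effect = 4,
                                              noise_sd = 1,
                                              inhibition_fraction = 0.5,
                                              seed = 1L) {
  if (n_responsive >= n_genes) stop("n_responsive must be < n_genes")
  if (effect < 0) stop("effect must be >= 0")  # 0 = null construction
  if (n_experiments_per_pathway < 2L) stop("need >= 2 experiments per pathway")
  if (inhibition_fraction < 0 || inhibition_fraction > 1)
    stop("inhibition_fraction must lie in [0, 1]")
  genes <- sprintf("g%05d", seq_len(n_genes))
  pathways <- sprintf("PATH%02d", seq_len(n_pathways))
  with_seed(seed, {
    truth_sets <- list()
    psets <- list()
    n_inh <- round(inhibition_fraction * n_experiments_per_pathway)
    for (p in pathways) {
      planted <- sample(genes, n_responsive)
      sgn <- setNames(sample(c(-1, 1), n_responsive, replace = TRUE), planted)
      truth_sets[[p]] <- sgn
      ptypes <- sample(rep(c("inhibition", "activation"),
                           c(n_inh, n_experiments_per_pathway - n_inh)))
      exps <- lapply(seq_len(n_experiments_per_pathway), function(i) {
        z <- rnorm(n_genes, 0, noise_sd)
        names(z) <- genes
        flip <- if (ptypes[i] == "inhibition") -1 else 1
        z[planted] <- flip * sgn * (effect + rnorm(n_responsive, 0, 0.25 * noise_sd))
        perturbation_experiment(p, ptypes[i],
                                sprintf("SYN_%s_E%02d", p, i),
                                gene = genes, z = unname(z))
      })
      psets[[p]] <- pathway_experiment_set(p, exps)
    }
    list(psets = psets,
         truth = list(responsive_genes = truth_sets, genes = genes,
                      effect = effect, seed = seed))
  })
}

#' Simulate a drug-response cohort with one dysregulated pathway
#'
#' Cell lines are labelled resistant with probability-free deterministic
#' counts (\code{round(resistant_fraction * n_cell_lines)}); resistant lines
#' draw AUC ~ Uniform(0.8, 1), sensitive ~ Uniform(0.4, 0.8). Expression is
#' Normal(0, 1) baseline; in resistant lines, \code{shift} is added to the
#' dysregulated pathway's planted responsive genes, sign-matched to each
#' gene's planted direction.
#'
#' @param n_cell_lines Number of cell lines; default 16 (8 vs 8 at the
#'   default resistant fraction).
#' @param prgs_truth \code{truth} component of
#'   \code{\link{simulate_perturbation_experiments}}.
#' @param dysregulated_pathway Pathway label present in the truth.
#' @param shift Mean shift (in expression SD units, >= 0); default 2.
#' @param resistant_fraction Fraction of resistant lines; default 0.5.
#' @param drug Drug name used in the AUC table; default "synthdrug".
#' @param seed Integer seed.
#' @return List with \code{expr} (genes x cell lines matrix), \code{auc}
#'   (long drug-response data.frame) and \code{truth} (adds
#'   \code{group_labels} and \code{dysregulated_pathways}).
#' @export
simulate_cohort <- function(n_cell_lines = 16L, prgs_truth,
                            dysregulated_pathway, shift = 2,
                            resistant_fraction = 0.5,
                            drug = "synthdrug", seed = 1L) {
  if (!dysregulated_pathway %in% names(prgs_truth$responsive_genes))
    stop("dysregulated_pathway not present in truth")
  if (shift < 0) stop("shift must be >= 0")
  if (resistant_fraction <= 0 || resistant_fraction >= 1)
    stop("resistant_fraction must lie in (0, 1)")
  genes <- prgs_truth$genes
  lines <- sprintf("CL%03d", seq_len(n_cell_lines))
  n_res <- round(resistant_fraction * n_cell_lines)
  if (n_res < 1L || n_res >= n_cell_lines)
    stop("resistant_fraction leaves an empty group")
  with_seed(seed, {
    resistant <- sort(sample(lines, n_res))
    labels <- setNames(ifelse(lines %in% resistant, "resistant", "sensitive"),
                       lines)
    auc <- ifelse(labels == "resistant",
                  runif(n_cell_lines, 0.8, 1.0),
                  runif(n_cell_lines, 0.4, 0.8))
    # keep sensitive AUC strictly below the 0.8 boundary
    auc[labels == "sensitive"] <- pmin(auc[labels == "sensitive"], 0.8 - 1e-9)
    expr <- matrix(rnorm(length(genes) * n_cell_lines), length(genes),
                   n_cell_lines, dimnames = list(genes, lines))
    sgn <- prgs_truth$responsive_genes[[dysregulated_pathway]]
    expr[names(sgn), labels == "resistant"] <-
      expr[names(sgn), labels == "resistant"] + shift * sgn
    list(expr = expr,
         auc = as_drug_response(data.frame(cell_line = lines, drug = drug,
                                           auc = auc)),
         truth = c(prgs_truth,
                   list(group_labels = labels,
                        dysregulated_pathways = setNames(
                          list(dysregulated_pathway), drug))))
  })
}

#' Set-recovery metrics against planted truth
#'
#' @param truth_set Character vector of planted identifiers.
#' @param predicted_set Character vector of predictions.
#' @return List with \code{recall}, \code{precision} (\code{NA} when the
#'   prediction is empty) and \code{n_overlap}.
#' @export
recovery_metrics <- function(truth_set, predicted_set) {
  truth_set <- unique(as.character(truth_set))
  predicted_set <- unique(as.character(predicted_set))
  if (length(truth_set) == 0L) stop("truth set must be nonempty")
  ov <- length(intersect(truth_set, predicted_set))
  list(recall = ov / length(truth_set),
       precision = if (length(predicted_set) == 0L) NA_real_
                   else ov / length(predicted_set),
       n_overlap = ov)
}

#' Rank of a pathway in a method's p-value ordering
#'
#' @param results \code{data.frame} from \code{\link{run_all_methods}}.
#' @param pathway Pathway label.
#' @param method One of \code{"gsea_like"}, \code{"hypergeom"},
#'   \code{"bates"}.
#' @return Integer rank (1 = smallest p-value; ties share the minimum rank).
#' @export
pathway_rank <- function(results, pathway, method) {
  sub <- results[results$method == method & !is.na(results$p_value), ]
  if (!pathway %in% sub$pathway)
    stop("pathway has no evaluable result for method ", method)
  p <- sub$p_value[match(pathway, sub$pathway)]
  sum(sub$p_value < p) + 1L
}
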