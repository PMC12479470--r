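## Pathway-responsive gene signature (PRGS) construction: per-experiment
## cleanup (duplicate collapse, median filter), perturbation-sign adjustment,
## per-experiment Gaussian transform, cross-experiment averaging, and the
## |z-score| > threshold discrete view.

#' Configuration for PRGS construction
#'
#' @param threshold Discrete-signature threshold on |z-score|; default 2.58,
#'   the two-sided standard-normal critical value at p = 0.01 rounded to two
#'   decimals.
#' @param min_datasets Minimum number of experiments a gene must survive in to
#'   be scored; default 2.
#' @param median_filter Drop, within each experiment, gene records whose |z|
#'   falls below the experiment's median |z|; default \code{TRUE}.
#' @param median_on \code{"abs_z"} (default) filters on |z|; \code{"z"} on the
#'   raw signed z (sensitivity analysis).
#' @param duplicate_rule How within-experiment duplicate gene records are
#'   resolved; only \code{"max_abs"} (keep the record with maximal |z|) is
#'   implemented.
#' @return List of class \code{"prgs_config"}.
#' @export
prgs_config <- function(threshold = 2.58, min_datasets = 2L,
                        median_filter = TRUE, median_on = c("abs_z", "z"),
                        duplicate_rule = "max_abs") {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be > 0")
  if (!is.numeric(min_datasets) || min_datasets < 1) stop("min_datasets must be >= 1")
  duplicate_rule <- match.arg(duplicate_rule)
  structure(list(threshold = threshold, min_datasets = as.integer(min_datasets),
                 median_filter = isTRUE(median_filter),
                 median_on = match.arg(median_on),
                 duplicate_rule = duplicate_rule),
            class = "prgs_config")
}

#' Sign-adjust raw z-values for the perturbation type
#'
#' Activation experiments keep z unchanged; inhibition experiments negate it,
#' so that a gene induced by pathway activity always carries a positive
#' adjusted z regardless of the direction the experiment pushed the pathway.
#'
#' @param z_raw Finite numeric vector of raw z-values.
#' @param ptype \code{"activation"} or \code{"inhibition"}.
#' @return Adjusted z-values (magnitudes preserved).
#' @export
adjust_z <- function(z_raw, ptype) {
  if (any(!is.finite(z_raw))) stop("z_raw must be finite")
  sgn <- switch(parse_ptype(ptype), activation = 1, inhibition = -1)
  sgn * z_raw
}

#' Drop gene records below the experiment's median magnitude
#'
#' Retains records whose |z| is at least the experiment-wide median of |z|
#' (or raw z, if configured), emulating the exclusion of genes expressed below
#' the median.
#'
#' @param experiment A \code{perturbation_experiment} with >= 2 records.
#' @param on \code{"abs_z"} (default) or \code{"z"}.
#' @return The filtered \code{perturbation_experiment}.
#' @export
filter_below_median <- function(experiment, on = c("abs_z", "z")) {
  stopifnot(inherits(experiment, "perturbation_experiment"))
  if (length(experiment$gene) < 2L)
    stop("experiment needs >= 2 gene records")
  stat <- switch(match.arg(on), abs_z = abs(experiment$z), z = experiment$z)
  keep <- stat >= median(stat)
  experiment$gene <- experiment$gene[keep]
  experiment$z <- experiment$z[keep]
  experiment
}

#' Collapse duplicate gene records within an experiment
#'
#' When a gene appears several times (probe-level duplicates), the record with
#' maximal |z| is kept; exact ties go to the first occurrence. Output keeps the
#' first-occurrence order of genes.
#'
#' @param experiment A \code{perturbation_experiment}.
#' @return Experiment with one record per gene.
#' @export
collapse_duplicates <- function(experiment) {
  stopifnot(inherits(experiment, "perturbation_experiment"))
  if (!anyDuplicated(experiment$gene)) return(experiment)
  o <- order(-abs(experiment$z))            # stable: ties keep input order
  sel <- o[!duplicated(experiment$gene[o])]
  sel <- sel[order(match(experiment$gene[sel], unique(experiment$gene)))]
  experiment$gene <- experiment$gene[sel]
  experiment$z <- experiment$z[sel]
  experiment
}

#' Aggregate per-gene z-scores across a pathway's experiments
#'
#' Per experiment the pipeline is: collapse duplicates, (optionally) filter
#' below-median records, sign-adjust for perturbation type, Gaussian-transform.
#' Per gene, the z-score is the arithmetic mean of its transformed values over
#' the experiments containing it; genes seen in fewer than
#' \code{cfg$min_datasets} experiments are dropped. Experiments with fewer than
#' two genes after filtering are skipped with a warning.
#'
#' @param pset A \code{pathway_experiment_set}.
#' @param cfg A \code{\link{prgs_config}}.
#' @return \code{data.frame} with columns \code{gene}, \code{zscore},
#'   \code{n_datasets}, ordered by gene identifier.
#' @export
pathway_gene_zscores <- function(pset, cfg = prgs_config()) {
  stopifnot(inherits(pset, "pathway_experiment_set"),
            inherits(cfg, "prgs_config"))
  genes <- character(0)
  vals <- numeric(0)
  for (e in pset$experiments) {
    e <- collapse_duplicates(e)
    if (cfg$median_filter && length(e$gene) >= 2L)
      e <- filter_below_median(e, on = cfg$median_on)
    if (length(e$gene) < 2L) {
      warning(sprintf("experiment %s skipped: fewer than 2 genes after filtering",
                      e$accession))
      next
    }
    zt <- gaussian_transform(adjust_z(e$z, e$ptype))
    genes <- c(genes, e$gene)
    vals <- c(vals, zt)
  }
  if (length(genes) == 0L)
    return(data.frame(gene = character(0), zscore = numeric(0),
                      n_datasets = integer(0)))
  zscore <- tapply(vals, genes, mean)
  n <- tapply(vals, genes, length)
  keep <- n >= cfg$min_datasets
  g <- sort(names(zscore)[keep])
  data.frame(gene = g, zscore = as.numeric(zscore[g]),
             n_datasets = as.integer(n[g]), row.names = NULL)
}

#' Build a pathway-responsive gene signature
#'
#' The continuous view is the full gene-to-z-score mapping from
#' \code{\link{pathway_gene_zscores}}; the discrete view is the set of genes
#' with |z-score| strictly above \code{cfg$threshold} (under a standard-normal
#' null, 2.58 corresponds to a two-sided p below 0.01).
#'
#' @param pset A \code{pathway_experiment_set}.
#' @param cfg A \code{\link{prgs_config}}.
#' @return Object of class \code{"prgs"}: list with \code{pathway},
#'   \code{zscore} (named numeric), \code{n_datasets} (named integer),
#'   \code{threshold} and \code{discrete} (character vector).
#' @export
build_prgs <- function(pset, cfg = prgs_config()) {
  tab <- pathway_gene_zscores(pset, cfg)
  if (nrow(tab) == 0L)
    stop(sprintf("pathway '%s' yields no genes in >= %d datasets",
                 pset$pathway, cfg$min_datasets))
  zscore <- setNames(tab$zscore, tab$gene)
  structure(
    list(pathway = pset$pathway, zscore = zscore,
         n_datasets = setNames(tab$n_datasets, tab$gene),
         threshold = cfg$threshold,
         discrete = tab$gene[abs(tab$zscore) > cfg$threshold]),
    class = "prgs")
}

#' @export
print.prgs <- function(x, ...) {
  cat(sprintf("PRGS for pathway '%s': %d scored genes, %d discrete (|z| > %g)\n",
              x$pathway, length(x$zscore), length(x$discrete), x$threshold))
  invisible(x)
}

#' @export
summary.prgs <- function(object, ...) {
  z <- object$zscore
  cat(sprintf("PRGS '%s'\n", object$pathway))
  cat(sprintf("  genes scored: %d (in %d-%d datasets)\n", length(z),
              min(object$n_datasets), max(object$n_datasets)))
  cat(sprintf("  z-score range: [%.3f, %.3f]\n", min(z), max(z)))
  cat(sprintf("  discrete (|z| > %g): %d up, %d down\n", object$threshold,
              sum(z[object$discrete] > 0), sum(z[object$discrete] < 0)))
  invisible(object)
}

#' Jaccard index between two gene sets
#'
#' |a intersect b| / |a union b|; used to compare responsive signatures against
#' static pathway-membership gene sets.
#'
#' @param a,b Character vectors (at least one nonempty).
#' @return Number in [0, 1].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L)
    stop("Jaccard index undefined for two empty sets")
  length(intersect(a, b)) / length(union(a, b))
}
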