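## Enrichment statistics over ranked gene lists: the weighted running-sum
## (GSEA-like) enrichment score with a gene-set permutation null, and the
## hypergeometric over-representation test. The Bates rank test lives in
## bates.R; the LOESS-derived z computation feeding it is below.

#' Rank genes by t-statistic
#'
#' Descending by t; exact ties break lexicographically by gene identifier, so
#' the ranking is deterministic.
#'
#' @param deg_records \code{data.frame} with columns \code{gene} and
#'   \code{t_stat} (one row per gene), or a named numeric vector.
#' @return Object of class \code{"ranked_genes"}: list with \code{genes}
#'   (ordered ids) and \code{metric} (named numeric, same order).
#' @export
rank_genes <- function(deg_records) {
  if (is.data.frame(deg_records)) {
    stopifnot(all(c("gene", "t_stat") %in% names(deg_records)))
    metric <- setNames(deg_records$t_stat, deg_records$gene)
  } else {
    stopifnot(is.numeric(deg_records), !is.null(names(deg_records)))
    metric <- deg_records
  }
  if (length(metric) == 0L) stop("no genes to rank")
  if (anyDuplicated(names(metric)))
    stop("duplicate gene identifier(s): ",
         paste(unique(names(metric)[duplicated(names(metric))]), collapse = ", "))
  o <- order(-metric, names(metric))
  structure(list(genes = names(metric)[o], metric = metric[o]),
            class = "ranked_genes")
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list accumulating |metric|^weight_p / N_R at set members
#' (hits) and 1 / (N - N_H) at non-members (misses); the enrichment score is
#' the signed value of the running difference P_hit - P_miss at the position
#' of its maximum absolute deviation (first such position on ties).
#'
#' @param ranked A \code{\link{rank_genes}} result.
#' @param s Character vector: the gene set (must intersect the list but not
#'   cover it).
#' @param weight_p Weighting exponent on |metric|; default 1 (0 gives the
#'   classical unweighted Kolmogorov-Smirnov statistic).
#' @return List with \code{es}, \code{profile} (running deviation, one value
#'   per list position), \code{argmax_pos}, and \code{n_hit}.
#' @export
enrichment_score <- function(ranked, s, weight_p = 1) {
  stopifnot(inherits(ranked, "ranked_genes"))
  hit <- ranked$genes %in% s
  n_hit <- sum(hit)
  N <- length(ranked$genes)
  if (n_hit == 0L) stop("no overlap between gene set and ranked list")
  if (n_hit == N) stop("gene set covers the entire ranked list")
  w <- abs(ranked$metric)^weight_p
  nr <- sum(w[hit])
  if (nr == 0)
    stop("all set members carry zero metric weight; use weight_p = 0")
  p_hit <- cumsum(ifelse(hit, w, 0)) / nr
  p_miss <- cumsum(!hit) / (N - n_hit)
  profile <- p_hit - p_miss
  pos <- which.max(abs(profile))
  list(es = profile[[pos]], profile = unname(profile),
       argmax_pos = pos, n_hit = n_hit)
}

# Enrichment score from sorted hit positions only (O(k) per permutation):
# the running deviation is piecewise linear, decreasing between hits, so its
# extrema occur at hit positions (after the hit step) or immediately before a
# hit; both candidate sets are evaluated in closed form.
es_from_positions <- function(pos_sorted, w_hits, N) {
  k <- length(pos_sorted)
  cw <- cumsum(w_hits)
  W <- cw[k]
  j <- seq_len(k)
  at_hit <- cw / W - (pos_sorted - j) / (N - k)
  before_hit <- c(0, cw[-k]) / W - (pos_sorted - j) / (N - k)
  cand <- c(at_hit, before_hit)
  cand[[which.max(abs(cand))]]
}

#' GSEA-like enrichment test with a gene-set permutation null
#'
#' Significance of the \code{\link{enrichment_score}} is assessed against
#' random gene sets of the same size drawn from the ranked list; the p-value
#' uses add-one smoothing, p = (1 + #{|ES*| >= |ES|}) / (1 + n_perm), and is
#' deterministic under a fixed seed.
#'
#' @param ranked A \code{\link{rank_genes}} result.
#' @param s Gene set (character vector).
#' @param weight_p Weighting exponent; default 1.
#' @param n_perm Number of permutations (>= 100); default 10000.
#' @param seed Optional integer seed for the permutation stream.
#' @return List with \code{method = "gsea_like"}, \code{statistic} (the ES),
#'   \code{p_value}, \code{n_set}, \code{n_overlap}, and \code{details}
#'   (argmax position, n_perm, seed).
#' @export
gsea_like_test <- function(ranked, s, weight_p = 1, n_perm = 10000L,
                           seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  obs <- enrichment_score(ranked, s, weight_p)
  N <- length(ranked$genes)
  k <- obs$n_hit
  w_all <- abs(ranked$metric)^weight_p
  perm_abs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sort.int(sample.int(N, k))
      abs(es_from_positions(idx, w_all[idx], N))
    }, numeric(1))
  })
  p <- (1 + sum(perm_abs >= abs(obs$es))) / (1 + n_perm)
  list(method = "gsea_like", statistic = obs$es, p_value = p,
       n_set = length(unique(s)), n_overlap = k,
       details = list(argmax_pos = obs$argmax_pos, n_perm = n_perm,
                      seed = seed, weight_p = weight_p))
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least k genes shared between the
#' query set (e.g. DEGs) and the signature, under random draws from the
#' universe: P(X >= k) with X ~ Hypergeometric(N, M, n), where N = |universe|,
#' M = |signature in universe|, n = |query|, k = |query in signature|.
#'
#' @param degs Query gene set; must be a subset of \code{universe}.
#' @param prgs_discrete Signature gene set (discrete PRGS).
#' @param universe Background gene universe.
#' @return List with \code{method = "hypergeom"}, \code{statistic} (overlap
#'   k), \code{p_value}, \code{n_set}, \code{n_overlap}, \code{details}
#'   (N, M, n, k).
#' @export
hypergeom_test <- function(degs, prgs_discrete, universe) {
  degs <- unique(as.character(degs))
  universe <- unique(as.character(universe))
  if (length(universe) < 1L) stop("empty universe")
  if (length(setdiff(degs, universe)) > 0L)
    stop("query genes outside the universe: ",
         paste(head(setdiff(degs, universe), 5), collapse = ", "))
  M_set <- intersect(unique(as.character(prgs_discrete)), universe)
  if (length(M_set) == 0L) stop("PRGS disjoint from universe")
  N <- length(universe); n <- length(degs); M <- length(M_set)
  k <- length(intersect(degs, M_set))
  p <- if (k == 0L) 1 else phyper(k - 1L, M, N - M, n, lower.tail = FALSE)
  list(method = "hypergeom", statistic = k, p_value = p,
       n_set = M, n_overlap = k,
       details = list(N = N, M = M, n = n, k = k))
}

#' LOESS-scaled differential-expression z-values
#'
#' Computes per-gene z-values as the ratio of log fold change to a local
#' scale estimate: a LOESS curve of |log_fc| against mean expression serves as
#' the local absolute-deviation proxy for the standard deviation, so that z is
#' invariant to an overall rescaling of the fold changes.
#'
#' @param log_fc Numeric vector of log fold changes (length >= 20).
#' @param mean_expr Mean expression per gene, same length.
#' @param span LOESS span; default 0.5.
#' @param degree Local polynomial degree; default 2.
#' @return Numeric vector of z-values, finite.
#' @export
loess_z <- function(log_fc, mean_expr, span = 0.5, degree = 2) {
  if (length(log_fc) != length(mean_expr)) stop("length mismatch")
  if (length(log_fc) < 20L) stop("need >= 20 genes for a stable LOESS fit")
  if (any(!is.finite(log_fc)) || any(!is.finite(mean_expr)))
    stop("inputs must be finite")
  if (all(log_fc == 0)) stop("all fold changes are zero")
  fit <- loess(abs(log_fc) ~ mean_expr, span = span, degree = degree)
  sd_hat <- pmax(predict(fit, mean_expr), 1e-8)
  z <- log_fc / sd_hat
  stopifnot(all(is.finite(z)))
  z
}

#' Run all three enrichment methods over a PRGS collection
#'
#' Wires the full contrast for one drug: split cell lines into groups, rank
#' all genes by t-statistic, select DEGs, then score each pathway with the
#' GSEA-like statistic (discrete PRGS vs the full ranked list), the
#' hypergeometric test (DEGs vs discrete PRGS over the expression universe)
#' and the Bates rank test (continuous PRGS vs DEGs). Per-pathway errors are
#' reported in the \code{note} column and do not stop the run; an empty DEG
#' set leaves the hypergeometric and Bates rows not evaluable while the
#' GSEA-like score is still computed.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param auc_table Long drug-response \code{data.frame}.
#' @param drug Drug name.
#' @param prgs_collection List of \code{\link{build_prgs}} objects.
#' @param config Optional list overriding \code{auc_threshold} (0.8),
#'   \code{n_sensitive} (8), \code{n_resistant_min} (8), \code{n_resistant_max}
#'   (12), \code{p_max} (0.01), \code{t_min_abs} (0), \code{weight_p} (1),
#'   \code{n_perm} (1000), \code{p_cutoff} (0.01), \code{seed} (NULL).
#' @return \code{data.frame} with one row per (pathway, method): columns
#'   \code{drug}, \code{pathway}, \code{method}, \code{statistic},
#'   \code{p_value}, \code{n_set}, \code{n_overlap}, \code{significant},
#'   \code{note}.
#' @export
run_all_methods <- function(expr, auc_table, drug, prgs_collection,
                            config = list()) {
  cfg <- modifyList(list(auc_threshold = 0.8, n_sensitive = 8L,
                         n_resistant_min = 8L, n_resistant_max = 12L,
                         p_max = 0.01, t_min_abs = 0, weight_p = 1,
                         n_perm = 1000L, p_cutoff = 0.01, seed = NULL),
                    config)
  expr <- as_expression_matrix(expr)
  groups <- assign_groups(auc_table, drug, cfg$auc_threshold, cfg$n_sensitive,
                          cfg$n_resistant_min, cfg$n_resistant_max)
  de <- differential_expression(expr, groups)
  ranked <- rank_genes(de)
  degs <- select_degs(de, p_max = cfg$p_max, t_min_abs = cfg$t_min_abs)$gene
  universe <- rownames(expr)
  rows <- list()
  add <- function(pathway, method, res, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      drug = drug, pathway = pathway, method = method,
      statistic = if (is.null(res)) NA_real_ else as.numeric(res$statistic),
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      n_set = if (is.null(res)) NA_integer_ else as.integer(res$n_set),
      n_overlap = if (is.null(res)) NA_integer_ else as.integer(res$n_overlap),
      significant = if (is.null(res)) NA else res$p_value < cfg$p_cutoff,
      note = note, row.names = NULL)
  }
  for (i in seq_along(prgs_collection)) {
    prgs <- prgs_collection[[i]]
    stopifnot(inherits(prgs, "prgs"))
    # permutation stream keyed by set content so identical signatures get
    # identical p-values regardless of pathway label or position
    seed_i <- if (is.null(cfg$seed)) NULL else
      child_seed(cfg$seed, paste0("gsea:", paste(sort(prgs$discrete),
                                                 collapse = "|")))
    tryCatch(
      add(prgs$pathway, "gsea_like",
          gsea_like_test(ranked, prgs$discrete, cfg$weight_p, cfg$n_perm,
                         seed = seed_i)),
      error = function(e) add(prgs$pathway, "gsea_like", NULL,
                              note = conditionMessage(e)))
    if (length(degs) == 0L) {
      add(prgs$pathway, "hypergeom", NULL, note = "not evaluable: no DEGs")
      add(prgs$pathway, "bates", NULL, note = "not evaluable: no DEGs")
      next
    }
    tryCatch(
      add(prgs$pathway, "hypergeom",
          hypergeom_test(degs, prgs$discrete, universe)),
      error = function(e) add(prgs$pathway, "hypergeom", NULL,
                              note = conditionMessage(e)))
    tryCatch(
      add(prgs$pathway, "bates", bates_test(prgs$zscore, degs)),
      error = function(e) add(prgs$pathway, "bates", NULL,
                              note = conditionMessage(e)))
  }
  do.call(rbind, rows)
}
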