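## Drug-response cohort handling: sensitive/resistant splits from AUC values
## and differential expression between the two groups.

#' Split cell lines into drug-sensitive and drug-resistant groups
#'
#' Sensitive lines have AUC strictly below \code{auc_threshold}, resistant
#' lines AUC at or above it. The \code{n_sensitive} lines with smallest AUC and
#' up to \code{n_resistant_max} lines with largest AUC are selected (at least
#' \code{n_resistant_min} must qualify). AUC ties break lexicographically by
#' cell-line identifier, so the split is invariant to input row order.
#'
#' @param table Long drug-response \code{data.frame}
#'   (see \code{\link{as_drug_response}}).
#' @param drug Drug name to split on.
#' @param auc_threshold Sensitive/resistant AUC boundary; default 0.8.
#' @param n_sensitive Number of sensitive lines to take; default 8.
#' @param n_resistant_min,n_resistant_max Bounds on the resistant group size;
#'   defaults 8 and 12.
#' @return Object of class \code{"drug_groups"}: list with \code{drug},
#'   \code{sensitive} and \code{resistant} (data.frames of \code{cell_line},
#'   \code{auc}) and \code{auc_threshold}.
#' @export
assign_groups <- function(table, drug, auc_threshold = 0.8,
                          n_sensitive = 8L, n_resistant_min = 8L,
                          n_resistant_max = 12L) {
  table <- as_drug_response(table)
  sub <- table[table$drug == drug, ]
  if (nrow(sub) == 0L) stop("no AUC entries for drug '", drug, "'")
  sens_pool <- sub[sub$auc < auc_threshold, ]
  res_pool <- sub[sub$auc >= auc_threshold, ]
  if (nrow(sens_pool) < n_sensitive)
    stop(sprintf("drug '%s': only %d line(s) below AUC %g (need %d sensitive)",
                 drug, nrow(sens_pool), auc_threshold, n_sensitive))
  if (nrow(res_pool) < n_resistant_min)
    stop(sprintf("drug '%s': only %d line(s) at/above AUC %g (need >= %d resistant)",
                 drug, nrow(res_pool), auc_threshold, n_resistant_min))
  sens_pool <- sens_pool[order(sens_pool$auc, sens_pool$cell_line), ]
  res_pool <- res_pool[order(-res_pool$auc, res_pool$cell_line), ]
  sens <- head(sens_pool, n_sensitive)
  res <- head(res_pool, n_resistant_max)
  structure(
    list(drug = drug,
         sensitive = data.frame(cell_line = sens$cell_line, auc = sens$auc,
                                row.names = NULL),
         resistant = data.frame(cell_line = res$cell_line, auc = res$auc,
                                row.names = NULL),
         auc_threshold = auc_threshold),
    class = "drug_groups")
}

#' @export
print.drug_groups <- function(x, ...) {
  cat(sprintf("Drug '%s' (AUC threshold %g): %d sensitive, %d resistant\n",
              x$drug, x$auc_threshold, nrow(x$sensitive), nrow(x$resistant)))
  cat("  sensitive AUC:", sprintf("%.3f", x$sensitive$auc), "\n")
  cat("  resistant AUC:", sprintf("%.3f", x$resistant$auc), "\n")
  invisible(x)
}

#' Flag drugs with extreme response bias
#'
#' A drug is dropped when more than \code{limit} (strictly) of its profiled
#' lines fall on one side of the AUC threshold, since a near-uniform response
#' leaves no contrast to analyze.
#'
#' @param table Long drug-response \code{data.frame}.
#' @param drug Drug name.
#' @param limit Bias fraction limit; default 0.9.
#' @param auc_threshold Sensitive/resistant boundary; default 0.8.
#' @return \code{TRUE} to keep the drug, \code{FALSE} to drop it.
#' @export
extreme_bias_filter <- function(table, drug, limit = 0.9, auc_threshold = 0.8) {
  table <- as_drug_response(table)
  auc <- table$auc[table$drug == drug]
  if (length(auc) < 10L)
    stop(sprintf("drug '%s' has %d profiled line(s); need >= 10 for a stable bias fraction",
                 drug, length(auc)))
  frac <- max(mean(auc >= auc_threshold), mean(auc < auc_threshold))
  frac <= limit
}

#' Differential expression between resistant and sensitive groups
#'
#' Per gene, a two-sample t-test oriented resistant minus sensitive ("up"
#' means higher expression in the resistant group). The default is the
#' pooled-variance Student test; Welch is available. Genes with zero pooled
#' variance get t = 0, p = 1.
#'
#' @param matrix Genes-by-samples numeric matrix.
#' @param groups A \code{\link{assign_groups}} result; every member cell line
#'   must be a column of \code{matrix} and each group must have >= 2 members.
#' @param var_equal Pooled-variance Student test if \code{TRUE} (default),
#'   Welch otherwise.
#' @return \code{data.frame} with columns \code{gene}, \code{t_stat},
#'   \code{p_value}, \code{direction} ("up"/"down").
#' @export
differential_expression <- function(matrix, groups, var_equal = TRUE) {
  matrix <- as_expression_matrix(matrix)
  stopifnot(inherits(groups, "drug_groups"))
  res_ids <- groups$resistant$cell_line
  sens_ids <- groups$sensitive$cell_line
  missing <- setdiff(c(res_ids, sens_ids), colnames(matrix))
  if (length(missing) > 0L)
    stop("cell line(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(res_ids) < 2L || length(sens_ids) < 2L)
    stop("each group needs >= 2 members")
  X <- matrix[, res_ids, drop = FALSE]
  Y <- matrix[, sens_ids, drop = FALSE]
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, nrow(matrix))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t_stat <- ifelse(se > 0, (mx - my) / se, 0)
  p_value <- ifelse(se > 0, 2 * pt(-abs(t_stat), df), 1)
  data.frame(gene = rownames(matrix), t_stat = t_stat, p_value = p_value,
             direction = ifelse(t_stat >= 0, "up", "down"),
             row.names = NULL)
}

#' Select differentially expressed genes
#'
#' Keeps records with p strictly below \code{p_max} and |t| strictly above
#' \code{t_min_abs}. The returned data.frame carries an \code{"n_up"} /
#' \code{"n_down"} attribute with the direction partition.
#'
#' @param records Output of \code{\link{differential_expression}}.
#' @param p_max p-value cutoff (strict); default 0.01.
#' @param t_min_abs additional |t| filter (strict); default 0 (off). The
#'   companion magnitude filter used alongside p < 0.01 is 2.8.
#' @return Subset of \code{records}.
#' @export
select_degs <- function(records, p_max = 0.01, t_min_abs = 0) {
  stopifnot(is.data.frame(records),
            all(c("gene", "t_stat", "p_value", "direction") %in% names(records)))
  if (nrow(records) == 0L) stop("records must be nonempty")
  out <- records[records$p_value < p_max & abs(records$t_stat) > t_min_abs, ]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  out
}
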