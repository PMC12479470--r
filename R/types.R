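## Domain containers. Deliberately light-weight: plain lists / data.frames /
## matrices with validating constructors, following base-R modelling idiom.

#' Construct a perturbation experiment
#'
#' One perturbation dataset: a pathway label, a perturbation type, an accession
#' label, and a per-gene table of raw z-values. A gene may appear more than
#' once at load time (probe-level duplicates); \code{\link{collapse_duplicates}}
#' resolves them.
#'
#' @param pathway Pathway label (nonempty string).
#' @param ptype Perturbation type: \code{"activation"} or \code{"inhibition"}
#'   (synonyms such as \code{"activating"}, \code{"stimulation"},
#'   \code{"inhibiting"} are accepted, case-insensitively).
#' @param accession Experiment accession label (nonempty string).
#' @param gene Character vector of gene identifiers.
#' @param z Numeric vector of raw z-values, same length as \code{gene}.
#' @return An object of class \code{"perturbation_experiment"}.
#' @export
perturbation_experiment <- function(pathway, ptype, accession, gene, z) {
  stopifnot(is.character(gene), is.numeric(z))
  if (length(gene) != length(z))
    stop("gene and z must have the same length")
  if (!is.character(pathway) || length(pathway) != 1L || !nzchar(pathway))
    stop("pathway must be a nonempty string")
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession))
    stop("accession must be a nonempty string")
  if (any(!is.finite(z)))
    stop("z values must be finite")
  structure(
    list(pathway = pathway, ptype = parse_ptype(ptype),
         accession = accession, gene = gene, z = as.numeric(z)),
    class = "perturbation_experiment")
}

#' @export
print.perturbation_experiment <- function(x, ...) {
  cat(sprintf("Perturbation experiment %s [%s, %s]: %d gene records\n",
              x$accession, x$pathway, x$ptype, length(x$gene)))
  invisible(x)
}

#' Parse a perturbation-type token
#'
#' Case-insensitive; \code{activating}/\code{stimulation} map to
#' \code{activation}, \code{inhibiting} to \code{inhibition}.
#'
#' @param token Character scalar.
#' @return \code{"activation"} or \code{"inhibition"}.
#' @export
parse_ptype <- function(token) {
  if (!is.character(token) || length(token) != 1L)
    stop("ptype must be a single string")
  tok <- tolower(trimws(token))
  if (tok %in% c("activation", "activating", "stimulation")) return("activation")
  if (tok %in% c("inhibition", "inhibiting")) return("inhibition")
  stop(sprintf(paste0("unknown perturbation type '%s'; accepted tokens: ",
                      "activation, activating, stimulation, inhibition, ",
                      "inhibiting"), token))
}

#' Group perturbation experiments for one pathway
#'
#' @param pathway Pathway label.
#' @param experiments Nonempty list of \code{perturbation_experiment} objects,
#'   all sharing \code{pathway}.
#' @return An object of class \code{"pathway_experiment_set"}.
#' @export
pathway_experiment_set <- function(pathway, experiments) {
  if (length(experiments) == 0L)
    stop("experiments must be nonempty")
  ok <- vapply(experiments, function(e)
    inherits(e, "perturbation_experiment") && identical(e$pathway, pathway),
    logical(1))
  if (!all(ok))
    stop("all experiments must be perturbation_experiment objects sharing the pathway label")
  structure(list(pathway = pathway, experiments = experiments),
            class = "pathway_experiment_set")
}

#' @export
print.pathway_experiment_set <- function(x, ...) {
  cat(sprintf("Pathway '%s': %d perturbation experiment(s)\n",
              x$pathway, length(x$experiments)))
  invisible(x)
}

#' Validate a genes-by-samples expression matrix
#'
#' The package represents expression data as a base numeric matrix with unique
#' gene row names and unique sample column names; this checks the invariants.
#'
#' @param values Numeric matrix, rows = genes, columns = samples.
#' @return The validated matrix (invisibly unchanged).
#' @export
as_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in expression matrix")
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  values
}

#' Validate a long-form drug-response table
#'
#' @param entries \code{data.frame} with columns \code{cell_line}, \code{drug}
#'   and \code{auc} (area under the concentration-response curve, in [0, 1]).
#' @return The validated \code{data.frame}.
#' @export
as_drug_response <- function(entries) {
  need <- c("cell_line", "drug", "auc")
  if (!is.data.frame(entries) || !all(need %in% names(entries)))
    stop("drug-response table needs columns cell_line, drug, auc")
  entries$auc <- as.numeric(entries$auc)
  if (any(!is.finite(entries$auc)) || any(entries$auc < 0 | entries$auc > 1))
    stop("AUC values must lie in [0, 1]")
  if (anyDuplicated(entries[c("cell_line", "drug")]))
    stop("duplicate (cell_line, drug) pairs in drug-response table")
  entries[need]
}
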