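## Readers/writers for the tabular formats the framework touches: GMT gene
## sets, TSV expression matrices, long/wide AUC tables, long perturbation
## tables. All text, UTF-8, tab-separated.

#' Read gene sets from a GMT file
#'
#' Each line is \code{name<TAB>description<TAB>member1<TAB>member2...}.
#' Duplicate members within a line are collapsed; set order is preserved.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (the members, unique, in first-seen
#'   order); each element carries a \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d (need >= 3 tab-separated fields)", i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("GMT line %d has no members", i))
    nms[i] <- f[1]
    sets[[i]] <- structure(members, description = f[2])
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' Members are written in lexicographic order so output is deterministic.
#'
#' @param sets Nonempty named list of character vectors, optionally carrying a
#'   \code{"description"} attribute (defaults to the set name).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  if (length(sets) == 0L) stop("sets must be nonempty")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set needs a name")
  lines <- vapply(seq_along(sets), function(i) {
    members <- unique(as.character(sets[[i]]))
    if (length(members) == 0L)
      stop(sprintf("gene set '%s' has no members", names(sets)[i]))
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    fields <- c(names(sets)[i], desc, sort(members))
    if (any(grepl("\t", fields, fixed = TRUE)))
      stop("GMT fields cannot contain tab characters")
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' First column = gene identifiers, header row = sample identifiers. Duplicate
#' gene rows and non-numeric cells are errors (pre-collapse duplicates
#' explicitly; silent aggregation is not performed).
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene row names and sample column names.
#' @export
read_expression_table <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("expression table needs a gene column plus >= 1 sample")
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s) in expression table: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(raw[-1])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                 vals[bad[1], bad[2]], bad[1], colnames(raw)[-1][bad[2]]))
  }
  dimnames(num) <- list(genes, colnames(raw)[-1])
  as_expression_matrix(num)
}

#' Write an expression matrix to TSV
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param digits Significant digits to keep (default 6).
#' @export
write_expression_table <- function(mat, path, digits = 6) {
  mat <- as_expression_matrix(mat)
  df <- data.frame(gene = rownames(mat), signif(mat, digits),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a perturbation-experiment compendium from long TSV
#'
#' Expects columns \code{pathway}, \code{accession}, \code{ptype}, \code{gene},
#' \code{z}. Rows are grouped into one experiment per (pathway, accession), and
#' experiments into one \code{\link{pathway_experiment_set}} per pathway, in
#' first-seen order.
#'
#' @param path Path to a TSV file.
#' @return Named list of \code{pathway_experiment_set} objects.
#' @export
read_perturbation_experiments <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  need <- c("pathway", "accession", "ptype", "gene", "z")
  if (!all(need %in% names(df)))
    stop("perturbation table needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("empty perturbation table: ", path)
  z <- suppressWarnings(as.numeric(df$z))
  if (anyNA(z))
    stop("non-numeric z value at row ", which(is.na(z))[1])
  key <- paste(df$pathway, df$accession, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    rows <- key == k
    ptok <- unique(df$ptype[rows])
    if (length(ptok) != 1L)
      stop("inconsistent ptype within experiment ", df$accession[rows][1])
    exp <- perturbation_experiment(
      pathway = df$pathway[rows][1], ptype = ptok,
      accession = df$accession[rows][1],
      gene = df$gene[rows], z = z[rows])
    out[[exp$pathway]] <- c(out[[exp$pathway]], list(exp))
  }
  lapply(setNames(nm = names(out)), function(p)
    pathway_experiment_set(p, out[[p]]))
}

#' Write a perturbation-experiment compendium to long TSV
#'
#' @param psets List of \code{pathway_experiment_set} objects.
#' @param path Output path.
#' @export
write_perturbation_experiments <- function(psets, path) {
  rows <- do.call(rbind, lapply(psets, function(ps)
    do.call(rbind, lapply(ps$experiments, function(e)
      data.frame(pathway = e$pathway, accession = e$accession,
                 ptype = e$ptype, gene = e$gene, z = e$z)))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a drug-response AUC table (wide or long TSV)
#'
#' Long form has header columns \code{cell_line}, \code{drug}, \code{auc};
#' anything else is treated as wide form (first column = cell lines, remaining
#' columns = drugs; blank cells are missing pairs). The form is auto-detected
#' from the header.
#'
#' @param path Path to a TSV file.
#' @return Long \code{data.frame} with columns \code{cell_line}, \code{drug},
#'   \code{auc}.
#' @export
read_drug_response <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (all(c("cell_line", "drug", "auc") %in% names(df))) {
    df$auc <- parse_auc(df$auc)
    return(as_drug_response(df))
  }
  if (ncol(df) < 2L) stop("wide AUC table needs >= 1 drug column")
  long <- do.call(rbind, lapply(names(df)[-1], function(d) {
    keep <- nzchar(trimws(df[[d]])) & !is.na(df[[d]])
    data.frame(cell_line = df[[1]][keep], drug = d,
               auc = parse_auc(df[[d]][keep]))
  }))
  as_drug_response(long)
}

parse_auc <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) stop("non-numeric AUC value: ", x[which(is.na(v))[1]])
  if (any(v < 0 | v > 1))
    stop("AUC out of range [0, 1]: ", v[which(v < 0 | v > 1)[1]])
  v
}

#' Write a drug-response table to long TSV
#'
#' @param entries Long drug-response \code{data.frame}
#'   (see \code{\link{as_drug_response}}).
#' @param path Output path.
#' @export
write_drug_response <- function(entries, path) {
  entries <- as_drug_response(entries)
  write.table(entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
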