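#' Construct a spectral-count matrix
#'
#' The central container of the package: an integer proteins x samples
#' spectral-count table together with per-protein identification metadata, a
#' two-group sample annotation and per-sample totals of significant assigned
#' spectra. Per-sample totals are always recomputed as column sums over the
#' retained records, so they stay consistent under filtering and subsetting.
#'
#' @param counts integer matrix, proteins in rows (rownames = accessions),
#'   samples in columns (colnames = sample ids). All entries must be
#'   non-negative integers; missing values are rejected, a zero must be
#'   explicit because cohort-unique classification hinges on true zeros.
#' @param annotation data.frame with columns `sample_id` and `group`; every
#'   sample of `counts` must appear exactly once and the groups must be
#'   exactly two, both non-empty.
#' @param meta optional data.frame of identification metadata with columns
#'   `accession`, `gene`, `description`, `unique_peptides`, `probability`,
#'   `is_contaminant`, `is_decoy`, `is_cdna_like`. Missing columns are filled
#'   with permissive defaults (empty text, `unique_peptides = 2`,
#'   `probability = 1`, all flags `FALSE`).
#' @param reference group label used as the reference (denominator) cohort,
#'   e.g. "CN". Defaults to the group of the first annotated sample.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `meta`, `annotation`, `sample_totals` and attribute-like element
#'   `groups` (`c(reference, comparison)`).
#' @examples
#' m <- matrix(rpois(24, 5), 3, 8,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:8)))
#' ann <- data.frame(sample_id = paste0("S", 1:8),
#'                   group = rep(c("CN", "CR"), each = 4))
#' cm <- count_matrix(m, ann)
#' cm$sample_totals
#' @export
count_matrix <- function(counts, annotation, meta = NULL, reference = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("`counts` must have sample-id colnames")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    stop("`counts` must have accession rownames")
  if (anyNA(counts))
    stop("`counts` contains missing values; zeros must be explicit")
  if (!is.numeric(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("`counts` must contain non-negative integers")
  storage.mode(counts) <- "integer"
  acc <- rownames(counts) %||% character(0)
  if (any(acc == "") || anyNA(acc)) stop("empty accession in `counts` rownames")
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))

  annotation <- validate_annotation(annotation)
  if (!setequal(colnames(counts), annotation$sample_id))
    stop("sample ids of `counts` and `annotation` differ")
  annotation <- annotation[match(colnames(counts), annotation$sample_id), ,
                           drop = FALSE]
  rownames(annotation) <- NULL

  groups <- unique(annotation$group)
  if (is.null(reference)) reference <- groups[1L]
  if (!reference %in% groups) stop("reference group '", reference,
                                   "' not present in annotation")
  groups <- c(reference, setdiff(groups, reference))

  meta <- complete_meta(meta, acc)

  structure(list(counts = counts,
                 meta = meta,
                 annotation = annotation,
                 sample_totals = colSums(counts),
                 groups = groups),
            class = "count_matrix")
}

validate_annotation <- function(annotation) {
  if (!is.data.frame(annotation) ||
      !all(c("sample_id", "group") %in% names(annotation)))
    stop("annotation must be a data.frame with columns sample_id and group")
  annotation$sample_id <- as.character(annotation$sample_id)
  annotation$group <- as.character(annotation$group)
  if (anyDuplicated(annotation$sample_id))
    stop("duplicate sample_id in annotation")
  groups <- unique(annotation$group)
  if (length(groups) != 2L)
    stop("annotation must define exactly two groups, found: ",
         paste(groups, collapse = ", "))
  annotation[, c("sample_id", "group")]
}

complete_meta <- function(meta, accessions) {
  n <- length(accessions)
  out <- data.frame(accession = accessions,
                    gene = character(n),
                    description = character(n),
                    unique_peptides = rep(2L, n),
                    probability = rep(1, n),
                    is_contaminant = logical(n),
                    is_decoy = logical(n),
                    is_cdna_like = logical(n),
                    stringsAsFactors = FALSE)
  if (is.null(meta)) return(out)
  if (!"accession" %in% names(meta)) stop("meta needs an accession column")
  i <- match(accessions, meta$accession)
  if (anyNA(i)) stop("meta is missing accession(s): ",
                     paste(accessions[is.na(i)], collapse = ", "))
  for (col in setdiff(names(out), "accession"))
    if (col %in% names(meta)) out[[col]] <- meta[[col]][i]
  out$unique_peptides <- as.integer(out$unique_peptides)
  out$probability <- as.numeric(out$probability)
  if (any(out$probability < 0 | out$probability > 1, na.rm = TRUE))
    stop("protein probability must lie in [0, 1]")
  for (col in c("is_contaminant", "is_decoy", "is_cdna_like"))
    out[[col]] <- as.logical(out[[col]])
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  g <- x$groups
  n_g <- table(factor(x$annotation$group, levels = g))
  cat(sprintf("count_matrix: %d proteins x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  groups: %s (reference, n=%d) vs %s (n=%d)\n",
              g[1], n_g[1], g[2], n_g[2]))
  cat(sprintf("  total significant spectra: %s\n",
              format(sum(x$sample_totals), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' `i` indexes records (proteins), `j` samples. Totals are recomputed over the
#' retained records. Dropping samples must leave both groups non-empty.
#'
#' @param x a [count_matrix()]
#' @param i,j row (protein) / column (sample) indices
#' @param ... ignored
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  keep <- match(rownames(counts), x$meta$accession)
  ann <- x$annotation[match(colnames(counts), x$annotation$sample_id), ,
                      drop = FALSE]
  count_matrix(counts, ann, meta = x$meta[keep, , drop = FALSE],
               reference = if (x$groups[1] %in% ann$group) x$groups[1] else NULL)
}

#' Sample ids of one group
#' @param x a [count_matrix()]
#' @param group group label
#' @return character vector of sample ids
#' @export
group_samples <- function(x, group) {
  x$annotation$sample_id[x$annotation$group == group]
}
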