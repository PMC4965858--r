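#' Column mapping for protein identification reports
#'
#' Vendor exports (Scaffold-style and others) name their columns freely; a
#' dialect maps them onto the canonical fields. Columns not mapped to a
#' canonical field are treated as per-sample spectral-count columns unless
#' `samples` lists them explicitly. Flag columns are optional: absent flags
#' default to `FALSE` and can later be inferred (see [flag_cdna_like()]).
#'
#' @param accession,gene,description,unique_peptides,probability column names
#'   in the report header; `gene`, `description`, `unique_peptides` and
#'   `probability` may be `NULL` if absent.
#' @param contaminant,decoy,cdna optional names of logical flag columns
#'   (accepted cell values: TRUE/FALSE, 1/0, yes/no, case-insensitive).
#' @param samples optional explicit character vector of sample columns.
#' @return a `report_dialect` list.
#' @export
report_dialect <- function(accession = "accession", gene = "gene",
                           description = "description",
                           unique_peptides = "unique_peptides",
                           probability = "probability",
                           contaminant = "is_contaminant",
                           decoy = "is_decoy", cdna = NULL,
                           samples = NULL) {
  structure(list(accession = accession, gene = gene,
                 description = description,
                 unique_peptides = unique_peptides,
                 probability = probability, contaminant = contaminant,
                 decoy = decoy, cdna = cdna, samples = samples),
            class = "report_dialect")
}

parse_flag <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n", "")] <- FALSE
  if (anyNA(out))
    stop("column '", column, "' has unparseable flag value(s): ",
         paste(unique(v[is.na(out)]), collapse = ", "))
  out
}

#' Read a protein identification report
#'
#' Ingests a tab-separated protein-level report (one row per protein, one
#' count column per sample holding the number of significant assigned MS/MS
#' spectra) into a [count_matrix()]. Counts must parse as non-negative
#' integers; a missing or malformed cell is an error naming the offending row
#' and column — blank cells are never imputed as zero.
#'
#' @param path report file (TSV, one header line, UTF-8, "." decimal point).
#' @param annotation sample annotation: a data.frame or path to a two-column
#'   TSV `sample_id  group`. Header sample columns must match the annotated
#'   sample ids exactly.
#' @param dialect a [report_dialect()].
#' @param reference reference group label (see [count_matrix()]).
#' @return a [count_matrix()] with totals computed over all rows read.
#' @export
read_protein_report <- function(path, annotation,
                                dialect = report_dialect(),
                                reference = NULL) {
  if (!file.exists(path)) stop("report file not found: ", path)
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  annotation <- validate_annotation(annotation)

  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "", na.strings = NULL,
                           fileEncoding = "UTF-8")
  mapped <- unlist(dialect[c("accession", "gene", "description",
                             "unique_peptides", "probability",
                             "contaminant", "decoy", "cdna")])
  missing_cols <- setdiff(mapped, names(raw))
  if (length(missing_cols))
    stop("report is missing configured column(s): ",
         paste(missing_cols, collapse = ", "))
  sample_cols <- dialect$samples %||% setdiff(names(raw), mapped)
  if (!length(sample_cols)) stop("report has no sample count columns")
  extra <- setdiff(sample_cols, annotation$sample_id)
  if (length(extra))
    stop("sample column(s) absent from annotation: ",
         paste(extra, collapse = ", "))
  absent <- setdiff(annotation$sample_id, sample_cols)
  if (length(absent))
    stop("annotated sample(s) missing from report header: ",
         paste(absent, collapse = ", "))

  acc <- trimws(raw[[dialect$accession]])
  bad <- which(acc == "")
  if (length(bad))
    stop("row(s) with missing accession rejected: data line(s) ",
         paste(bad, collapse = ", "))
  dup <- unique(acc[duplicated(acc)])
  if (length(dup))
    stop("duplicate accession(s): ", paste(dup, collapse = ", "))

  counts <- matrix(0L, nrow(raw), length(sample_cols),
                   dimnames = list(acc, sample_cols))
  for (col in sample_cols) {
    cell <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val) | val < 0 | val != floor(val))
    if (length(bad))
      stop(sprintf("unparseable or negative count '%s' (row %s, column '%s')",
                   cell[bad[1]], acc[bad[1]], col))
    counts[, col] <- as.integer(val)
  }

  meta <- data.frame(accession = acc, stringsAsFactors = FALSE)
  meta$gene <- if (!is.null(dialect$gene)) trimws(raw[[dialect$gene]]) else ""
  meta$description <- if (!is.null(dialect$description))
    raw[[dialect$description]] else ""
  if (!is.null(dialect$unique_peptides)) {
    up <- suppressWarnings(as.integer(raw[[dialect$unique_peptides]]))
    if (anyNA(up)) stop("unparseable unique_peptides value (row ",
                        acc[which(is.na(up))[1]], ")")
    meta$unique_peptides <- up
  }
  if (!is.null(dialect$probability)) {
    pr <- suppressWarnings(as.numeric(raw[[dialect$probability]]))
    if (anyNA(pr) || any(pr < 0 | pr > 1))
      stop("protein probability outside [0,1] or unparseable (row ",
           acc[which(is.na(pr) | pr < 0 | pr > 1)[1]], ")")
    meta$probability <- pr
  }
  if (!is.null(dialect$contaminant))
    meta$is_contaminant <- parse_flag(raw[[dialect$contaminant]],
                                      dialect$contaminant)
  if (!is.null(dialect$decoy))
    meta$is_decoy <- parse_flag(raw[[dialect$decoy]], dialect$decoy)
  if (!is.null(dialect$cdna))
    meta$is_cdna_like <- parse_flag(raw[[dialect$cdna]], dialect$cdna)

  count_matrix(counts, annotation, meta = meta, reference = reference)
}

#' Write a protein report in the canonical dialect
#'
#' Inverse of [read_protein_report()] with the default dialect; write/read
#' round-trips reproduce counts, metadata and flags exactly.
#'
#' @param x a [count_matrix()]
#' @param path output TSV path
#' @export
write_protein_report <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- cbind(x$meta[c("accession", "gene", "description", "unique_peptides",
                       "probability", "is_contaminant", "is_decoy")],
              as.data.frame(x$counts, check.names = FALSE))
  write_tsv(df, path)
}

#' Read / write a sample annotation table
#'
#' @param path two-column TSV `sample_id  group`
#' @return data.frame with columns `sample_id`, `group`
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           fileEncoding = "UTF-8")
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param annotation data.frame to write
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(validate_annotation(annotation), path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name  description
#' member...`. Duplicate members within a line are collapsed; duplicate set
#' names or lines with fewer than three fields are errors.
#'
#' @param path GMT file
#' @return a named list of class `gene_sets`; each element is
#'   `list(description =, genes =)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 0L) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("gene set '", p[1], "' is empty")
    list(description = p[2], genes = genes)
  })
  names(sets) <- nm
  structure(sets, class = "gene_sets")
}

#' Write a GMT gene-set collection
#' @param sets a `gene_sets` list as returned by [read_gmt()]
#' @param path output path
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t"),
    "")
  writeLines(lines, path, useBytes = TRUE)
}

differential_columns <- c("accession", "gene", "description", "n_ref",
                          "n_cmp", "present_ref", "present_cmp", "raw_ratio",
                          "rsc", "p_value", "q_value", "selected", "category")

#' Write / read a differential-expression table
#'
#' Tab-separated, stable column order
#' (`accession gene description n_ref n_cmp present_ref present_cmp
#' raw_ratio rsc p_value q_value selected category`), numerics at full
#' precision so that write-then-read is lossless.
#'
#' @param records data.frame of differential records
#'   (see [differential_analysis()])
#' @param path TSV path
#' @export
write_differential_table <- function(records, path) {
  miss <- setdiff(differential_columns, names(records))
  if (length(miss)) stop("differential table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- records[differential_columns]
  bad <- !vapply(df[c("raw_ratio", "rsc", "p_value", "q_value")],
                 function(x) all(is.finite(x)), TRUE)
  if (any(bad)) stop("non-finite values in column(s): ",
                     paste(names(bad)[bad], collapse = ", "))
  write_tsv(df, path)
}

#' @rdname write_differential_table
#' @export
read_differential_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(differential_columns, names(df))
  if (length(miss)) stop("differential table is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("n_ref", "n_cmp", "present_ref", "present_cmp"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("raw_ratio", "rsc", "p_value", "q_value"))
    df[[col]] <- as.numeric(df[[col]])
  df$selected <- as.logical(df$selected)
  df
}

# full-precision deterministic TSV writer shared by all tabular output
write_tsv <- function(df, path) {
  df <- as.data.frame(df, check.names = FALSE)
  for (col in names(df)) {
    x <- df[[col]]
    if (is.double(x)) df[[col]] <- sprintf("%.17g", x)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ok <- try(utils::write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write: ", path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
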