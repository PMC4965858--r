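#' Identification acceptance and exclusion policy
#'
#' Defaults encode the study-grade acceptance rules for spectral-counting
#' reports: protein probability of at least 99%, at least two identified
#' unique peptides, and exclusion of contaminant, reversed-database (decoy)
#' and "cDNA-like" entries. The probability rule is implemented as
#' `probability >= min_probability` (validation software reports 99% as the
#' floor value, so a strict ">" would drop the boundary class). The upstream
#' 1% peptide/protein FDR of the database search is assumed to be encoded in
#' the report's probability/decoy columns and is not recomputed here.
#'
#' @param min_unique_peptides minimum unique peptides across the experiment.
#' @param min_probability minimum protein probability in `[0, 1]`.
#' @param exclude_contaminants,exclude_decoys,exclude_cdna_like enable the
#'   respective exclusion rules.
#' @param cdna_pattern case-insensitive regular expression applied to the
#'   protein description to recognize "cDNA-like" entries; the default
#'   matches the literal substring "cDNA".
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(min_unique_peptides = 2L, min_probability = 0.99,
                          exclude_contaminants = TRUE, exclude_decoys = TRUE,
                          exclude_cdna_like = TRUE, cdna_pattern = "cDNA") {
  stopifnot(min_unique_peptides >= 1, min_probability >= 0,
            min_probability <= 1)
  structure(list(min_unique_peptides = as.integer(min_unique_peptides),
                 min_probability = min_probability,
                 exclude_contaminants = isTRUE(exclude_contaminants),
                 exclude_decoys = isTRUE(exclude_decoys),
                 exclude_cdna_like = isTRUE(exclude_cdna_like),
                 cdna_pattern = cdna_pattern),
            class = "filter_policy")
}

#' Flag "cDNA-like" records by description pattern
#'
#' No formal definition of a "cDNA-like protein" exists in identification
#' reports; operationally they are recognized by their description (e.g.
#' "cDNA FLJ55673, highly similar to ..."). Sets `is_cdna_like` on matching
#' records; idempotent, never clears an existing flag.
#'
#' @param x a [count_matrix()]
#' @param pattern case-insensitive regular expression on the description.
#' @return `x` with updated `meta$is_cdna_like`
#' @export
flag_cdna_like <- function(x, pattern = "cDNA") {
  stopifnot(inherits(x, "count_matrix"))
  hit <- tryCatch(suppressWarnings(
    grepl(pattern, x$meta$description, ignore.case = TRUE, perl = TRUE)),
    error = function(e) stop("invalid cdna pattern: ",
                             conditionMessage(e)))
  x$meta$is_cdna_like <- x$meta$is_cdna_like | hit
  x
}

#' Apply identification filters to a count matrix
#'
#' Applies the enabled rules of a [filter_policy()] and returns the retained
#' matrix (record order preserved, sample totals recomputed over retained
#' records) together with a per-rule removal report. Each removed record is
#' attributed to the first rule it fails, in the fixed order contaminant,
#' decoy, cDNA-like, probability, unique peptides, so that per-rule counts
#' sum to the total number removed.
#'
#' @param x a [count_matrix()]
#' @param policy a [filter_policy()]
#' @return list with elements `matrix` (filtered [count_matrix()]) and
#'   `report` (data.frame `rule`, `n_removed`, `accessions`).
#' @export
apply_filters <- function(x, policy = filter_policy()) {
  stopifnot(inherits(x, "count_matrix"), inherits(policy, "filter_policy"))
  if (policy$exclude_cdna_like)
    x <- flag_cdna_like(x, policy$cdna_pattern)
  m <- x$meta
  fails <- list(
    contaminant = policy$exclude_contaminants & m$is_contaminant,
    decoy = policy$exclude_decoys & m$is_decoy,
    cdna_like = policy$exclude_cdna_like & m$is_cdna_like,
    probability = m$probability < policy$min_probability,
    unique_peptides = m$unique_peptides < policy$min_unique_peptides)
  assigned <- rep(NA_character_, nrow(m))
  for (rule in names(fails)) {
    idx <- which(fails[[rule]] & is.na(assigned))
    assigned[idx] <- rule
  }
  report <- data.frame(
    rule = names(fails),
    n_removed = vapply(names(fails),
                       function(r) sum(assigned == r, na.rm = TRUE), 0L),
    accessions = vapply(names(fails), function(r)
      paste(m$accession[which(assigned == r)], collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  keep <- which(is.na(assigned))
  out <- if (length(keep) == nrow(m)) x else x[keep, ]
  list(matrix = out, report = report)
}
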