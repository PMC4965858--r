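#' Gene-set over-representation analysis
#'
#' Local replacement for web-service pathway enrichment: for each gene set,
#' the upper-tail hypergeometric probability of observing at least the given
#' overlap between the query and the set, drawn from a stated universe. The
#' universe should be the genes the experiment could have detected (here:
#' all post-filter identified proteins), not the whole genome. Sets are
#' intersected with the universe; query genes outside the universe are
#' dropped with a warning. Only sets overlapping the query are reported; BH
#' q-values are computed across all reported sets.
#'
#' The p-value equals the one-sided Fisher exact p of the 2x2 table
#' (in set / not in set) x (in query / not in query).
#'
#' @param query character vector of gene symbols (deduplicated internally).
#' @param sets a `gene_sets` collection, see [read_gmt()].
#' @param universe character vector of gene symbols.
#' @return data.frame sorted by p (ties by set name) with columns
#'   `set_name`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `q_value`, `members_hit` (comma-joined).
#' @export
overrepresentation <- function(query, sets, universe) {
  universe <- unique(universe[nzchar(universe)])
  if (!length(universe)) stop("empty universe")
  query <- unique(query[nzchar(query)])
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ...")
    query <- intersect(query, universe)
    if (!length(query)) stop("no query genes left inside the universe")
  }
  U <- length(universe); Q <- length(query)
  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]]$genes, universe)
    hit <- intersect(genes, query)
    if (!length(hit)) return(NULL)
    S <- length(genes); k <- length(hit)
    p <- stats::phyper(k - 1, S, U - S, Q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = S, query_size = Q,
               universe_size = U, p_value = p,
               members_hit = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p_value = numeric(),
                      q_value = numeric(), members_hit = character(),
                      stringsAsFactors = FALSE))
  rows$q_value <- bh_adjust(rows$p_value)
  rows <- rows[order(rows$p_value, rows$set_name), ]
  rownames(rows) <- NULL
  rows[c("set_name", "overlap", "set_size", "query_size", "universe_size",
         "p_value", "q_value", "members_hit")]
}

#' Build an enrichment query from differential results
#'
#' Collects the gene symbols of selected differential records in the
#' requested direction: `"enriched"` takes positive signed folds (including
#' proteins unique to the comparison cohort), `"diminished"` negative folds
#' (including proteins unique to the reference cohort), `"both"` all
#' selected. Records with an empty gene symbol are dropped with a warning;
#' duplicates collapse to one symbol.
#'
#' @param records differential records with columns `gene`, `rsc`,
#'   `selected`.
#' @param direction `"enriched"`, `"diminished"` or `"both"`.
#' @return character vector of gene symbols.
#' @export
build_query_from_differential <- function(records,
                                          direction = c("enriched",
                                                        "diminished",
                                                        "both")) {
  direction <- match.arg(direction)
  sel <- records[isTRUE_vec(records$selected, nrow(records)), , drop = FALSE]
  sel <- switch(direction,
                enriched = sel[sel$rsc > 0, , drop = FALSE],
                diminished = sel[sel$rsc < 0, , drop = FALSE],
                both = sel)
  genes <- sel$gene
  empty <- !nzchar(trimws(genes))
  if (any(empty))
    warning(sum(empty), " selected record(s) without a gene symbol dropped")
  unique(genes[!empty])
}
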