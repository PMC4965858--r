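#' Sample-sample correlation matrix
#'
#' Pairwise correlation of per-sample protein count profiles. The default
#' transform normalizes each sample to counts-per-total, rescales by the
#' median sample total and takes `log2(x + 1)`, which makes samples of
#' different sequencing-free "depth" (total significant spectra) comparable;
#' `transform = "none"` correlates raw counts. Optionally appends one pooled
#' pseudo-sample per cohort (sum of its samples' counts), mirroring
#' "combined" columns in published correlation plots.
#'
#' @param x a [count_matrix()] with at least two samples.
#' @param method `"pearson"` or `"spearman"`.
#' @param transform `"log2cpm"` (default, see above) or `"none"`.
#' @param include_combined append per-group pooled pseudo-samples named
#'   `<group>_combined`.
#' @return symmetric correlation matrix with unit diagonal, class
#'   `correlation_matrix`.
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman"),
                               transform = c("log2cpm", "none"),
                               include_combined = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  method <- match.arg(method)
  transform <- match.arg(transform)
  counts <- x$counts
  if (include_combined) {
    for (g in x$groups) {
      pooled <- rowSums(counts[, group_samples(x, g), drop = FALSE])
      counts <- cbind(counts, pooled)
      colnames(counts)[ncol(counts)] <- paste0(g, "_combined")
    }
  }
  if (ncol(counts) < 2) stop("need at least two samples")
  mat <- if (transform == "log2cpm") {
    totals <- colSums(counts)
    if (any(totals == 0))
      stop("sample with zero total spectra: ",
           colnames(counts)[which(totals == 0)[1]])
    log2(sweep(counts, 2, totals, "/") * stats::median(totals) + 1)
  } else counts
  const <- which(apply(mat, 2, function(v) stats::sd(v) == 0))
  if (length(const))
    stop("constant sample profile(s): ",
         paste(colnames(mat)[const], collapse = ", "))
  cc <- stats::cor(mat, method = method)
  cc[cbind(1:ncol(cc), 1:ncol(cc))] <- 1
  structure(cc, class = c("correlation_matrix", class(cc)))
}

#' Agglomerative clustering of samples on correlation distance
#'
#' Hierarchical clustering on the distance `d = 1 - correlation` with
#' average, complete or single linkage. Deterministic: among equal-distance
#' candidate merges (within 1e-12), the pair whose (sorted) cluster labels —
#' the lexicographically smallest member sample id of each cluster — is
#' smallest is merged first. Returns an `hclust`-compatible structure so the
#' standard tree machinery (plotting, `ape::as.phylo`) applies.
#'
#' @param corr a [correlation_matrix()] (or any symmetric similarity matrix
#'   with unit diagonal and dimnames).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return object of classes `linkage_tree`, `hclust`.
#' @export
cluster_samples <- function(corr, linkage = c("average", "complete",
                                              "single")) {
  linkage <- match.arg(linkage)
  d <- 1 - unclass(corr)
  n <- nrow(d)
  if (is.null(rownames(d))) stop("correlation matrix needs sample names")
  if (n < 2) stop("need at least two samples to cluster")
  labels <- rownames(d)

  # active clusters: list of member indices; id: hclust convention
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)                       # negative = singleton
  tags <- labels                           # lexicographic tie-break label
  dist <- d
  diag(dist) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    k <- length(members)
    dmin <- min(dist[upper.tri(dist)])
    best <- NULL
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (dist[i, j] <= dmin + 1e-12) {
        pair <- sort(c(tags[i], tags[j]))
        if (is.null(best) || pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2]))
          best <- list(i = i, j = j, pair = pair)
      }
    }
    i <- best$i; j <- best$j
    row <- c(ids[i], ids[j])
    # hclust convention: singletons (negative) first, by ascending index;
    # prior merges ascending
    row <- row[order(row >= 0, abs(row))]
    merge[step, ] <- row
    height[step] <- dist[i, j]
    ni <- length(members[[i]]); nj <- length(members[[j]])
    newd <- vapply(seq_len(k), function(l) {
      if (l == i || l == j) return(Inf)
      switch(linkage,
             average = (ni * dist[i, l] + nj * dist[j, l]) / (ni + nj),
             complete = max(dist[i, l], dist[j, l]),
             single = min(dist[i, l], dist[j, l]))
    }, 0)
    members[[i]] <- c(members[[i]], members[[j]])
    ids[i] <- step
    tags[i] <- min(tags[i], tags[j])
    dist[i, ] <- newd; dist[, i] <- newd; dist[i, i] <- Inf
    members <- members[-j]; ids <- ids[-j]; tags <- tags[-j]
    dist <- dist[-j, -j, drop = FALSE]
  }

  ord <- tree_order(merge, n)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = linkage,
                 dist.method = "1 - correlation",
                 call = match.call()),
            class = c("linkage_tree", "hclust"))
}

tree_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1)
}

#' Serialize a linkage tree to Newick
#'
#' Converts the ultrametric tree to `ape`'s `phylo` representation (leaf
#' depth = merge height / 2) and writes Newick with branch lengths,
#' terminated by ";". Spaces in leaf names are replaced by underscores per
#' Newick convention.
#'
#' @param tree a [cluster_samples()] result (any `hclust` works).
#' @param digits significant digits for branch lengths.
#' @return single Newick string.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "hclust"))
  phy <- ape::as.phylo(tree)
  phy$tip.label <- gsub(" ", "_", phy$tip.label, fixed = TRUE)
  ape::write.tree(phy, digits = digits)
}

#' Protein detection overlap between and within cohorts
#'
#' A protein is "detected" in a sample when its count is positive. Reports,
#' per cohort, the number of proteins detected in at least one and in all of
#' its samples, and across cohorts the intersection and per-cohort-only
#' counts (detection meaning >= 1 sample of the cohort).
#'
#' @param x a [count_matrix()].
#' @return nested list: `per_group[[g]] = list(detected, in_all_samples)`,
#'   plus `intersection`, `only_ref`, `only_cmp`, `groups`.
#' @export
overlap_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  det <- lapply(x$groups, function(g) {
    sub <- x$counts[, group_samples(x, g), drop = FALSE] > 0
    list(any = rowSums(sub) > 0, all = rowSums(sub) == ncol(sub))
  })
  names(det) <- x$groups
  per_group <- lapply(det, function(d)
    list(detected = sum(d$any), in_all_samples = sum(d$all)))
  ref <- det[[x$groups[1]]]$any
  cmp <- det[[x$groups[2]]]$any
  list(per_group = per_group,
       intersection = sum(ref & cmp),
       only_ref = sum(ref & !cmp),
       only_cmp = sum(!ref & cmp),
       groups = x$groups)
}
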