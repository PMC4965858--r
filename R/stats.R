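#' Pool spectral counts by group
#'
#' Sums per-sample significant spectral counts within each of the two cohorts
#' and records, per protein, in how many samples of each cohort it was
#' detected (count > 0). Group totals `N_ref`/`N_cmp` are the sums of the
#' per-sample totals of significant spectra within each group and are
#' attached as attributes.
#'
#' @param x a [count_matrix()] with exactly two annotated groups.
#' @return data.frame with columns `accession`, `n_ref`, `n_cmp`,
#'   `present_ref`, `present_cmp`; attributes `N_ref`, `N_cmp`, `groups`.
#' @export
pool_counts <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  ref <- group_samples(x, x$groups[1])
  cmp <- group_samples(x, x$groups[2])
  if (!length(ref) || !length(cmp))
    stop("each group needs at least one sample")
  cr <- x$counts[, ref, drop = FALSE]
  cc <- x$counts[, cmp, drop = FALSE]
  out <- data.frame(accession = rownames(x$counts),
                    n_ref = as.integer(rowSums(cr)),
                    n_cmp = as.integer(rowSums(cc)),
                    present_ref = as.integer(rowSums(cr > 0)),
                    present_cmp = as.integer(rowSums(cc > 0)),
                    stringsAsFactors = FALSE)
  attr(out, "N_ref") <- sum(x$sample_totals[ref])
  attr(out, "N_cmp") <- sum(x$sample_totals[cmp])
  attr(out, "groups") <- x$groups
  out
}

#' Signed normalized spectral-count ratio (Rsc)
#'
#' The ratio of pseudocount-corrected, depth-normalized pooled spectral
#' counts between the comparison and reference cohorts,
#' \deqn{R = \frac{(n_{cmp} + f)/N_{cmp}}{(n_{ref} + f)/N_{ref}},}
#' displayed with the negative-inverse convention: when `R < 1` the signed
#' value is `-1/R`, so `|rsc| >= 1` always and a protein undetected in the
#' reference cohort still gets a finite fold thanks to the pseudocount `f`.
#' The default `f = 1.25` is the established spectral-counting correction
#' factor in the label-free quantitation lineage this statistic comes from.
#'
#' Vectorized over `n_ref`/`n_cmp`.
#'
#' @param n_ref,n_cmp pooled counts per protein in reference / comparison
#'   group.
#' @param N_ref,N_cmp positive group totals of significant spectra (only
#'   their ratio matters for `rsc`).
#' @param f pseudocount added to each pooled count, `f > 0`.
#' @return data.frame with columns `raw_ratio` (R) and `rsc` (signed).
#' @examples
#' compute_rsc(n_ref = 0, n_cmp = 21, N_ref = 1.12, N_cmp = 1)  # ~ +19.9
#' @export
compute_rsc <- function(n_ref, n_cmp, N_ref, N_cmp, f = 1.25) {
  stopifnot(f > 0, all(N_ref > 0), all(N_cmp > 0),
            all(n_ref >= 0), all(n_cmp >= 0))
  r <- ((n_cmp + f) / N_cmp) / ((n_ref + f) / N_ref)
  data.frame(raw_ratio = r, rsc = ifelse(r >= 1, r, -1 / r))
}

#' Calibrate the group-total ratio from printed worked examples
#'
#' Published spectral-counting tables print pooled counts and the signed Rsc
#' but usually not the underlying group totals. Given rows
#' `(n_ref, n_cmp, printed_rsc)`, recovers the single between-group scale
#' `r = N_ref / N_cmp` by least squares on the model
#' `|rsc| = r * (n_cmp + f)/(n_ref + f)` (positive printed values) or
#' `|rsc| = (n_ref + f) / (r * (n_cmp + f))` (negative printed values, the
#' negative-inverse convention); closed form `r = sum(x*y)/sum(x^2)` with
#' `x` the per-row count ratio and `y` the sign-consistent printed fold.
#'
#' @param n_ref,n_cmp pooled counts.
#' @param printed_rsc printed signed Rsc values.
#' @param f pseudocount, as used when the table was produced.
#' @return the calibrated ratio `r` (scalar); attribute `per_row` holds the
#'   per-row implied ratios.
#' @export
calibrate_total_ratio <- function(n_ref, n_cmp, printed_rsc, f = 1.25) {
  ok <- is.finite(n_ref) & is.finite(n_cmp) & is.finite(printed_rsc)
  if (!any(ok)) stop("no finite calibration rows")
  n_ref <- n_ref[ok]; n_cmp <- n_cmp[ok]; y <- printed_rsc[ok]
  x <- (n_cmp + f) / (n_ref + f)
  # sign-consistent response: for negative printed folds the model is
  # 1/(r x) = |y|  <=>  r x = 1/|y|
  y_pos <- ifelse(y >= 0, y, 1 / abs(y))
  r <- sum(x * y_pos) / sum(x^2)
  structure(r, per_row = y_pos / x)
}

#' Two-sided Fisher exact test on pooled spectral counts
#'
#' Exact two-sided p-value for the 2x2 table
#' `[[n_ref, N_ref - n_ref], [n_cmp, N_cmp - n_cmp]]` contrasting a protein's
#' pooled spectra against the remainder of each cohort's total. Two-sidedness
#' follows the classical minimum-likelihood (point-probability) rule: the
#' p-value sums the hypergeometric probabilities of all tables with the same
#' margins whose point probability does not exceed that of the observed table
#' (ties included, up to a 1e-7 relative guard against floating-point
#' misranking). A degenerate margin (zero row or column sum) yields p = 1.
#'
#' Vectorized over `n_ref`/`n_cmp` (and totals if supplied per element).
#'
#' @param n_ref,n_cmp pooled protein counts per group.
#' @param N_ref,N_cmp group totals, `n_ref <= N_ref`, `n_cmp <= N_cmp`.
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
fisher_count_test <- function(n_ref, N_ref, n_cmp, N_cmp) {
  n <- max(length(n_ref), length(n_cmp))
  n_ref <- rep_len(as.numeric(n_ref), n); n_cmp <- rep_len(as.numeric(n_cmp), n)
  N_ref <- rep_len(as.numeric(N_ref), n); N_cmp <- rep_len(as.numeric(N_cmp), n)
  if (any(n_ref > N_ref) || any(n_cmp > N_cmp) || any(c(n_ref, n_cmp) < 0))
    stop("need 0 <= n_ref <= N_ref and 0 <= n_cmp <= N_cmp")
  vapply(seq_len(n), function(i)
    fisher_two_sided_1(n_ref[i], N_ref[i], n_cmp[i], N_cmp[i]), 0)
}

fisher_two_sided_1 <- function(a, Nr, b, Nc) {
  # margins are rounded: calibrated group totals may be non-integer
  a <- round(a); b <- round(b); Nr <- round(Nr); Nc <- round(Nc)
  k <- a + b                      # column-1 margin (protein total)
  if (k == 0 || k == Nr + Nc || Nr == 0 || Nc == 0) return(1)
  lo <- max(0, k - Nc); hi <- min(k, Nr)
  support <- lo:hi
  ld <- stats::dhyper(support, Nr, Nc, k, log = TRUE)  # log-space: extreme
  lobs <- ld[support == a]                             # tables underflow
  keep <- ld <= lobs + log1p(1e-7)
  p <- exp(lobs + log(sum(exp(ld[keep] - lobs))))
  min(1, max(p, .Machine$double.xmin))   # keep p in (0, 1] under underflow
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical FDR step-up: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' original input order. Inputs must lie in `(0, 1]`.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return adjusted q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(p[o] * m / (m:1)))
  q
}

#' Differential selection policy
#'
#' Defaults encode the stringent selection used for spectral-count
#' differential calls: raw Fisher p below `alpha = 0.05` and an absolute
#' signed fold strictly above `min_fold = 2`. The BH-adjusted q-value is
#' always reported alongside; set `use_adjusted = TRUE` to gate on q instead
#' of p.
#'
#' @param alpha significance level.
#' @param min_fold strict threshold on `|rsc|`.
#' @param use_adjusted compare `q_value` (TRUE) or raw `p_value` (FALSE) to
#'   `alpha`.
#' @export
selection_policy <- function(alpha = 0.05, min_fold = 2, use_adjusted = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, min_fold > 0)
  structure(list(alpha = alpha, min_fold = min_fold,
                 use_adjusted = isTRUE(use_adjusted)),
            class = "selection_policy")
}

#' Flag differential records under a selection policy
#'
#' @param records data.frame with columns `p_value`, `q_value`, `rsc`.
#' @param policy a [selection_policy()].
#' @return `records` with logical column `selected` set; order preserved.
#' @export
select_differential <- function(records, policy = selection_policy()) {
  stopifnot(inherits(policy, "selection_policy"))
  crit_p <- if (policy$use_adjusted) records$q_value else records$p_value
  records$selected <- crit_p < policy$alpha &
    abs(records$rsc) > policy$min_fold
  records
}

#' Categorize differential records
#'
#' Labels each record by its pooled-count pattern: `unique_to_cmp`
#' (`n_ref == 0`, `n_cmp > 0`), `unique_to_ref` (`n_cmp == 0`, `n_ref > 0`),
#' `common_enriched` (both detected, `rsc > 0`) or `common_diminished` (both
#' detected, `rsc < 0`). A record with zero counts in both groups cannot be
#' categorized and is an error (such records are dropped before testing by
#' [differential_analysis()]).
#'
#' @param records data.frame with columns `n_ref`, `n_cmp`, `rsc`.
#' @return `records` with character column `category`.
#' @export
categorize <- function(records) {
  if (any(records$n_ref == 0 & records$n_cmp == 0))
    stop("record with zero pooled counts in both groups cannot be categorized")
  records$category <- ifelse(
    records$n_ref == 0, "unique_to_cmp",
    ifelse(records$n_cmp == 0, "unique_to_ref",
           ifelse(records$rsc > 0, "common_enriched", "common_diminished")))
  records
}

#' Partition summary of selected differential proteins
#'
#' The Venn-style breakdown of the selected set: cohort-unique proteins on
#' either side and common proteins split by direction. Counts always sum to
#' the number of selected records.
#'
#' @param records categorized differential records (see [categorize()]).
#' @return named integer vector with elements `unique_to_ref`,
#'   `unique_to_cmp`, `common_enriched`, `common_diminished`, `total`.
#' @export
partition_summary <- function(records) {
  sel <- records[isTRUE_vec(records$selected, nrow(records)), , drop = FALSE]
  lv <- c("unique_to_ref", "unique_to_cmp", "common_enriched",
          "common_diminished")
  counts <- table(factor(sel$category, levels = lv))
  out <- c(as.integer(counts), nrow(sel))
  names(out) <- c(lv, "total")
  out
}

isTRUE_vec <- function(x, n) {
  if (is.null(x)) rep(TRUE, n) else !is.na(x) & x
}

#' Replicate-presence breakdown
#'
#' For a set of proteins and one cohort, the fraction of proteins detected
#' (count > 0) in exactly `k` of the cohort's `m` samples, `k = 1..m`,
#' normalized over proteins detected in at least one sample. Proteins with
#' all-zero counts in the cohort are excluded from the denominator and
#' reported separately.
#'
#' @param x a [count_matrix()].
#' @param accessions proteins to tabulate (must exist in `x`).
#' @param group cohort label.
#' @return list with `fractions` (named numeric, `k = 1..m`), `n_detected`,
#'   `n_undetected`.
#' @export
presence_breakdown <- function(x, accessions, group) {
  stopifnot(inherits(x, "count_matrix"))
  idx <- match(accessions, rownames(x$counts))
  if (anyNA(idx))
    stop("unknown accession(s): ",
         paste(accessions[is.na(idx)], collapse = ", "))
  cols <- group_samples(x, group)
  if (!length(cols)) stop("unknown group: ", group)
  m <- length(cols)
  k <- rowSums(x$counts[idx, cols, drop = FALSE] > 0)
  det <- k[k > 0]
  frac <- if (length(det)) as.vector(table(factor(det, levels = 1:m))) /
    length(det) else rep(NA_real_, m)
  names(frac) <- as.character(1:m)
  list(fractions = frac, n_detected = length(det),
       n_undetected = sum(k == 0))
}

#' Full differential spectral-count analysis
#'
#' The quantitative core in one call: pools counts by cohort, drops (with a
#' message) records with zero pooled counts in both cohorts, computes the
#' signed Rsc with pseudocount `f`, the two-sided Fisher exact p against the
#' group totals, BH q-values, applies the selection policy and categorizes
#' every record.
#'
#' @param x a [count_matrix()] (normally already filtered, see
#'   [apply_filters()]).
#' @param f pseudocount (see [compute_rsc()]).
#' @param policy a [selection_policy()].
#' @param group_totals optional named override `c(ref =, cmp =)` for the
#'   group totals used in normalization and testing — for reproducing
#'   published tables whose totals are not those of the rows at hand.
#' @return data.frame of differential records (one row per retained protein,
#'   input order preserved) with columns
#'   `accession gene description n_ref n_cmp present_ref present_cmp
#'   raw_ratio rsc p_value q_value selected category`; attributes `N_ref`,
#'   `N_cmp`, `groups`, `n_dropped`.
#' @export
differential_analysis <- function(x, f = 1.25, policy = selection_policy(),
                                  group_totals = NULL) {
  pools <- pool_counts(x)
  N_ref <- attr(pools, "N_ref"); N_cmp <- attr(pools, "N_cmp")
  if (!is.null(group_totals)) {
    stopifnot(all(c("ref", "cmp") %in% names(group_totals)))
    N_ref <- group_totals[["ref"]]; N_cmp <- group_totals[["cmp"]]
  }
  drop <- pools$n_ref == 0 & pools$n_cmp == 0
  if (any(drop)) {
    message(sum(drop), " record(s) with zero counts in both groups dropped")
    pools <- pools[!drop, , drop = FALSE]
  }
  if (!nrow(pools)) stop("no records with nonzero pooled counts")
  rsc <- compute_rsc(pools$n_ref, pools$n_cmp, N_ref, N_cmp, f = f)
  p <- fisher_count_test(pools$n_ref, N_ref, pools$n_cmp, N_cmp)
  q <- bh_adjust(p)
  mi <- match(pools$accession, x$meta$accession)
  out <- data.frame(accession = pools$accession,
                    gene = x$meta$gene[mi],
                    description = x$meta$description[mi],
                    pools[c("n_ref", "n_cmp", "present_ref", "present_cmp")],
                    raw_ratio = rsc$raw_ratio, rsc = rsc$rsc,
                    p_value = p, q_value = q,
                    stringsAsFactors = FALSE)
  out <- select_differential(out, policy)
  out <- categorize(out)
  rownames(out) <- NULL
  attr(out, "N_ref") <- N_ref
  attr(out, "N_cmp") <- N_cmp
  attr(out, "groups") <- attr(pools, "groups")
  attr(out, "n_dropped") <- sum(drop)
  out
}
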