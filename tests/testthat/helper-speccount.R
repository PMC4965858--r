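# shared fixture builders and independent oracles

# count matrix from a plain matrix; 2 groups split evenly unless groups given
make_cm <- function(counts, groups = NULL, meta = NULL, reference = "CN") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("P%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  if (is.null(groups))
    groups <- rep(c("CN", "CR"), each = ncol(counts) / 2)
  ann <- data.frame(sample_id = colnames(counts), group = groups)
  count_matrix(counts, ann, meta = meta, reference = reference)
}

# exhaustive two-sided Fisher oracle: enumerate every table with the observed
# margins, point probability from binomial coefficients (not dhyper)
fisher_enum_oracle <- function(a, Nr, b, Nc) {
  k <- a + b
  if (k == 0 || Nr == 0 || Nc == 0 || k == Nr + Nc) return(1)
  xs <- max(0, k - Nc):min(k, Nr)
  pr <- vapply(xs, function(x)
    choose(Nr, x) * choose(Nc, k - x) / choose(Nr + Nc, k), 0)
  obs <- pr[xs == a]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# naive quadratic BH step-up: q_i = min_{p_j >= p_i} p_j * m / rank(p_j)
bh_naive_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(ranked[i:m] * m / (i:m))), 0)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# minimal differential-record frame for selection/categorization tests
make_records <- function(n_ref, n_cmp, rsc, p = 0.01, selected = TRUE) {
  n <- max(length(n_ref), length(n_cmp), length(rsc))
  data.frame(accession = sprintf("A%04d", seq_len(n)),
             gene = sprintf("G%04d", seq_len(n)),
             description = rep_len("", n),
             n_ref = rep_len(n_ref, n), n_cmp = rep_len(n_cmp, n),
             present_ref = rep(NA_integer_, n),
             present_cmp = rep(NA_integer_, n),
             raw_ratio = rep_len(abs(rsc), n), rsc = rep_len(rsc, n),
             p_value = rep_len(p, n), q_value = rep_len(p, n),
             selected = rep_len(selected, n),
             stringsAsFactors = FALSE)
}

quiet_diff <- function(...) suppressMessages(differential_analysis(...))
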