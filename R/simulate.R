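#' Configuration for the synthetic report generator
#'
#' The generator emulates the statistical structure of a two-cohort
#' label-free spectral-counting experiment: overdispersed non-negative
#' integer counts (gamma-Poisson, i.e. negative binomial), a log-normal
#' protein abundance distribution, per-sample depth differing between
#' cohorts, a subset of proteins detected in only one cohort, per-sample
#' dropout producing proteins seen in 1..m of m replicates, and injected
#' contaminant / decoy / "cDNA-like" nuisance rows carrying the description
#' substrings the default filters detect.
#'
#' Defaults mirror a published two-cohort ascites-proteome experiment:
#' 4 + 4 samples, ~3,000 proteins, a reference/comparison total-spectra
#' ratio of 1.12, and cohort-unique fractions of 7.5% / 6.5%.
#'
#' @param n_proteins number of real (non-nuisance) proteins.
#' @param samples_per_group replicates per cohort.
#' @param mean_depth expected total significant spectra per comparison-group
#'   sample; reference samples get `mean_depth * depth_ratio`.
#' @param depth_ratio reference/comparison expected-depth ratio.
#' @param dispersion negative-binomial size parameter (gamma shape); larger
#'   means less overdispersed. The default 8 corresponds to a replicate
#'   coefficient of variation of roughly 35% at moderate counts.
#' @param frac_de fraction of proteins with a planted two-cohort effect.
#' @param fold_range length-2 interval of planted fold changes (>= 1);
#'   direction is random.
#' @param frac_unique_ref,frac_unique_cmp fractions of proteins with zero
#'   rate in the other cohort.
#' @param abundance_sdlog log-normal standard deviation of the relative
#'   protein abundance distribution; 0 gives a homogeneous proteome where
#'   every protein shares the same expected count.
#' @param dropout per-cell probability of zeroing a detected count.
#' @param n_contaminants,n_decoys,n_cdna_like injected nuisance rows.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @export
synthetic_config <- function(n_proteins = 3000, samples_per_group = 4,
                             mean_depth = 20000, depth_ratio = 1.12,
                             dispersion = 8, frac_de = 0.05,
                             fold_range = c(2, 8),
                             frac_unique_ref = 0.075,
                             frac_unique_cmp = 0.065,
                             abundance_sdlog = 1.5,
                             dropout = 0.1, n_contaminants = 20,
                             n_decoys = 20, n_cdna_like = 30, seed = 1) {
  stopifnot(n_proteins >= 0, samples_per_group >= 1, mean_depth > 0,
            depth_ratio > 0, dispersion > 0,
            length(fold_range) == 2, all(fold_range >= 1),
            fold_range[1] <= fold_range[2],
            abundance_sdlog >= 0, dropout >= 0, dropout < 1)
  fr <- c(frac_de, frac_unique_ref, frac_unique_cmp)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stop("frac_de + frac_unique_ref + frac_unique_cmp must lie in [0, 1]")
  structure(as.list(environment())[c(
    "n_proteins", "samples_per_group", "mean_depth", "depth_ratio",
    "dispersion", "frac_de", "fold_range", "frac_unique_ref",
    "frac_unique_cmp", "abundance_sdlog", "dropout", "n_contaminants",
    "n_decoys", "n_cdna_like", "seed")], class = "synthetic_config")
}

#' Generate a synthetic protein report with ground truth
#'
#' Draws a two-cohort spectral-count experiment under a [synthetic_config()].
#' Per protein `i` and sample `j`,
#' `count_ij ~ NB(mu = w_i * depth_j * e_ij, size = dispersion)` where `w`
#' are normalized log-normal abundances, `depth_j` the cohort's expected
#' depth, and `e_ij` the planted effect (fold in the comparison cohort for
#' differential proteins; zero in the other cohort for cohort-unique
#' proteins); dropout then zeroes cells independently. Nuisance rows get
#' moderate counts in both cohorts and the flags / description substrings
#' the default [filter_policy()] removes. The caller's RNG state is
#' preserved.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `matrix` (a [count_matrix()], reference group
#'   "CN"), `truth` (data.frame `accession`, `category` in
#'   `null|de_up|de_down|unique_ref|unique_cmp|nuisance`, `true_fold`,
#'   `nuisance`), and `config`.
#' @export
simulate_counts <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_proteins
  m <- config$samples_per_group
  samples <- c(paste0("CN", seq_len(m)), paste0("CR", seq_len(m)))
  ann <- data.frame(sample_id = samples,
                    group = rep(c("CN", "CR"), each = m))
  is_ref <- ann$group == "CN"
  depth <- ifelse(is_ref, config$mean_depth * config$depth_ratio,
                  config$mean_depth)

  category <- character(0); fold <- numeric(0)
  counts <- matrix(0L, 0, 2 * m)
  if (n > 0) {
    w <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
    w <- w / sum(w)
    n_de <- round(config$frac_de * n)
    n_ur <- round(config$frac_unique_ref * n)
    n_uc <- round(config$frac_unique_cmp * n)
    category <- rep("null", n)
    shuffle <- sample.int(n)
    category[shuffle[seq_len(n_de)]] <- "de"
    category[shuffle[n_de + seq_len(n_ur)]] <- "unique_ref"
    category[shuffle[n_de + n_ur + seq_len(n_uc)]] <- "unique_cmp"
    fold <- rep(1, n)
    de <- which(category == "de")
    f_mag <- stats::runif(length(de), config$fold_range[1],
                          config$fold_range[2])
    up <- stats::runif(length(de)) < 0.5
    category[de] <- ifelse(up, "de_up", "de_down")
    fold[de] <- ifelse(up, f_mag, 1 / f_mag)

    effect <- matrix(1, n, 2 * m)
    effect[, !is_ref] <- fold                 # fold applies to comparison
    effect[category == "unique_ref", !is_ref] <- 0
    effect[category == "unique_cmp", is_ref] <- 0
    mu <- (w %o% depth) * effect
    counts <- matrix(stats::rnbinom(n * 2 * m, mu = mu,
                                    size = config$dispersion),
                     n, 2 * m)
    if (config$dropout > 0)
      counts[stats::runif(length(counts)) < config$dropout] <- 0L
  }
  acc <- sprintf("SP%05d", seq_len(n))
  gene <- sprintf("GENE%04d", seq_len(n))
  desc <- sprintf("Synthetic protein %d", seq_len(n))
  up_pep <- 2L + stats::rpois(n, 1)
  prob <- 0.99 + 0.01 * stats::runif(n)
  contam <- decoy <- logical(n)

  add_nuisance <- function(k, prefix, descs, is_cont, is_dec) {
    if (k == 0) return()
    cn <- matrix(stats::rnbinom(k * 2 * m, mu = 6,
                                size = config$dispersion), k, 2 * m)
    counts <<- rbind(counts, cn)
    acc <<- c(acc, sprintf("%s%03d", prefix, seq_len(k)))
    gene <<- c(gene, rep("", k))
    desc <<- c(desc, descs)
    up_pep <<- c(up_pep, 1L + stats::rpois(k, 1))
    prob <<- c(prob, stats::runif(k, 0.5, 1))
    contam <<- c(contam, rep(is_cont, k))
    decoy <<- c(decoy, rep(is_dec, k))
    category <<- c(category, rep("nuisance", k))
    fold <<- c(fold, rep(NA_real_, k))
  }
  add_nuisance(config$n_contaminants, "CONT",
               sprintf("Keratin, type II cytoskeletal %d (common contaminant)",
                       seq_len(config$n_contaminants)), TRUE, FALSE)
  add_nuisance(config$n_decoys, "REV",
               sprintf("Reverse sequence decoy %d",
                       seq_len(config$n_decoys)), FALSE, TRUE)
  add_nuisance(config$n_cdna_like, "CDNA",
               sprintf("cDNA FLJ%05d, highly similar to synthetic protein",
                       seq_len(config$n_cdna_like)), FALSE, FALSE)

  rownames(counts) <- acc
  colnames(counts) <- samples
  meta <- data.frame(accession = acc, gene = gene, description = desc,
                     unique_peptides = up_pep, probability = prob,
                     is_contaminant = contam, is_decoy = decoy,
                     is_cdna_like = logical(length(acc)),
                     stringsAsFactors = FALSE)
  truth <- data.frame(accession = acc, category = category,
                      true_fold = fold, nuisance = category == "nuisance",
                      stringsAsFactors = FALSE)
  list(matrix = count_matrix(counts, ann, meta = meta, reference = "CN"),
       truth = truth, config = config)
}

#' Write a simulated experiment to disk
#'
#' Emits the same TSV dialect [read_protein_report()] reads, plus the
#' annotation, the ground-truth table and the generating config (JSON).
#' Byte-identical for identical configs.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory (created if needed).
#' @return named character vector of the four paths.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(dir, "report.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_protein_report(sim$matrix, paths["report"])
  write_annotation(sim$matrix$annotation, paths["annotation"])
  write_tsv(sim$truth, paths["truth"])
  jsonlite::write_json(unclass(sim$config), paths["config"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}

#' Recovery metrics against planted ground truth
#'
#' Compares a differential-analysis result with the generator's truth over
#' non-nuisance rows. Planted positives are the `de_up`, `de_down`,
#' `unique_ref` and `unique_cmp` categories. Truth rows absent from the
#' results (e.g. dropped for zero counts in both cohorts) count as not
#' selected.
#'
#' @param truth truth table from [simulate_counts()].
#' @param results differential records (see [differential_analysis()]).
#' @return list: `sensitivity` (selected fraction of planted positives),
#'   `fdp` (planted-null fraction of the selected set), `sign_agreement`
#'   (fraction of selected planted positives whose `rsc` sign matches the
#'   planted direction; `NA` if none), `null_selection_rate` (selected
#'   fraction of planted nulls), `n_selected`.
#' @export
recovery_report <- function(truth, results) {
  unknown <- setdiff(results$accession, truth$accession)
  if (length(unknown))
    stop("results contain accession(s) not in truth: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  tr <- truth[!truth$nuisance, , drop = FALSE]
  i <- match(tr$accession, results$accession)
  selected <- ifelse(is.na(i), FALSE, results$selected[i])
  rsc <- ifelse(is.na(i), NA_real_, results$rsc[i])
  pos <- tr$category %in% c("de_up", "de_down", "unique_ref", "unique_cmp")
  null <- tr$category == "null"
  up <- tr$category %in% c("de_up", "unique_cmp")   # enriched in comparison
  tp <- selected & pos
  sign_ok <- ifelse(up, rsc > 0, rsc < 0)
  list(sensitivity = if (any(pos)) mean(selected[pos]) else NA_real_,
       fdp = if (any(selected)) sum(selected & null) / sum(selected) else 0,
       sign_agreement = if (any(tp)) mean(sign_ok[tp]) else NA_real_,
       null_selection_rate = if (any(null)) mean(selected[null]) else NA_real_,
       n_selected = sum(selected))
}
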