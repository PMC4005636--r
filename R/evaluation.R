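PREDICTION_CATEGORIES <- c("TP", "WP", "FN", "FP", "TN")

#' Categorize predictions against ground truth at one rank
#'
#' * known truth, prediction matches — `TP` (true prediction)
#' * known truth, prediction differs — `WP` (wrong prediction)
#' * known truth, predicted unknown — `FN` (false negative)
#' * unknown truth, predicted a taxon — `FP` (false positive)
#' * unknown truth, predicted unknown — `TN` (true negative)
#'
#' @param truth_taxon character vector of true taxa at the rank.
#' @param truth_known logical: is the true taxon represented in the reference
#'   database at this rank?
#' @param predicted character vector of predicted taxa; `NA` means the
#'   classifier called the query unknown at this rank.
#' @return factor vector over `c("TP","WP","FN","FP","TN")`.
#' @export
categorize <- function(truth_taxon, truth_known, predicted) {
  stopifnot(length(truth_taxon) == length(truth_known),
            length(truth_taxon) == length(predicted))
  out <- data.table::fcase(
    truth_known & !is.na(predicted) & predicted == truth_taxon, "TP",
    truth_known & !is.na(predicted), "WP",
    truth_known & is.na(predicted), "FN",
    !truth_known & !is.na(predicted), "FP",
    default = "TN")
  factor(out, levels = PREDICTION_CATEGORIES)
}

#' Sensitivity and specificity of a set of prediction outcomes
#'
#' Sensitivity is the normalized portion of sequences from known taxa correctly
#' assigned as known plus sequences from unknown taxa correctly assigned as
#' unknown; specificity is the portion of sequences from known taxa predicted
#' as the correct taxon. The default `"macro"` mode averages per-taxon rates
#' over taxa (grouping by the true taxon), the `"micro"` mode pools counts.
#'
#' @param outcomes table with `truth_taxon`, `category` (from [categorize()]).
#' @param mode `"macro"` (default) or `"micro"`.
#' @return list with `sn` and `sp`, both in `[0,1]` (`NaN` when undefined).
#' @export
sensitivity_specificity <- function(outcomes, mode = c("macro", "micro")) {
  mode <- match.arg(mode)
  oc <- data.table::as.data.table(outcomes)
  stopifnot(nrow(oc) >= 1L)
  oc[, category := as.character(category)]
  # correct calls for Sn: right taxon for known queries, "unknown" for unknown
  oc[, ok_sn := category %in% c("TP", "TN")]
  oc[, is_known := category %in% c("TP", "WP", "FN")]
  oc[, ok_sp := category == "TP"]
  if (mode == "micro") {
    sn <- mean(oc$ok_sn)
    sp <- if (any(oc$is_known)) mean(oc$ok_sp[oc$is_known]) else NaN
    return(list(sn = sn, sp = sp))
  }
  per_taxon <- oc[, .(sn = mean(ok_sn),
                      sp = if (any(is_known)) mean(ok_sp[is_known]) else NA_real_),
                  by = truth_taxon]
  list(sn = mean(per_taxon$sn),
       sp = mean(per_taxon$sp, na.rm = TRUE))
}

#' Grid-search specification for the weight vector
#'
#' @param grid candidate `w_d` values, ascending, all in (0,1); default
#'   `0.05, 0.10, ..., 0.95`.
#' @param n_replicates random subsamples per grid value (default 10).
#' @param sample_fraction fraction of the benchmark sampled per replicate
#'   (default 0.10).
#' @param seed RNG seed.
#' @return an object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(grid = seq(0.05, 0.95, by = 0.05),
                             n_replicates = 10L, sample_fraction = 0.10,
                             seed = 1L) {
  stopifnot(all(grid > 0), all(grid < 1), !is.unsorted(grid),
            n_replicates >= 1L, sample_fraction > 0, sample_fraction <= 1)
  structure(list(grid = grid, n_replicates = as.integer(n_replicates),
                 sample_fraction = sample_fraction, seed = as.integer(seed)),
            class = "grid_search_spec")
}

#' Optimize w_d by grid search
#'
#' For each grid value, classifies `n_replicates` random subsamples of the
#' benchmark and records the mean accuracy, `(TP + TN) / total` at
#' `accuracy_rank` (species by default — the finest rank). Ties on accuracy go
#' to the grid value closest to 0.5, then the smaller one.
#'
#' @param spec a [grid_search_spec()].
#' @param truth benchmark truth table: `query_id`, `truth_taxon`, `known`
#'   (logical) at `accuracy_rank`.
#' @param classify_fn `function(w_d, query_ids)` returning a table with
#'   `query_id` and `predicted` (`NA` = unknown) for those queries.
#' @param accuracy_rank rank label, documentation only (default `"species"`).
#' @return list: `best_wd`, `accuracy` table (`w_d`, `mean_accuracy`, `sd`).
#' @export
grid_search_wd <- function(spec, truth, classify_fn, accuracy_rank = "species") {
  tr <- data.table::as.data.table(truth)
  stopifnot(all(c("query_id", "truth_taxon", "known") %in% names(tr)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n_sub <- max(1L, round(nrow(tr) * spec$sample_fraction))
  subsamples <- lapply(seq_len(spec$n_replicates),
                       function(.) tr[sample.int(nrow(tr), n_sub)])
  rows <- lapply(spec$grid, function(wd) {
    accs <- vapply(subsamples, function(sub) {
      pred <- data.table::as.data.table(classify_fn(wd, sub$query_id))
      m <- merge(sub, pred, by = "query_id", all.x = TRUE)
      cat_ <- categorize(m$truth_taxon, m$known, m$predicted)
      mean(cat_ %in% c("TP", "TN"))
    }, numeric(1))
    data.table::data.table(w_d = wd, mean_accuracy = mean(accs), sd = sd(accs))
  })
  tab <- data.table::rbindlist(rows)
  best <- tab$mean_accuracy
  cand <- which(abs(best - max(best)) < 1e-12)
  # tie rule: closest to 0.5, then smaller
  cand <- cand[order(abs(tab$w_d[cand] - 0.5), tab$w_d[cand])]
  list(best_wd = tab$w_d[cand[1L]], accuracy = tab[], rank = accuracy_rank)
}

#' Build novelty-stratified benchmark splits
#'
#' For each requested novelty fraction, holds out that fraction of genomes
#' (rounded) so that query fragments from held-out genomes are "unknown" to
#' the retained reference set. Realized novelty must land within `tol` of the
#' request.
#'
#' @param genome_ids all available genome ids.
#' @param novelty_levels fractions in `[0, 1)` of genomes to hold out.
#' @param seed RNG seed for the random hold-out draw.
#' @param tol maximum |realized - requested| novelty (default 0.02).
#' @return list, one element per level: `novelty_requested`,
#'   `novelty_realized`, `held_out`, `reference` genome-id vectors.
#' @export
novelty_stratified_benchmark <- function(genome_ids, novelty_levels, seed = 1L,
                                         tol = 0.02) {
  n <- length(genome_ids)
  stopifnot(n >= 2L, all(novelty_levels >= 0), all(novelty_levels < 1))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(novelty_levels, function(f) {
    k <- round(n * f)
    if (k >= n)
      stop("infeasible novelty fraction ", f, ": at most ",
           (n - 1) / n, " achievable with ", n, " genomes")
    realized <- k / n
    if (abs(realized - f) > tol)
      stop("requested novelty ", f, " not realizable within ", tol,
           " with ", n, " genomes (closest: ", realized, ")")
    held <- sort(sample(genome_ids, k))
    list(novelty_requested = f, novelty_realized = realized,
         held_out = held, reference = setdiff(genome_ids, held))
  })
}
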