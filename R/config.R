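#' Ortholog-candidate filtering thresholds
#'
#' Thresholds applied to all-vs-all protein matches before reciprocal-best-match
#' detection: percent amino acid identity strictly above `min_identity`,
#' alignment coverage of the shorter gene at least `min_coverage`, and e-value
#' strictly below `max_evalue`.
#'
#' @param min_identity percent identity lower bound (exclusive). Default 40.
#' @param min_coverage minimum fraction of the shorter gene covered by the
#'   alignment (inclusive). Default 0.7.
#' @param max_evalue e-value upper bound (exclusive). Default 1e-12.
#' @return an object of class `ortholog_thresholds`.
#' @export
ortholog_thresholds <- function(min_identity = 40, min_coverage = 0.7,
                                max_evalue = 1e-12) {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1, max_evalue > 0)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 max_evalue = max_evalue),
            class = "ortholog_thresholds")
}

#' AAI rank bands for novelty calls
#'
#' Genome pairs of the same species typically share >=95% AAI (a cutoff chosen
#' to represent recently described, homogeneous species), same-genus pairs
#' 60-80%, and pairs sharing only a phylum-level lineage fall below 45%.
#' Queries whose best-match AAI lands between these bands are called novel at
#' the corresponding rank.
#'
#' @param species_min AAI at or above which a match is a known species (95).
#' @param genus_low lower edge of the genus band (60).
#' @param genus_high upper edge of the printed genus band (80); retained for
#'   reporting, the novelty call treats all of `[genus_low, species_min)` as a
#'   novel species of the matched genus.
#' @param phylum_max AAI below which a query is a novel phylum-level lineage (45).
#' @return an object of class `rank_bands`.
#' @export
rank_bands <- function(species_min = 95, genus_low = 60, genus_high = 80,
                       phylum_max = 45) {
  stopifnot(phylum_max < genus_low, genus_low <= genus_high,
            genus_high < species_min, species_min <= 100, phylum_max > 0)
  structure(list(species_min = species_min, genus_low = genus_low,
                 genus_high = genus_high, phylum_max = phylum_max),
            class = "rank_bands")
}

#' Linear combination weights for D and M
#'
#' The per-match weight is the convex combination `w_d * D + w_m * M`;
#' `w_d + w_m` must equal 1, so only `w_d` is free (the grid-search optimizer
#' tunes it).
#'
#' @param w_d weight on the discriminative component D, in `[0,1]`.
#' @return an object of class `combined_weight_config` with fields `w_d`, `w_m`.
#' @export
combined_weight_config <- function(w_d = 0.5) {
  stopifnot(is.numeric(w_d), length(w_d) == 1L, w_d >= 0, w_d <= 1)
  structure(list(w_d = w_d, w_m = 1 - w_d), class = "combined_weight_config")
}

#' Online classifier configuration
#'
#' @param top_n number of top matches per query gene to use (default 5; with
#'   `top_n = 1` the classifier reduces to a weighted best-hit/LCA scheme).
#' @param score_cutoff minimum likelihood for accepting the top candidate taxon
#'   at a rank (default 0.5). Acceptance uses `>=`.
#' @param weight_cfg a [combined_weight_config()].
#' @param bands a [rank_bands()] used for novelty calls.
#' @param d_mode `"posterior"` (default) scores identity x as
#'   `f_intra(x) / (f_intra(x) + f_inter(x))`; `"difference"` uses the clamped
#'   density difference `f_intra(x) - f_inter(x)`.
#' @param parent_renorm if `TRUE`, likelihoods at genus/species are
#'   re-normalized over the accepted parent's subtree; the default keeps the
#'   global denominator so out-of-subtree matches dilute the likelihood.
#' @param exclude_genomes character vector of subject genome ids whose hits are
#'   ignored (leave-out benchmarking).
#' @param aai_summary how best-match AAI is summarized over the hits supporting
#'   the deepest accepted taxon: `"mean"` (default, robust to a single spurious
#'   hit) or `"max"`.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(top_n = 5L, score_cutoff = 0.5,
                              weight_cfg = combined_weight_config(),
                              bands = rank_bands(),
                              d_mode = c("posterior", "difference"),
                              parent_renorm = FALSE,
                              exclude_genomes = character(),
                              aai_summary = c("mean", "max")) {
  top_n <- as.integer(top_n)
  stopifnot(top_n >= 1L, score_cutoff >= 0, score_cutoff <= 1,
            inherits(weight_cfg, "combined_weight_config"),
            inherits(bands, "rank_bands"))
  structure(list(top_n = top_n, score_cutoff = score_cutoff,
                 weight_cfg = weight_cfg, bands = bands,
                 d_mode = match.arg(d_mode), parent_renorm = isTRUE(parent_renorm),
                 exclude_genomes = as.character(exclude_genomes),
                 aai_summary = match.arg(aai_summary)),
            class = "classifier_config")
}

# The three ranks the classifier descends, in order.
CLASSIFY_RANKS <- c("phylum", "genus", "species")
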