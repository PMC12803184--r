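#' Pipeline configuration
#'
#' Collects every tunable constant of the acetylome analysis pipeline in one
#' validated list. Defaults encode the standard multi-tissue acetylome
#' workflow:
#' site localization probability strictly greater than 0.75, protein- and
#' precursor-level q-values at or below 0.01, detection in at least two
#' replicates of one tissue in one sex, Perseus-style imputation with a 1.8
#' log2-unit downshift and 0.3 width multiplier, Euclidean/average-linkage
#' clustering cut into 400 groups, Fisher over-representation at alpha 0.05,
#' and the variance-based ontology term selection thresholds (across-tissue
#' sd > 0.6, some tissue below 0.6 and some above 3.0 on the -log10 p scale,
#' >90\% overlap pruning).
#'
#' @param site_prob_min Minimum site localization probability; sites are kept
#'   only when strictly greater than this value. Default 0.75.
#' @param qvalue_max Maximum PG and EG q-value (inclusive). Default 0.01.
#' @param min_replicates Replicates within one tissue-sex group required to
#'   call a site detected. Default 2.
#' @param impute_downshift Downshift of the imputation distribution in units
#'   of the feature's observed standard deviation. Default 1.8.
#' @param impute_width Width multiplier for the imputation distribution.
#'   Default 0.3.
#' @param cluster_metric Distance metric for site clustering ("euclidean").
#' @param cluster_linkage Agglomeration method ("average").
#' @param n_cut_groups Number of groups the site dendrogram is cut into.
#'   Default 400.
#' @param ora_alpha Significance cutoff for Fisher over-representation.
#'   Default 0.05.
#' @param term_sd_min Minimum across-tissue standard deviation of -log10 p
#'   for a term to be retained (strict). Default 0.6.
#' @param term_low_max A retained term must have some tissue with -log10 p
#'   strictly below this. Default 0.6.
#' @param term_high_min A retained term must have some tissue with -log10 p
#'   strictly above this. Default 3.0.
#' @param overlap_max Pairwise annotation overlap above which (strictly) one
#'   of two terms is pruned. Default 0.9.
#' @param sd_convention "sample" (n-1 denominator) or "population" (n) for the
#'   across-tissue sd used in term selection. Default "sample".
#' @param flank_radius Residues on each side of the modified lysine in a
#'   flanking window. Default 7 (15-mers).
#' @param sasa_probe_radius Solvent probe radius in Angstrom. Default 1.4.
#' @param sasa_n_points Sphere sample points per atom for Shrake-Rupley.
#'   Default 100.
#' @param sasa_include_hydrogens Include hydrogen atoms when present.
#'   Default TRUE.
#' @param sasa_include_hetatm Include HETATM records. Default FALSE.
#' @param n_rank_bins Equal-count abundance-rank bins for variant fold
#'   enrichment. Default 10 (deciles).
#' @param top_k_unique Number of uniquely enriched terms reported per tissue.
#'   Default 10.
#' @param ora_alternative Sidedness of the Fisher tests: "greater" (default,
#'   over-representation) or "two.sided".
#' @param normalize_target "tissue" aligns each run to its tissue's pooled
#'   median (default); "global" aligns all runs to the matrix-wide median.
#' @param enrichment_universe "proteome" (default) tests each tissue's acetyl
#'   proteins against the full detected proteome; "acetyl" restricts the
#'   universe to the union of acetyl proteins.
#' @param rng_seed Integer seed driving every stochastic step. Default 1.
#' @param column_map Named character vector translating the canonical site
#'   report column names to the dialect found in the input file. Names are
#'   the canonical columns, values the file's headers.
#'
#' @return A validated list of class `"atlas_config"`.
#' @examples
#' cfg <- atlas_config(rng_seed = 7)
#' cfg$site_prob_min
#' @export
atlas_config <- function(site_prob_min = 0.75,
                         qvalue_max = 0.01,
                         min_replicates = 2L,
                         impute_downshift = 1.8,
                         impute_width = 0.3,
                         cluster_metric = "euclidean",
                         cluster_linkage = "average",
                         n_cut_groups = 400L,
                         ora_alpha = 0.05,
                         term_sd_min = 0.6,
                         term_low_max = 0.6,
                         term_high_min = 3.0,
                         overlap_max = 0.9,
                         sd_convention = c("sample", "population"),
                         flank_radius = 7L,
                         sasa_probe_radius = 1.4,
                         sasa_n_points = 100L,
                         sasa_include_hydrogens = TRUE,
                         sasa_include_hetatm = FALSE,
                         n_rank_bins = 10L,
                         top_k_unique = 10L,
                         ora_alternative = c("greater", "two.sided"),
                         normalize_target = c("tissue", "global"),
                         enrichment_universe = c("proteome", "acetyl"),
                         rng_seed = 1L,
                         column_map = NULL) {
  cfg <- list(
    site_prob_min = site_prob_min,
    qvalue_max = qvalue_max,
    min_replicates = as.integer(min_replicates),
    impute_downshift = impute_downshift,
    impute_width = impute_width,
    cluster_metric = cluster_metric,
    cluster_linkage = cluster_linkage,
    n_cut_groups = as.integer(n_cut_groups),
    ora_alpha = ora_alpha,
    term_sd_min = term_sd_min,
    term_low_max = term_low_max,
    term_high_min = term_high_min,
    overlap_max = overlap_max,
    sd_convention = match.arg(sd_convention),
    flank_radius = as.integer(flank_radius),
    sasa_probe_radius = sasa_probe_radius,
    sasa_n_points = as.integer(sasa_n_points),
    sasa_include_hydrogens = isTRUE(sasa_include_hydrogens),
    sasa_include_hetatm = isTRUE(sasa_include_hetatm),
    n_rank_bins = as.integer(n_rank_bins),
    top_k_unique = as.integer(top_k_unique),
    ora_alternative = match.arg(ora_alternative),
    normalize_target = match.arg(normalize_target),
    enrichment_universe = match.arg(enrichment_universe),
    rng_seed = as.integer(rng_seed),
    column_map = column_map
  )
  validate_atlas_config(cfg)
  class(cfg) <- "atlas_config"
  cfg
}

validate_atlas_config <- function(cfg) {
  frac <- c("site_prob_min", "qvalue_max", "ora_alpha", "overlap_max")
  for (f in frac) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("config field '%s' must be a fraction in [0, 1]", f))
  }
  counts <- c("min_replicates", "n_cut_groups", "flank_radius",
              "sasa_n_points", "n_rank_bins", "top_k_unique")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop(sprintf("config field '%s' must be a positive count", f))
  }
  if (cfg$sasa_probe_radius <= 0)
    stop("config field 'sasa_probe_radius' must be > 0")
  if (cfg$impute_width <= 0)
    stop("config field 'impute_width' must be > 0")
  invisible(cfg)
}

#' @export
print.atlas_config <- function(x, ...) {
  cat("Acetylome pipeline configuration\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  flat <- flat[names(flat) != "column_map"]
  for (nm in names(flat))
    cat(sprintf("  %-24s %s\n", nm, format(flat[[nm]])))
  if (!is.null(x$column_map))
    cat(sprintf("  column_map remaps %d columns\n", length(x$column_map)))
  invisible(x)
}
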