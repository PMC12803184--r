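#' Normalize free-text clinical significance labels
#'
#' @param x Character vector of clinical annotations.
#' @return Factor with levels pathogenic, non-pathogenic, uncertain.
#' @export
normalize_significance <- function(x) {
  lx <- tolower(trimws(x))
  out <- ifelse(lx %in% c("pathogenic", "likely pathogenic",
                          "pathogenic/likely pathogenic"), "pathogenic",
         ifelse(lx %in% c("benign", "likely benign",
                          "benign/likely benign"), "non-pathogenic",
                "uncertain"))
  factor(out, levels = c("pathogenic", "non-pathogenic", "uncertain"))
}

#' Read a mouse-to-human residue variant table
#'
#' @param path Tab-separated file with columns `mouse_protein`,
#'   `mouse_position`, `human_protein`, `human_position`, `ref_aa`,
#'   `alt_aa`, `significance`, `phenotype`.
#' @return Data frame with `significance` normalized.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  v <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mouse_protein", "mouse_position", "ref_aa", "alt_aa",
            "significance")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  v$mouse_position <- as.integer(v$mouse_position)
  v$significance <- normalize_significance(v$significance)
  v
}

#' Join acetyl sites to human residue variants
#'
#' One output row per (site, variant) pair matched on mouse protein and
#' residue position. Variants whose reference residue is not lysine at a
#' joined site are excluded with a warning (integrity check); sites with no
#' variant are counted in the `n_unmatched_sites` attribute, and variant
#' rows joining no site in `n_unmatched_variants`.
#'
#' @param sites An `acetyl_sites` object (collapsed).
#' @param variants Variant data frame from [read_variant_table()].
#' @return Data frame of joined variant records.
#' @export
join_sites_variants <- function(sites, variants) {
  stopifnot(inherits(sites, "acetyl_sites"))
  m <- sites$meta
  key_site <- paste(m$protein_id, m$position)
  key_var <- paste(variants$mouse_protein, variants$mouse_position)
  hit <- key_var %in% key_site
  joined <- variants[hit, , drop = FALSE]
  bad_ref <- joined$ref_aa != "K"
  if (any(bad_ref)) {
    warning(sum(bad_ref), " joined variant(s) with non-lysine reference ",
            "residue excluded")
    joined <- joined[!bad_ref, , drop = FALSE]
  }
  joined$collapse_key <- m$collapse_key[match(paste(joined$mouse_protein,
                                                    joined$mouse_position),
                                              key_site)]
  rownames(joined) <- NULL
  key_joined <- paste(joined$mouse_protein, joined$mouse_position)
  attr(joined, "n_unmatched_sites") <- sum(!key_site %in% key_joined)
  attr(joined, "n_unmatched_variants") <- sum(!hit)
  joined
}

#' Flag acetyl-mimic substitutions
#'
#' Lysine-to-glutamine substitutions remove the lysine's positive charge and
#' chemically approximate constitutive acetylation (mimic); lysine-to-
#' arginine preserves the charge and approximates the unmodified state
#' (non-mimic); lysine-to-glutamate reverses the charge and is classified
#' separately.
#'
#' @param joined Joined variant data frame from [join_sites_variants()].
#' @return The input with a `substitution_class` column: `mimic` (K>Q),
#'   `charge_preserving` (K>R), `charge_reversing` (K>E), `other`.
#' @export
flag_acetyl_mimics <- function(joined) {
  cls <- ifelse(joined$alt_aa == "Q", "mimic",
         ifelse(joined$alt_aa == "R", "charge_preserving",
         ifelse(joined$alt_aa == "E", "charge_reversing", "other")))
  joined$substitution_class <- factor(cls, levels = c("mimic",
                                                      "charge_preserving",
                                                      "charge_reversing",
                                                      "other"))
  joined
}

#' Fold enrichment of pathogenic variants across abundance ranks
#'
#' Ranks sites by mean abundance (mean of detected log2 values across runs;
#' imputed draws are never measurements and are excluded), splits them into
#' `cfg$n_rank_bins` equal-count bins from low to high abundance, and
#' reports per bin the ratio of the bin's pathogenic-site fraction to the
#' overall pathogenic fraction. The site-count-weighted mean of the folds is
#' exactly 1.
#'
#' @param site_abundance Named numeric vector: collapse key -> mean detected
#'   log2 abundance.
#' @param pathogenic_keys Collapse keys of sites carrying at least one
#'   pathogenic variant.
#' @param cfg An [atlas_config()].
#' @return A `fold_curve` data frame: `bin`, `n_sites`, `n_pathogenic`,
#'   `fold` (low-abundance bin first).
#' @export
abundance_rank_enrichment <- function(site_abundance, pathogenic_keys,
                                      cfg = atlas_config()) {
  n <- length(site_abundance)
  k <- cfg$n_rank_bins
  if (k < 2) stop("n_rank_bins must be at least 2")
  if (k > n) stop("more bins than sites")
  ord <- order(site_abundance, names(site_abundance))  # deterministic ties
  bin <- rep(seq_len(k), times = diff(round(seq(0, n, length.out = k + 1))))
  is_path <- names(site_abundance)[ord] %in% pathogenic_keys
  n_sites <- tabulate(bin, k)
  n_path <- vapply(seq_len(k), function(b) sum(is_path[bin == b]), integer(1))
  overall <- sum(n_path) / n
  fold <- if (overall > 0) (n_path / n_sites) / overall else rep(NA_real_, k)
  out <- data.frame(bin = seq_len(k), n_sites = n_sites,
                    n_pathogenic = n_path, fold = fold)
  class(out) <- c("fold_curve", "data.frame")
  out
}

#' Mean detected abundance per site
#'
#' @param m A log2 `abundance_matrix` before imputation (missing cells
#'   intact).
#' @return Named numeric vector, collapse key -> mean of observed values.
#' @export
site_mean_abundance <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- m$values
  v[m$imputed_mask] <- NA_real_
  rowMeans(v, na.rm = TRUE)
}

#' @export
plot.fold_curve <- function(x, ...) {
  graphics::barplot(x$fold, names.arg = x$bin,
                    xlab = "abundance rank bin (low to high)",
                    ylab = "pathogenic fold enrichment", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
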