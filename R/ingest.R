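# canonical site-report column names (Spectronaut PTMSiteReport dialect)
.report_columns <- c(
  protein_id       = "PG.ProteinGroups",
  gene             = "PG.Genes",
  position         = "PTM.SiteLocation",
  mod_title        = "PTM.ModificationTitle",
  site_probability = "PTM.SiteProbability",
  collapse_key     = "PTM.CollapseKey",
  flank            = "PTM.FlankingRegion",
  pg_qvalue        = "PG.Qvalue",
  eg_qvalue        = "EG.Qvalue"
)

#' Read a sample design table
#'
#' @param path Tab-separated file with columns `run_id`, `tissue`, `sex`,
#'   `replicate`, `enriched`.
#' @return A data frame, one row per run.
#' @export
read_sample_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("run_id", "tissue", "sex", "replicate", "enriched")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design table missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$run_id))
    stop("design table has duplicated run_id values")
  d$replicate <- as.integer(d$replicate)
  d$enriched <- as.logical(d$enriched)
  d
}

#' Read a PTM site report
#'
#' Parses a tab-separated site-level report (Spectronaut PTMSiteReport
#' dialect by default) into an `acetyl_sites` object: per-site metadata plus
#' a sites-by-runs intensity matrix. Quantity columns are matched to the
#' design's `run_id` values; quantity-like columns that match no run are
#' reported in the `unmatched_columns` attribute. Non-Spectronaut dialects
#' are adapted through `cfg$column_map` (canonical name -> file header).
#'
#' @param path Site report file path.
#' @param design Sample design data frame (see [read_sample_design()]).
#' @param cfg An [atlas_config()].
#' @return An object of class `acetyl_sites`: a list with `meta` (data frame
#'   of site fields), `intensities` (numeric matrix, `NA` = not quantified;
#'   zeros are kept verbatim here and treated as missing when the abundance
#'   matrix is built) and `design`.
#' @export
read_site_report <- function(path, design, cfg = atlas_config()) {
  if (!file.exists(path)) stop("site report not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  as_acetyl_sites(raw, design, cfg)
}

#' Build an `acetyl_sites` object from an in-memory report table
#'
#' Same parsing contract as [read_site_report()] for a data frame already in
#' memory (e.g. the `report` element of an [simulate_atlas()] result).
#'
#' @param raw Site report data frame (canonical or remapped column names).
#' @param design Sample design data frame.
#' @param cfg An [atlas_config()].
#' @return An `acetyl_sites` object.
#' @export
as_acetyl_sites <- function(raw, design, cfg = atlas_config()) {
  cols <- .report_columns
  if (!is.null(cfg$column_map)) {
    km <- intersect(names(cfg$column_map), names(cols))
    cols[km] <- cfg$column_map[km]
  }
  miss <- cols[!cols %in% names(raw)]
  if (length(miss))
    stop("site report missing required column(s): ", paste(miss, collapse = ", "))
  prob <- suppressWarnings(as.numeric(raw[[cols["site_probability"]]]))
  bad <- which(is.na(prob) & !is.na(raw[[cols["site_probability"]]]) &
                 nzchar(raw[[cols["site_probability"]]]))
  if (length(bad))
    stop("non-numeric site probability at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  meta <- data.frame(
    protein_id       = raw[[cols["protein_id"]]],
    gene             = raw[[cols["gene"]]],
    position         = as.integer(raw[[cols["position"]]]),
    mod_title        = raw[[cols["mod_title"]]],
    site_probability = prob,
    collapse_key     = raw[[cols["collapse_key"]]],
    flank            = raw[[cols["flank"]]],
    pg_qvalue        = as.numeric(raw[[cols["pg_qvalue"]]]),
    eg_qvalue        = as.numeric(raw[[cols["eg_qvalue"]]]),
    stringsAsFactors = FALSE
  )
  quant_cols <- setdiff(names(raw), cols)
  run_cols <- intersect(design$run_id, quant_cols)
  unmatched <- setdiff(quant_cols, design$run_id)
  inten <- matrix(NA_real_, nrow = nrow(raw), ncol = length(design$run_id),
                  dimnames = list(NULL, design$run_id))
  for (r in run_cols) {
    v <- raw[[r]]
    v[v %in% c("", "NA", "NaN", "Filtered")] <- NA
    inten[, r] <- suppressWarnings(as.numeric(v))
  }
  out <- structure(list(meta = meta, intensities = inten, design = design),
                   class = "acetyl_sites")
  attr(out, "unmatched_columns") <- unmatched
  out
}

#' @export
print.acetyl_sites <- function(x, ...) {
  cat(sprintf("acetyl_sites: %d records x %d runs (%d distinct collapse keys)\n",
              nrow(x$meta), ncol(x$intensities),
              length(unique(x$meta$collapse_key))))
  invisible(x)
}

#' Apply identification filters to site records
#'
#' Keeps records whose modification title contains the acetyl-lysine label,
#' whose site localization probability is strictly greater than
#' `cfg$site_prob_min`, and whose protein-group and precursor q-values are
#' both at or below `cfg$qvalue_max`. Counts of each rejection reason are
#' attached as the `rejections` attribute.
#'
#' @param x An `acetyl_sites` object.
#' @param cfg An [atlas_config()].
#' @param label Modification label to require; default `"Acetyl (K)"`.
#' @return Filtered `acetyl_sites`.
#' @export
filter_acetyl_sites <- function(x, cfg = atlas_config(), label = "Acetyl (K)") {
  stopifnot(inherits(x, "acetyl_sites"))
  m <- x$meta
  is_ack <- grepl(label, m$mod_title, fixed = TRUE)
  prob_ok <- !is.na(m$site_probability) & m$site_probability > cfg$site_prob_min
  q_ok <- !is.na(m$pg_qvalue) & !is.na(m$eg_qvalue) &
    m$pg_qvalue <= cfg$qvalue_max & m$eg_qvalue <= cfg$qvalue_max
  keep <- is_ack & prob_ok & q_ok
  out <- structure(list(meta = m[keep, , drop = FALSE],
                        intensities = x$intensities[keep, , drop = FALSE],
                        design = x$design),
                   class = "acetyl_sites")
  rownames(out$meta) <- NULL
  attr(out, "rejections") <- c(
    not_acetyl = sum(!is_ack),
    low_probability = sum(is_ack & !prob_ok),
    high_qvalue = sum(is_ack & prob_ok & !q_ok)
  )
  out
}

#' Collapse records to unique acetyl sites
#'
#' One record per distinct collapse key. Duplicate keys arise when several
#' precursors quantify the same site; their per-run intensities are merged by
#' taking the per-run maximum (order-independent and conservative). Metadata
#' of the first occurrence is kept; duplicates whose protein or position
#' disagree raise an integrity error.
#'
#' @param x An `acetyl_sites` object (normally already filtered).
#' @return `acetyl_sites` with one record per collapse key.
#' @export
collapse_unique_sites <- function(x) {
  stopifnot(inherits(x, "acetyl_sites"))
  key <- x$meta$collapse_key
  if (!anyDuplicated(key)) return(x)
  first <- !duplicated(key)
  idx_by_key <- split(seq_along(key), key)
  for (k in names(idx_by_key)) {
    idx <- idx_by_key[[k]]
    if (length(idx) > 1L) {
      if (length(unique(x$meta$protein_id[idx])) > 1L ||
          length(unique(x$meta$position[idx])) > 1L)
        stop("collapse key '", k, "' maps to conflicting protein/position")
    }
  }
  meta <- x$meta[first, , drop = FALSE]
  rownames(meta) <- NULL
  inten <- matrix(NA_real_, nrow = nrow(meta), ncol = ncol(x$intensities),
                  dimnames = list(NULL, colnames(x$intensities)))
  keys_first <- key[first]
  for (i in seq_along(keys_first)) {
    idx <- idx_by_key[[keys_first[i]]]
    block <- x$intensities[idx, , drop = FALSE]
    v <- suppressWarnings(apply(block, 2, max, na.rm = TRUE))
    v[!is.finite(v)] <- NA_real_
    inten[i, ] <- v
  }
  structure(list(meta = meta, intensities = inten, design = x$design),
            class = "acetyl_sites")
}
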