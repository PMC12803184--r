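#' Build the sites-by-runs abundance matrix
#'
#' Places raw intensities by run for collapsed site records. Zero intensities
#' are treated as missing: DIA reports use 0 and NA interchangeably for
#' non-quantified cells, and zeros are not valid log2 inputs.
#'
#' @param x A collapsed `acetyl_sites` object (unique collapse keys).
#' @return An `abundance_matrix`: list with `values` (raw intensities, rows
#'   named by collapse key, columns by run), `design`, `log2 = FALSE`, and an
#'   all-`FALSE` `imputed_mask`.
#' @export
build_matrix <- function(x) {
  stopifnot(inherits(x, "acetyl_sites"))
  if (anyDuplicated(x$meta$collapse_key))
    stop("records must be collapsed to unique sites first")
  vals <- x$intensities
  vals[!is.na(vals) & vals == 0] <- NA_real_
  rownames(vals) <- x$meta$collapse_key
  extra <- setdiff(colnames(vals), x$design$run_id)
  if (length(extra))
    stop("intensity runs absent from design: ", paste(extra, collapse = ", "))
  structure(list(values = vals,
                 design = x$design,
                 meta = x$meta,
                 log2 = FALSE,
                 imputed_mask = matrix(FALSE, nrow(vals), ncol(vals),
                                       dimnames = dimnames(vals))),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d sites x %d runs, %.1f%% missing, %s scale\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values)),
              if (x$log2) "log2" else "raw"))
  invisible(x)
}

# tissue-sex group labels per design row
.group_labels <- function(design) paste(design$tissue, design$sex, sep = ".")

#' Detection filter
#'
#' A site is detected in a tissue when at least `cfg$min_replicates`
#' replicates of that tissue are quantified within at least one sex. Sites
#' detected in no tissue are removed.
#'
#' @param m An `abundance_matrix`.
#' @param cfg An [atlas_config()].
#' @return List with `matrix` (rows failing the rule removed) and `detection`
#'   (`detection_pattern`: logical sites-by-tissue matrix plus
#'   `n_tissues_detected`).
#' @export
detection_filter <- function(m, cfg = atlas_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  grp <- .group_labels(m$design)
  obs <- !is.na(m$values)
  counts <- sapply(unique(grp), function(g)
    rowSums(obs[, grp == g, drop = FALSE]))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(rownames(m$values), unique(grp)))
  pass_group <- counts >= cfg$min_replicates
  tissue_of_group <- vapply(strsplit(colnames(pass_group), ".", fixed = TRUE),
                            `[`, character(1), 1L)
  tissues <- unique(m$design$tissue)
  detected <- sapply(tissues, function(t)
    rowSums(pass_group[, tissue_of_group == t, drop = FALSE]) > 0)
  if (is.null(dim(detected))) detected <- matrix(detected, nrow = 1,
                                                 dimnames = list(rownames(m$values), tissues))
  keep <- rowSums(detected) > 0
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out$imputed_mask <- m$imputed_mask[keep, , drop = FALSE]
  if (!is.null(m$meta)) out$meta <- m$meta[keep, , drop = FALSE]
  det <- structure(list(detected = detected[keep, , drop = FALSE],
                        n_tissues_detected = rowSums(detected)[keep]),
                   class = "detection_pattern")
  list(matrix = out, detection = det)
}

#' Log2-transform observed intensities
#'
#' @param m An `abundance_matrix` on the raw scale.
#' @return The matrix on the log2 scale; missing cells preserved.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (m$log2) stop("matrix is already log2-transformed")
  v <- m$values
  if (any(v <= 0, na.rm = TRUE))
    stop("nonpositive observed intensity: log2 transform undefined")
  m$values <- log2(v)
  m$log2 <- TRUE
  m
}

#' Median normalization
#'
#' Shifts each run so that its observed-value median equals its group's
#' pooled median. With `cfg$normalize_target = "tissue"` (default) the pooled
#' median is the median of all observed values across the tissue's runs (both
#' sexes); `"global"` uses the matrix-wide median. Shift-only: within-run
#' value differences are preserved.
#'
#' @param m A log2-scale `abundance_matrix`.
#' @param cfg An [atlas_config()].
#' @return Normalized matrix; per-run shifts in the `shifts` attribute.
#' @export
median_normalize <- function(m, cfg = atlas_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!m$log2) stop("median normalization expects log2 scale")
  v <- m$values
  shifts <- setNames(numeric(ncol(v)), colnames(v))
  if (cfg$normalize_target == "global") {
    pooled <- rep(median(v, na.rm = TRUE), ncol(v))
  } else {
    tiss <- m$design$tissue[match(colnames(v), m$design$run_id)]
    pooled <- vapply(tiss, function(t)
      median(v[, m$design$run_id[m$design$tissue == t], drop = FALSE],
             na.rm = TRUE), numeric(1))
  }
  for (j in seq_len(ncol(v))) {
    run_med <- median(v[, j], na.rm = TRUE)
    if (is.na(run_med)) {
      warning("run '", colnames(v)[j], "' has no observed values; shift 0")
      shifts[j] <- 0
    } else {
      shifts[j] <- pooled[j] - run_med
    }
    v[, j] <- v[, j] + shifts[j]
  }
  m$values <- v
  attr(m, "shifts") <- shifts
  m
}

#' Left-shifted Gaussian imputation
#'
#' Perseus-style missing-not-at-random imputation, feature-wise: for each row
#' with observed mean mu and sample standard deviation sigma, every missing
#' cell is an independent draw from Normal(mu - downshift * sigma,
#' (width * sigma)^2). Observed cells are untouched. Rows with sigma = 0 fall
#' back to the matrix-wide median of row sigmas. Seeded from `cfg$rng_seed`
#' for bit-identical reruns.
#'
#' @param m A detection-filtered, normalized log2 `abundance_matrix`.
#' @param cfg An [atlas_config()].
#' @return Matrix with no missing cells and `imputed_mask` marking the draws.
#' @export
impute_left_shifted <- function(m, cfg = atlas_config()) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!m$log2) stop("imputation expects log2 scale")
  v <- m$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs < 2))
    stop("rows with < 2 observed values present; run detection_filter first")
  mu <- rowMeans(v, na.rm = TRUE)
  sig <- apply(v, 1, sd, na.rm = TRUE)
  fallback <- median(sig[sig > 0])
  if (!is.finite(fallback)) fallback <- 1
  sig[sig == 0] <- fallback
  mask <- is.na(v)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$rng_seed)
  for (i in seq_len(nrow(v))) {
    nmiss <- sum(mask[i, ])
    if (nmiss > 0)
      v[i, mask[i, ]] <- rnorm(nmiss,
                               mean = mu[i] - cfg$impute_downshift * sig[i],
                               sd = cfg$impute_width * sig[i])
  }
  m$values <- v
  m$imputed_mask <- mask
  m
}

#' Summarize to tissue-by-sex means
#'
#' For each site and tissue-sex group: the mean of observed replicate values
#' when any exist, otherwise the mean of the imputed replicate draws. The
#' result has no missing cells.
#'
#' @param detected A (possibly missing-containing) log2 `abundance_matrix`.
#' @param imputed The same matrix after [impute_left_shifted()].
#' @return Numeric matrix sites x tissue.sex, with an `observed` logical
#'   attribute marking cells backed by at least one measurement.
#' @export
summarize_tissue_sex <- function(detected, imputed) {
  stopifnot(inherits(detected, "abundance_matrix"),
            inherits(imputed, "abundance_matrix"),
            identical(dim(detected$values), dim(imputed$values)))
  grp <- .group_labels(detected$design)
  groups <- unique(grp)
  out <- matrix(NA_real_, nrow(detected$values), length(groups),
                dimnames = list(rownames(detected$values), groups))
  obs_flag <- matrix(FALSE, nrow(out), ncol(out), dimnames = dimnames(out))
  for (g in groups) {
    cols <- which(grp == g)
    dv <- detected$values[, cols, drop = FALSE]
    iv <- imputed$values[, cols, drop = FALSE]
    has_obs <- rowSums(!is.na(dv)) > 0
    mean_obs <- rowMeans(dv, na.rm = TRUE)
    mean_imp <- rowMeans(iv)
    out[, g] <- ifelse(has_obs, mean_obs, mean_imp)
    obs_flag[, g] <- has_obs
  }
  attr(out, "observed") <- obs_flag
  out
}

#' Row standardization (z-scores)
#'
#' Centers and scales each row to mean 0 and unit standard deviation using
#' the population (n) denominator, the heatmap display convention. Constant
#' rows become all-zero with a warning.
#'
#' @param x Numeric matrix with no missing cells.
#' @param denominator "population" (default) or "sample".
#' @return Standardized matrix.
#' @export
standardize_rows <- function(x, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  stopifnot(is.matrix(x), !anyNA(x))
  mu <- rowMeans(x)
  centered <- x - mu
  n <- ncol(x)
  ss <- rowSums(centered^2)
  sdv <- if (denominator == "population") sqrt(ss / n) else sqrt(ss / (n - 1))
  const <- sdv == 0
  if (any(const))
    warning(sum(const), " constant row(s) standardized to zeros")
  sdv[const] <- 1
  out <- centered / sdv
  out[const, ] <- 0
  out
}
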