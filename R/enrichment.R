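# vectorized exact hypergeometric p for 2x2 tables
# a = selected & annotated, b = selected & not, c = rest & annotated,
# d = rest & not
fisher_exact_2x2_vec <- function(a, b, c, d,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("counts must be nonnegative")
  m <- a + b          # selected margin
  k <- a + c          # annotated margin
  if (alternative == "greater") {
    p <- phyper(a - 1, k, b + d, m, lower.tail = FALSE)
  } else {
    p <- mapply(function(a, b, c, d) {
      m <- a + b; k <- a + c; N <- a + b + c + d
      lo <- max(0L, k - (N - m)); hi <- min(k, m)
      dens <- dhyper(lo:hi, k, N - k, m)
      sum(dens[dens <= dhyper(a, k, N - k, m) * (1 + 1e-7)])
    }, a, b, c, d)
  }
  pmin(p, 1)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric tail probability, one-sided over-representation by
#' default (is the top-left cell larger than expected under fixed margins?).
#' Degenerate tables with an all-zero row or column give p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts: rows are selected /
#'   rest, columns annotated / not annotated.
#' @param alternative "greater" (default) or "two.sided".
#' @return The p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)) # 1/6
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(tab), all(dim(tab) == 2))
  if (any(tab < 0)) stop("counts must be nonnegative")
  fisher_exact_2x2_vec(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                       alternative = alternative)
}

#' Per-tissue acetyl protein sets from a detection pattern
#'
#' @param detection A `detection_pattern` from [detection_filter()].
#' @param site_protein Named character vector, site key -> protein id.
#' @return Named list tissue -> character vector of proteins with at least
#'   one detected acetyl site in that tissue.
#' @export
tissue_acetyl_proteins <- function(detection, site_protein) {
  stopifnot(inherits(detection, "detection_pattern"))
  det <- detection$detected
  prot <- site_protein[rownames(det)]
  lapply(setNames(colnames(det), colnames(det)), function(t)
    sort(unique(prot[det[, t]])))
}

#' Tissue-level ontology term enrichment
#'
#' For every term and tissue, tests whether the tissue's acetyl proteins are
#' enriched for the term against the rest of the protein universe (Fisher
#' exact, one-sided by default). Tissues without acetyl proteins get p = 1
#' for every term, the convention for non-computable tests.
#'
#' @param tissue_proteins Named list tissue -> acetyl protein ids (see
#'   [tissue_acetyl_proteins()]).
#' @param annotations Named list protein -> closed term set.
#' @param universe Character vector of all detected proteins; must contain
#'   every acetyl protein.
#' @param cfg An [atlas_config()].
#' @return An `enrichment_matrix`: list with `p` and `neglog` (term x tissue
#'   matrices; `neglog` is -log10 p, exactly 0 where p = 1).
#' @export
tissue_enrichment <- function(tissue_proteins, annotations, universe,
                              cfg = atlas_config()) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty protein universe")
  stray <- setdiff(unlist(tissue_proteins, use.names = FALSE), universe)
  if (length(stray))
    stop("acetyl proteins outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  terms <- sort(unique(unlist(annotations[universe], use.names = FALSE)))
  tissues <- names(tissue_proteins)
  p <- matrix(1, length(terms), length(tissues),
              dimnames = list(terms, tissues))
  ann_ind <- vapply(terms, function(t)
    vapply(annotations[universe], function(s) t %in% s, logical(1)),
    logical(length(universe)))
  if (is.null(dim(ann_ind)))
    ann_ind <- matrix(ann_ind, nrow = length(universe))
  rownames(ann_ind) <- universe
  n_ann <- colSums(ann_ind)
  N <- length(universe)
  for (ti in tissues) {
    sel <- universe %in% tissue_proteins[[ti]]
    n_sel <- sum(sel)
    if (n_sel == 0) next                       # p stays 1.0
    a <- colSums(ann_ind[sel, , drop = FALSE])
    p[, ti] <- fisher_exact_2x2_vec(a, n_sel - a, n_ann - a,
                                    (N - n_sel) - (n_ann - a),
                                    alternative = cfg$ora_alternative)
  }
  structure(list(p = p, neglog = -log10(p)), class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d terms x %d tissues\n",
              nrow(x$p), ncol(x$p)))
  invisible(x)
}

# across-tissue sd of -log10 p under the configured convention
.term_sd <- function(neglog, convention) {
  if (convention == "sample") {
    apply(neglog, 1, sd)
  } else {
    n <- ncol(neglog)
    sqrt(apply(neglog, 1, function(v) mean((v - mean(v))^2)))
  }
}

#' Select variably enriched terms
#'
#' A term is retained when, across tissues on the -log10 p scale, (i) its
#' standard deviation is strictly greater than `term_sd_min`, (ii) some
#' tissue lies strictly below `term_low_max`, and (iii) some tissue lies
#' strictly above `term_high_min`. Together these select terms that are
#' strongly enriched somewhere but not everywhere.
#'
#' @param em An `enrichment_matrix`.
#' @param cfg An [atlas_config()].
#' @return Character vector of retained term ids.
#' @export
select_variable_terms <- function(em, cfg = atlas_config()) {
  stopifnot(inherits(em, "enrichment_matrix"))
  nl <- em$neglog
  sds <- .term_sd(nl, cfg$sd_convention)
  keep <- sds > cfg$term_sd_min &
    apply(nl, 1, min) < cfg$term_low_max &
    apply(nl, 1, max) > cfg$term_high_min
  rownames(nl)[keep]
}

#' Prune terms with near-identical annotation sets
#'
#' Removes one member of every pair whose annotated-protein overlap,
#' measured as the intersection over the smaller set, strictly exceeds
#' `overlap_max`. The member with the larger maximum -log10 p across tissues
#' is kept; ties go to the lexicographically smaller id.
#'
#' @param terms Candidate term ids.
#' @param term_proteins Named list term -> annotated protein ids (restricted
#'   to the relevant protein set).
#' @param em The `enrichment_matrix` used to score informativeness.
#' @param cfg An [atlas_config()].
#' @return Retained subset of `terms`.
#' @export
prune_overlapping_terms <- function(terms, term_proteins, em,
                                    cfg = atlas_config()) {
  if (length(terms) < 2) return(terms)
  score <- apply(em$neglog[terms, , drop = FALSE], 1, max)
  ord <- terms[order(-score, terms)]
  kept <- character()
  for (t in ord) {
    a <- term_proteins[[t]]
    clash <- FALSE
    for (k in kept) {
      b <- term_proteins[[k]]
      denom <- min(length(a), length(b))
      if (denom > 0 &&
          length(intersect(a, b)) / denom > cfg$overlap_max) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, t)
  }
  terms[terms %in% kept]
}

#' Keep only the most specific term of each ancestor-descendant pair
#'
#' @param terms Candidate term ids.
#' @param dag The `ontology_dag`.
#' @return Subset of `terms` with every retained ancestor of another
#'   retained term removed.
#' @export
prune_parent_child <- function(terms, dag) {
  anc <- term_ancestors(dag)
  ancestors_present <- unique(unlist(anc[intersect(terms, names(anc))],
                                     use.names = FALSE))
  setdiff(terms, ancestors_present)
}

#' Rank terms by tissue uniqueness
#'
#' Z-scores each term's -log10 p values across tissues, then scores each
#' term for the query tissue as that tissue's z minus the mean z of the
#' remaining tissues. Terms constant across tissues score 0.
#'
#' @param em An `enrichment_matrix`.
#' @param tissue Tissue name (column of the matrix).
#' @param cfg An [atlas_config()]; `top_k_unique` rows are returned.
#' @param terms Optional subset of terms to rank (default: all).
#' @return Data frame of term and uniqueness score, sorted descending.
#' @export
rank_unique_terms <- function(em, tissue, cfg = atlas_config(), terms = NULL) {
  stopifnot(inherits(em, "enrichment_matrix"))
  nl <- em$neglog
  if (!is.null(terms)) nl <- nl[intersect(terms, rownames(nl)), , drop = FALSE]
  if (ncol(nl) < 2) stop("uniqueness ranking requires at least 2 tissues")
  if (!tissue %in% colnames(nl)) stop("unknown tissue: ", tissue)
  mu <- rowMeans(nl)
  sdv <- apply(nl, 1, sd)
  z <- (nl - mu) / ifelse(sdv == 0, Inf, sdv)   # constant terms -> all-zero z
  others <- setdiff(colnames(nl), tissue)
  score <- z[, tissue] - rowMeans(z[, others, drop = FALSE])
  ord <- order(-score, rownames(nl))
  out <- data.frame(term = rownames(nl)[ord], score = score[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(out, cfg$top_k_unique)
}
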