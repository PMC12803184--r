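.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.PAD <- "_"

#' Flanking windows of every lysine in a proteome
#'
#' Extracts the +/- `flank_radius` residue window around each lysine of each
#' sequence; windows running off a terminus are padded with `_`. This is the
#' all-lysine background set for motif comparison.
#'
#' @param fasta Path to a proteome FASTA file, or a named character vector
#'   of sequences.
#' @param cfg An [atlas_config()].
#' @return Character vector of uniform-length flanks (length
#'   `2 * flank_radius + 1`).
#' @export
extract_background_flanks <- function(fasta, cfg = atlas_config()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    aa <- Biostrings::readAAStringSet(fasta)
    setNames(as.character(aa), names(aa))
  } else {
    fasta
  }
  r <- cfg$flank_radius
  flanks <- character()
  for (s in seqs) {
    s <- toupper(s)
    bad <- !strsplit(s, "")[[1]] %in% c(.AA20, "X", "U", "B", "Z", "*")
    if (any(bad))
      warning("sequence contains illegal characters; they are kept in flanks ",
              "but never counted")
    padded <- paste0(strrep(.PAD, r), s, strrep(.PAD, r))
    pos <- which(strsplit(s, "")[[1]] == "K")
    if (length(pos))
      flanks <- c(flanks, substring(padded, pos, pos + 2 * r))
  }
  flanks
}

#' Flanks of acetyl-site records
#'
#' @param x An `acetyl_sites` object.
#' @return Character vector of the records' flanking regions.
#' @export
site_flanks <- function(x) {
  stopifnot(inherits(x, "acetyl_sites"))
  x$meta$flank
}

#' Position frequency / information-content logo matrix
#'
#' Per-position residue counts and probabilities over the 20 standard amino
#' acids (terminal padding and non-standard residues are excluded from the
#' denominators, so edge columns are not diluted), plus the per-position
#' information content in bits against the uniform 20-residue background:
#' IC_j = log2(20) + sum_a p_aj log2 p_aj.
#'
#' @param flanks Character vector of uniform-length flanks.
#' @return A `logo_matrix`: list with `counts`, `prob`, `ic` (positions
#'   labelled -r..+r), and `n_flanks`.
#' @export
build_logo <- function(flanks) {
  if (!length(flanks)) stop("no flanks supplied")
  len <- unique(nchar(flanks))
  if (length(len) != 1) stop("flanks must have uniform length")
  r <- (len - 1) %/% 2
  pos_labels <- as.character(seq(-r, r))
  chars <- do.call(rbind, strsplit(toupper(flanks), ""))
  counts <- matrix(0L, length(.AA20), len,
                   dimnames = list(.AA20, pos_labels))
  for (j in seq_len(len)) {
    tab <- table(factor(chars[, j], levels = .AA20))
    counts[, j] <- as.integer(tab)
  }
  totals <- colSums(counts)
  prob <- sweep(counts, 2, pmax(totals, 1), "/")
  ic <- apply(prob, 2, function(p) {
    nz <- p[p > 0]
    log2(20) + sum(nz * log2(nz))
  })
  ic[totals == 0] <- 0
  structure(list(counts = counts, prob = prob, ic = ic,
                 n_flanks = length(flanks)),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("logo_matrix: %d flanks, positions %s..%s, max IC %.2f bits\n",
              x$n_flanks, colnames(x$counts)[1],
              colnames(x$counts)[ncol(x$counts)], max(x$ic)))
  invisible(x)
}

#' Foreground vs background motif enrichment
#'
#' Per-position per-residue log2 ratio of foreground to background
#' probabilities, with a pseudocount of `pseudocount` added to every
#' residue's count at every position so absent residues give finite,
#' strongly negative values. The center position (the modified lysine
#' itself) is excluded.
#'
#' @param foreground,background `logo_matrix` objects on matching positions.
#' @param pseudocount Count added per residue per position. Default 0.5.
#' @return Matrix of log2 enrichment, residues x positions; the center
#'   column is `NA`.
#' @export
compare_logos <- function(foreground, background, pseudocount = 0.5) {
  stopifnot(inherits(foreground, "logo_matrix"),
            inherits(background, "logo_matrix"),
            identical(colnames(foreground$counts), colnames(background$counts)))
  smooth <- function(l) {
    cnt <- l$counts + pseudocount
    sweep(cnt, 2, colSums(cnt), "/")
  }
  lr <- log2(smooth(foreground) / smooth(background))
  center <- which(colnames(lr) == "0")
  lr[, center] <- NA_real_
  lr
}

#' Plot a motif logo profile
#'
#' Barplot of per-position information content; a quick look at where the
#' flanking signal sits. For residue-level detail use the `prob` or
#' enrichment matrices directly.
#'
#' @param x A `logo_matrix`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.logo_matrix <- function(x, ...) {
  graphics::barplot(x$ic, names.arg = colnames(x$counts),
                    xlab = "position relative to acetyl-K",
                    ylab = "information content (bits)", ...)
  invisible(x)
}
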