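#' Build an ontology DAG from child-parent edges
#'
#' @param edges Data frame (or 2-column matrix) of is-a edges, child then
#'   parent term id.
#' @return An `ontology_dag`: list with `terms` and `parents` (named list,
#'   child -> character vector of parents). Construction fails on cycles,
#'   naming an edge on the cycle.
#' @export
ontology_dag <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge table needs two columns: child, parent")
  child <- as.character(edges[[1]])
  parent <- as.character(edges[[2]])
  terms <- sort(unique(c(child, parent)))
  parents <- split(parent, factor(child, levels = terms))
  parents <- lapply(parents, unique)
  dag <- structure(list(terms = terms, parents = parents),
                   class = "ontology_dag")
  # cycle check: depth-first with colors
  state <- setNames(integer(length(terms)), terms)  # 0 new, 1 active, 2 done
  for (t in terms) {
    if (state[t] != 0L) next
    stack <- list(list(node = t, i = 0L))
    state[t] <- 1L
    while (length(stack)) {
      top <- stack[[length(stack)]]
      ps <- parents[[top$node]]
      if (is.null(ps) || top$i >= length(ps)) {
        state[top$node] <- 2L
        stack[[length(stack)]] <- NULL
      } else {
        stack[[length(stack)]]$i <- top$i + 1L
        nxt <- ps[top$i + 1L]
        if (state[nxt] == 1L)
          stop("ontology contains a cycle through edge ",
               top$node, " -> ", nxt)
        if (state[nxt] == 0L) {
          state[nxt] <- 1L
          stack[[length(stack) + 1L]] <- list(node = nxt, i = 0L)
        }
      }
    }
  }
  dag
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d is-a edges\n",
              length(x$terms), sum(lengths(x$parents))))
  invisible(x)
}

#' Read an ontology from OBO or a child-parent edge list
#'
#' OBO files are read for their `[Term]` stanzas, using `id:` and `is_a:`
#' lines only; any other relationship types are ignored. Files that do not
#' look like OBO are read as tab-separated two-column child-parent lists.
#'
#' @param path File path.
#' @return An `ontology_dag`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\[Term\\]", lines))) {
    cur <- NA_character_
    child <- character(); parent <- character()
    in_term <- FALSE
    for (ln in lines) {
      if (grepl("^\\[", ln)) { in_term <- grepl("^\\[Term\\]", ln); cur <- NA; next }
      if (!in_term) next
      if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
      if (grepl("^is_a:", ln) && !is.na(cur)) {
        p <- trimws(sub("^is_a:", "", ln))
        p <- trimws(sub("!.*$", "", p))
        child <- c(child, cur); parent <- c(parent, p)
      }
    }
    ontology_dag(data.frame(child, parent, stringsAsFactors = FALSE))
  } else {
    edges <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                               comment.char = "#")
    ontology_dag(edges[, 1:2])
  }
}

#' All ancestors of each term
#'
#' @param dag An `ontology_dag`.
#' @return Named list term -> character vector of ancestors (excludes the
#'   term itself; empty for roots).
#' @export
term_ancestors <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  anc <- vector("list", length(dag$terms))
  names(anc) <- dag$terms
  done <- setNames(logical(length(dag$terms)), dag$terms)
  get_anc <- function(t) {
    if (done[[t]]) return(anc[[t]])
    ps <- dag$parents[[t]]
    res <- character()
    for (p in ps) res <- union(res, c(p, get_anc(p)))
    anc[[t]] <<- res
    done[[t]] <<- TRUE
    res
  }
  for (t in dag$terms) get_anc(t)
  anc
}

#' Ancestor closure of protein annotations
#'
#' Propagates each protein's direct term set upward through the is-a
#' hierarchy: a protein annotated to a term is counted for every ancestor of
#' that term.
#'
#' @param dag An `ontology_dag`.
#' @param direct Named list: protein -> character vector of directly
#'   annotated terms.
#' @return Named list with the closed term sets (direct union ancestors).
#' @export
ancestor_closure <- function(dag, direct) {
  anc <- term_ancestors(dag)
  lapply(direct, function(ts) {
    ts <- unique(ts)
    extra <- unlist(anc[intersect(ts, names(anc))], use.names = FALSE)
    sort(union(ts, extra))
  })
}

#' Read a protein-to-term annotation table
#'
#' @param path Tab-separated two-column file: protein id, term id. A header
#'   row is detected when the first line's second field is not term-like.
#' @return Named list protein -> character vector of direct terms.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  a <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (nrow(a) && a[1, 1] %in% c("protein", "protein_id"))
    a <- a[-1, , drop = FALSE]
  split(as.character(a[[2]]), as.character(a[[1]]))
}
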