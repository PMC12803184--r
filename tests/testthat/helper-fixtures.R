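# small in-code fixtures shared across test files

tiny_design <- function(tissues = c("liver", "brain"),
                        sexes = c("female", "male"), replicates = 3) {
  generate_design(length(tissues), sexes, replicates)[
    , c("run_id", "tissue", "sex", "replicate", "enriched")] |>
    (\(d) {
      d$tissue <- rep(tissues, each = length(sexes) * replicates)
      d$run_id <- sprintf("run_%s_%s_%d", d$tissue, d$sex, d$replicate)
      d
    })()
}

# build an acetyl_sites object directly from vectors
make_sites <- function(design,
                       collapse_key,
                       protein_id = sub("_K.*$", "", collapse_key),
                       position = as.integer(sub("^.*_K", "", collapse_key)),
                       intensities = NULL,
                       site_probability = 0.95,
                       mod_title = "Acetyl (K)",
                       pg_qvalue = 0.001, eg_qvalue = 0.001,
                       flank = strrep("A", 7) |> (\(a) paste0(a, "K", a))()) {
  n <- length(collapse_key)
  meta <- data.frame(
    protein_id = rep_len(protein_id, n),
    gene = sub("^P", "G", rep_len(protein_id, n)),
    position = rep_len(position, n),
    mod_title = rep_len(mod_title, n),
    site_probability = rep_len(site_probability, n),
    collapse_key = collapse_key,
    flank = rep_len(flank, n),
    pg_qvalue = rep_len(pg_qvalue, n),
    eg_qvalue = rep_len(eg_qvalue, n),
    stringsAsFactors = FALSE)
  if (is.null(intensities))
    intensities <- matrix(1000, n, nrow(design),
                          dimnames = list(NULL, design$run_id))
  structure(list(meta = meta, intensities = intensities, design = design),
            class = "acetyl_sites")
}

# abundance_matrix straight from a numeric matrix (log2 scale by default)
make_abundance <- function(values, design, log2 = TRUE) {
  structure(list(values = values, design = design, log2 = log2,
                 imputed_mask = matrix(FALSE, nrow(values), ncol(values),
                                       dimnames = dimnames(values))),
            class = "abundance_matrix")
}

# independent oracle: one-sided (greater) Fisher p by direct enumeration of
# the hypergeometric density from binomial coefficients
enum_fisher_greater <- function(a, b, c, d) {
  m <- a + b; k <- a + c; N <- a + b + c + d
  lo <- max(0, k - (N - m)); hi <- min(k, m)
  dens <- choose(m, lo:hi) * choose(N - m, k - (lo:hi)) / choose(N, k)
  sum(dens[(lo:hi) >= a])
}

# independent oracle: brute-force average-linkage cophenetic distances
bf_average_cophenetic <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1]) best <- c(avg, j, i)
    }
    i <- best[3]; j <- best[2]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[j]] <- c(clusters[[j]], clusters[[i]])
    clusters[[i]] <- NULL
  }
  as.dist(coph)
}

# reachability oracle for ancestor sets: repeated one-step parent expansion
bf_ancestors <- function(edges, term) {
  frontier <- term
  seen <- character()
  while (length(frontier)) {
    ps <- unique(edges$parent[edges$child %in% frontier])
    ps <- setdiff(ps, seen)
    seen <- c(seen, ps)
    frontier <- ps
  }
  sort(seen)
}

# a cached default-scenario simulation + analysis, shared by the slower tests
atlas_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_atlas(seed = 421)
      res <- run_atlas_simulation(sim, atlas_config(rng_seed = 421))
      cache <<- list(sim = sim, res = res)
    }
    cache
  }
})
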