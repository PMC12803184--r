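# approximate vertebrate amino-acid background frequencies
.aa_freq <- c(A = 7.0, C = 1.5, D = 5.5, E = 7.0, F = 4.0, G = 7.0, H = 2.5,
              I = 5.5, K = 6.5, L = 9.5, M = 2.5, N = 4.0, P = 5.0, Q = 4.0,
              R = 5.5, S = 7.5, T = 5.5, V = 6.5, W = 1.0, Y = 3.0)

.atlas_tissues <- c("brain", "heart", "liver", "kidney", "lung", "spleen",
                    "pancreas", "stomach", "intestine", "muscle", "fat",
                    "skin", "testis", "thymus", "bone")

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a multi-tissue sample design
#'
#' @param n_tissues Number of tissues (up to 15 named mouse tissues; more
#'   get generic labels).
#' @param sexes Character vector of sex labels.
#' @param replicates Replicates per tissue-sex group.
#' @return Design data frame: `run_id`, `tissue`, `sex`, `replicate`,
#'   `enriched`.
#' @export
generate_design <- function(n_tissues = 15L, sexes = c("female", "male"),
                            replicates = 3L) {
  stopifnot(n_tissues >= 1, replicates >= 1, length(sexes) >= 1)
  tissues <- if (n_tissues <= length(.atlas_tissues))
    .atlas_tissues[seq_len(n_tissues)]
  else c(.atlas_tissues, paste0("tissue", seq_len(n_tissues - length(.atlas_tissues))))
  g <- expand.grid(replicate = seq_len(replicates), sex = sexes,
                   tissue = tissues, stringsAsFactors = FALSE)
  g <- g[, c("tissue", "sex", "replicate")]
  g$run_id <- sprintf("run_%s_%s_%d", g$tissue, g$sex, g$replicate)
  g$enriched <- TRUE
  g[, c("run_id", "tissue", "sex", "replicate", "enriched")]
}

#' Simulate an atlas-like acetylome study with known ground truth
#'
#' Generates every input the pipeline reads -- site report, design, proteome
#' FASTA, predicted-structure atom tables, ontology, annotations and a
#' variant table -- from a single seed, with the planted truth recorded for
#' parameter-recovery testing. The default scenario is an atlas-like
#' design: 15 tissues x 2 sexes x 3 replicates, 2,000 acetyl sites on
#' 400 proteins, log-normal site abundances, intensity-dependent
#' (left-censored) missingness, tissue-specific proteins with a planted
#' enriched ontology term per tissue, a planted flanking-motif enrichment,
#' buried/exposed lysine pairs in helical decoy structures, and a planted
#' pathogenic-variant association with site abundance.
#'
#' @param n_tissues,sexes,replicates Study design (defaults 15, both sexes,
#'   3).
#' @param n_sites,n_proteins Atlas size (defaults 2000 sites, 400 proteins).
#' @param planted_per_tissue Tissue-specific proteins planted per tissue
#'   (default 12); all their sites are specific to that tissue.
#' @param broad_tissue_fraction Fraction of tissues in which each broad
#'   (non-planted) protein is expressed (default 0.5).
#' @param base_mean,base_sd Log2 mean and sd of site base abundances
#'   (defaults 20, 2).
#' @param rep_sd Replicate noise sd, log2 units (default 0.4).
#' @param run_shift_sd Per-run batch shift sd removed by normalization
#'   (default 0.3).
#' @param suppress_shift Log2 units below the global mean at which a site
#'   sits in tissues where its protein is not expressed (default 12, i.e.
#'   background level far inside the censoring window, so such cells are
#'   almost always missing).
#' @param missing_mid_offset,missing_scale Logistic missingness: a cell of
#'   latent log2 intensity x is missing with probability
#'   `plogis((base_mean - missing_mid_offset - x) / missing_scale)`
#'   (defaults 3 and 1, i.e. midpoint 3 log2 units below the global mean).
#' @param lod_margin Hard detection floor: cells more than
#'   `missing_mid_offset + lod_margin` log2 units below the global mean are
#'   never quantified, emulating the instrument's limit of detection
#'   (default 4).
#' @param filter_fail_fraction Fraction of report rows planted to fail each
#'   identification filter (localization, q-value, modification label);
#'   default 0.05 per filter, disjoint rows.
#' @param dup_fraction Fraction of sites given a second precursor row with
#'   the same collapse key (default 0.05).
#' @param motif_residue,motif_offset,motif_effect Planted motif: with
#'   probability `motif_effect` the proteome residue at `motif_offset`
#'   relative to an acetyl site is rewritten to `motif_residue` (defaults
#'   "E", -1, 0.5).
#' @param n_terms Background ontology terms (default 60) in a random
#'   tree-plus-shortcut DAG; one extra planted term per tissue under the
#'   root.
#' @param n_structure_proteins Proteins given decoy structures with one
#'   buried / one exposed lysine pair each (default 12).
#' @param buried_shell_points Crowding-shell atoms around each buried lysine
#'   (default 24).
#' @param variant_fraction Fraction of sites with a mapped human variant
#'   (default 0.6).
#' @param variant_association "planted" (default) links pathogenicity to
#'   abundance through a truncated logistic on the site's abundance
#'   percentile (zero below the 60th percentile, rising to ~0.7 at the
#'   top); "none" uses a flat 0.3 probability.
#' @param seed Integer seed; identical seeds give identical simulations.
#' @return An `atlas_simulation`: list with `design`, `report` (site-report
#'   data frame in the Spectronaut dialect), `proteome` (named character),
#'   `structures` (per-protein atom tables), `ontology_edges`,
#'   `annotations` (direct protein -> term list), `variants`, `universe`,
#'   and `truth`.
#' @export
simulate_atlas <- function(n_tissues = 15L,
                           sexes = c("female", "male"),
                           replicates = 3L,
                           n_sites = 2000L,
                           n_proteins = 400L,
                           planted_per_tissue = 12L,
                           broad_tissue_fraction = 0.5,
                           base_mean = 20,
                           base_sd = 2,
                           rep_sd = 0.4,
                           run_shift_sd = 0.3,
                           suppress_shift = 12,
                           missing_mid_offset = 3,
                           missing_scale = 1,
                           lod_margin = 4,
                           filter_fail_fraction = 0.05,
                           dup_fraction = 0.05,
                           motif_residue = "E",
                           motif_offset = -1L,
                           motif_effect = 0.5,
                           n_terms = 60L,
                           n_structure_proteins = 12L,
                           buried_shell_points = 24L,
                           variant_fraction = 0.6,
                           variant_association = c("planted", "none"),
                           seed = 1L) {
  variant_association <- match.arg(variant_association)
  with_seed(seed, {
    design <- generate_design(n_tissues, sexes, replicates)
    tissues <- unique(design$tissue)

    ## proteome ------------------------------------------------------------
    prot_ids <- sprintf("P%04d", seq_len(n_proteins))
    lens <- sample(100:200, n_proteins, replace = TRUE)
    proteome <- vapply(lens, function(L)
      paste(sample(names(.aa_freq), L, replace = TRUE, prob = .aa_freq),
            collapse = ""), character(1))
    names(proteome) <- prot_ids

    ## site selection ------------------------------------------------------
    kpos <- lapply(proteome, function(s) which(strsplit(s, "")[[1]] == "K"))
    all_sites <- data.frame(
      protein_id = rep(names(kpos), lengths(kpos)),
      position = unlist(kpos, use.names = FALSE),
      stringsAsFactors = FALSE)
    if (nrow(all_sites) < n_sites)
      stop("proteome too small for requested site count")
    pick <- sort(sample(nrow(all_sites), n_sites))
    sites <- all_sites[pick, , drop = FALSE]
    rownames(sites) <- NULL
    sites$collapse_key <- sprintf("%s_K%d", sites$protein_id, sites$position)

    ## planted motif: rewrite the proteome before flanks are extracted -----
    motif_hit <- runif(n_sites) < motif_effect
    for (i in which(motif_hit)) {
      p <- sites$position[i] + motif_offset
      s <- proteome[[sites$protein_id[i]]]
      # never overwrite a lysine: it could be (or become) another site
      if (p >= 1 && p <= nchar(s) && p != sites$position[i] &&
          substr(s, p, p) != "K")
        substr(proteome[[sites$protein_id[i]]], p, p) <- motif_residue
      else motif_hit[i] <- FALSE
    }

    ## tissue structure of the proteome ------------------------------------
    stopifnot(planted_per_tissue * n_tissues <= n_proteins)
    planted_prot <- split(
      prot_ids[seq_len(planted_per_tissue * n_tissues)],
      rep(tissues, each = planted_per_tissue))
    prot_tissue <- setNames(rep(NA_character_, n_proteins), prot_ids)
    for (t in names(planted_prot)) prot_tissue[planted_prot[[t]]] <- t
    broad_ids <- prot_ids[is.na(prot_tissue)]
    n_expr <- pmax(1L, stats::rbinom(length(broad_ids), n_tissues,
                                     broad_tissue_fraction))
    expressed <- setNames(vector("list", n_proteins), prot_ids)
    for (i in seq_along(broad_ids))
      expressed[[broad_ids[i]]] <- sample(tissues, n_expr[i])
    for (t in names(planted_prot))
      for (p in planted_prot[[t]]) expressed[[p]] <- t

    ## latent abundances and the report matrix ------------------------------
    base <- stats::rnorm(n_sites, base_mean, base_sd)
    # planted spike-in sites are placed above the censoring midpoint, the
    # usual spike-in benchmark convention: recovery of a spike below the
    # detection limit would measure the instrument, not the pipeline
    spike_floor <- base_mean - missing_mid_offset + 1.5
    planted_site <- !is.na(prot_tissue[sites$protein_id])
    base[planted_site] <- pmax(base[planted_site], spike_floor)
    run_shift <- stats::rnorm(nrow(design), 0, run_shift_sd)
    x0 <- base_mean - missing_mid_offset
    inten <- matrix(NA_real_, n_sites, nrow(design),
                    dimnames = list(sites$collapse_key, design$run_id))
    on_by_tissue <- sapply(tissues, function(t)
      vapply(expressed[sites$protein_id], function(e) t %in% e, logical(1)))
    for (j in seq_len(nrow(design))) {
      t <- design$tissue[j]
      mu <- ifelse(on_by_tissue[, t], base, base_mean - suppress_shift)
      x <- mu + stats::rnorm(n_sites, 0, rep_sd)
      miss <- x < (x0 - lod_margin) |
        runif(n_sites) < stats::plogis((x0 - x) / missing_scale)
      v <- 2^(x + run_shift[j])
      v[miss] <- NA_real_
      inten[, j] <- v
    }

    ## identification-filter columns ----------------------------------------
    n_fail <- round(filter_fail_fraction * n_sites)
    fail_idx <- if (n_fail > 0) sample(n_sites, min(3L * n_fail, n_sites))
                else integer()
    fail_prob <- utils::head(fail_idx, n_fail)
    rest <- setdiff(fail_idx, fail_prob)
    fail_q <- utils::head(rest, n_fail)
    fail_mod <- setdiff(rest, fail_q)
    prob <- runif(n_sites, 0.76, 1)
    prob[fail_prob] <- runif(length(fail_prob), 0.3, 0.75)
    pgq <- runif(n_sites, 0, 0.01)
    egq <- runif(n_sites, 0, 0.01)
    pgq[fail_q] <- runif(length(fail_q), 0.011, 0.2)
    mod <- rep("Acetyl (K)", n_sites)
    mod[fail_mod] <- "Phospho (STY)"
    passes <- !(seq_len(n_sites) %in% fail_idx)

    flank_of <- function(protein, pos, r = 7L) {
      s <- proteome[[protein]]
      padded <- paste0(strrep("_", r), s, strrep("_", r))
      substr(padded, pos, pos + 2L * r)
    }
    flanks <- mapply(flank_of, sites$protein_id, sites$position)

    report <- data.frame(
      PG.ProteinGroups = sites$protein_id,
      PG.Genes = sub("^P", "G", sites$protein_id),
      PTM.SiteLocation = sites$position,
      PTM.ModificationTitle = mod,
      PTM.SiteProbability = prob,
      PTM.CollapseKey = sites$collapse_key,
      PTM.FlankingRegion = flanks,
      PG.Qvalue = pgq,
      EG.Qvalue = egq,
      stringsAsFactors = FALSE, check.names = FALSE)
    report <- cbind(report, as.data.frame(inten, check.names = FALSE))

    # extra precursor rows sharing a collapse key
    dup_idx <- sample(which(passes), round(dup_fraction * n_sites))
    if (length(dup_idx)) {
      dup <- report[dup_idx, , drop = FALSE]
      qcols <- design$run_id
      dup[, qcols] <- dup[, qcols] * matrix(runif(length(dup_idx) *
                                                    length(qcols), 0.3, 0.9),
                                            length(dup_idx))
      report <- rbind(report, dup)
    }
    rownames(report) <- NULL

    ## ontology + annotations ----------------------------------------------
    bg_terms <- sprintf("T%04d", seq_len(n_terms))
    parent <- c("ROOT", vapply(2:n_terms, function(i)
      sample(c("ROOT", bg_terms[seq_len(i - 1)]), 1), character(1)))
    edges <- data.frame(child = bg_terms, parent = parent,
                        stringsAsFactors = FALSE)
    n_short <- max(1L, n_terms %/% 10L)
    sc_child <- sample(bg_terms[-(1:2)], n_short)
    sc_parent <- vapply(match(sc_child, bg_terms), function(i)
      bg_terms[sample(i - 1, 1)], character(1))
    keepsc <- sc_parent != edges$parent[match(sc_child, edges$child)]
    edges <- rbind(edges,
                   data.frame(child = sc_child[keepsc],
                              parent = sc_parent[keepsc],
                              stringsAsFactors = FALSE))
    planted_terms <- setNames(sprintf("TP_%s", tissues), tissues)
    edges <- rbind(edges, data.frame(child = unname(planted_terms),
                                     parent = "ROOT",
                                     stringsAsFactors = FALSE))
    annotations <- lapply(setNames(prot_ids, prot_ids), function(p)
      sample(bg_terms, 2))
    for (t in tissues)
      for (p in planted_prot[[t]])
        annotations[[p]] <- c(annotations[[p]], planted_terms[[t]])

    ## structures ------------------------------------------------------------
    cand <- vapply(prot_ids, function(p) {
      k <- kpos[[p]]
      k <- k[k > 3 & k < nchar(proteome[[p]]) - 3]
      length(k) >= 2
    }, logical(1))
    struct_ids <- utils::head(prot_ids[cand], n_structure_proteins)
    structures <- list()
    pairs <- list()
    plddt_truth <- list()
    for (p in struct_ids) {
      k <- kpos[[p]]
      k <- k[k > 3 & k < nchar(proteome[[p]]) - 3]
      pr <- sample(k, 2)
      buried <- pr[1]; exposed <- pr[2]
      L <- nchar(proteome[[p]])
      pl <- round(runif(L, 60, 95), 2)
      structures[[p]] <- helix_atoms(proteome[[p]], pl,
                                     buried_at = buried,
                                     shell_points = buried_shell_points)
      pairs[[p]] <- data.frame(protein_id = p, buried = buried,
                               exposed = exposed, stringsAsFactors = FALSE)
      plddt_truth[[p]] <- pl
    }

    ## variants ---------------------------------------------------------------
    pct <- rank(base, ties.method = "first") / n_sites
    p_path <- if (variant_association == "planted")
      ifelse(pct < 0.6, 0, 0.7 * stats::plogis((pct - 0.85) / 0.06))
    else rep(0.3, n_sites)
    has_var <- runif(n_sites) < variant_fraction
    is_path <- has_var & (runif(n_sites) < p_path)
    alt <- sample(c("Q", "R", "E", "T", "N", "M"), n_sites, replace = TRUE,
                  prob = c(0.25, 0.3, 0.15, 0.1, 0.1, 0.1))
    sig <- ifelse(is_path,
                  sample(c("Pathogenic", "Likely pathogenic"), n_sites,
                         replace = TRUE),
                  ifelse(runif(n_sites) < 0.8,
                         sample(c("Benign", "Likely benign"), n_sites,
                                replace = TRUE),
                         "Uncertain significance"))
    variants <- data.frame(
      mouse_protein = sites$protein_id[has_var],
      mouse_position = sites$position[has_var],
      human_protein = sub("^P", "H", sites$protein_id[has_var]),
      human_position = sites$position[has_var],
      ref_aa = "K",
      alt_aa = alt[has_var],
      significance = sig[has_var],
      phenotype = ifelse(is_path[has_var], "synthetic disease",
                         "no phenotype"),
      stringsAsFactors = FALSE)

    truth <- list(
      seed = seed,
      planted_proteins = planted_prot,
      planted_terms = planted_terms,
      site_table = data.frame(
        collapse_key = sites$collapse_key,
        protein_id = sites$protein_id,
        position = sites$position,
        base_abundance = base,
        tissue_specific = !is.na(prot_tissue[sites$protein_id]),
        home_tissue = unname(prot_tissue[sites$protein_id]),
        passes_filter = passes,
        motif_hit = motif_hit,
        pathogenic = is_path,
        stringsAsFactors = FALSE),
      missing_model = c(midpoint = x0, scale = missing_scale),
      motif = list(residue = motif_residue, offset = motif_offset,
                   effect = motif_effect),
      structure_pairs = do.call(rbind, pairs),
      plddt = plddt_truth,
      variant_association = variant_association)

    structure(list(design = design, report = report, proteome = proteome,
                   structures = structures, ontology_edges = edges,
                   annotations = annotations, variants = variants,
                   universe = prot_ids, truth = truth),
              class = "atlas_simulation")
  })
}

#' @export
print.atlas_simulation <- function(x, ...) {
  cat(sprintf(paste0("atlas_simulation: %d report rows, %d runs, %d proteins, ",
                     "%d structures, %d variants (seed %d)\n"),
              nrow(x$report), nrow(x$design), length(x$proteome),
              length(x$structures), nrow(x$variants), x$truth$seed))
  invisible(x)
}

# decoy helical backbone with optional crowding shell around a buried lysine
helix_atoms <- function(seq, plddt, buried_at = NULL, shell_points = 24L) {
  L <- nchar(seq)
  aa1 <- strsplit(seq, "")[[1]]
  aa3 <- names(.aa3to1)[match(aa1, .aa3to1)]
  aa3[is.na(aa3)] <- "UNK"
  i <- seq_len(L)
  ang <- i * (100 * pi / 180)
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
  offs <- list(N = c(-0.8, 0.6, -0.9), CA = c(0, 0, 0),
               C = c(0.9, 0.5, 0.7), O = c(1.5, 1.2, 0.9))
  rows <- list()
  serial <- 0L
  for (ri in i) {
    for (an in names(offs)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = an, resname = aa3[ri], chain = "A",
        residue_index = ri,
        x = ca[ri, 1] + offs[[an]][1], y = ca[ri, 2] + offs[[an]][2],
        z = ca[ri, 3] + offs[[an]][3],
        b_factor = plddt[ri],
        element = substr(an, 1, 1), hetatm = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  if (!is.null(buried_at)) {
    sp <- golden_spiral_points(shell_points) * 4.0
    ctr <- ca[buried_at, ]
    shell <- data.frame(
      serial = max(atoms$serial) + seq_len(shell_points),
      name = "DC", resname = "DUM", chain = "A",
      residue_index = 9000L + buried_at,
      x = ctr[1] + sp[, 1], y = ctr[2] + sp[, 2], z = ctr[3] + sp[, 3],
      b_factor = plddt[buried_at], element = "C", hetatm = FALSE,
      stringsAsFactors = FALSE)
    atoms <- rbind(atoms, shell)
  }
  atoms$vdw_radius <- unname(ifelse(is.na(.vdw_table[atoms$element]),
                                    .vdw_default, .vdw_table[atoms$element]))
  atoms
}

#' Write an atom table as a PDB file
#'
#' @param atoms Atom data frame (columns as returned by [parse_pdb()]).
#' @param path Output file.
#' @export
write_pdb <- function(atoms, path) {
  lines <- sprintf(
    "%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$hetatm, "HETATM", "ATOM"),
    atoms$serial, atoms$name, atoms$resname, atoms$chain,
    atoms$residue_index, atoms$x, atoms$y, atoms$z, 1.0, atoms$b_factor,
    atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write every simulated input to disk
#'
#' Writes exactly the formats the pipeline reads: `report.tsv`,
#' `design.tsv`, `proteome.fasta`, `structures/<protein>.pdb`,
#' `ontology_edges.tsv`, `annotations.tsv`, `variants.tsv`, `universe.txt`,
#' and the planted truth under `truth/`.
#'
#' @param sim An `atlas_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "atlas_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sim$design, "design.tsv")
  tsv(sim$report, "report.tsv")
  aa <- Biostrings::AAStringSet(sim$proteome)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"))
  dir.create(file.path(dir, "structures"), showWarnings = FALSE)
  for (p in names(sim$structures))
    write_pdb(sim$structures[[p]],
              file.path(dir, "structures", paste0(p, ".pdb")))
  utils::write.table(sim$ontology_edges, file.path(dir, "ontology_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  ann <- data.frame(protein = rep(names(sim$annotations),
                                  lengths(sim$annotations)),
                    term = unlist(sim$annotations, use.names = FALSE))
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  tsv(sim$variants, "variants.tsv")
  writeLines(sim$universe, file.path(dir, "universe.txt"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  tsv(sim$truth$site_table, "truth/site_table.tsv")
  tsv(sim$truth$structure_pairs, "truth/structure_pairs.tsv")
  tsv(data.frame(tissue = names(sim$truth$planted_terms),
                 term = unname(sim$truth$planted_terms)),
      "truth/planted_terms.tsv")
  tsv(data.frame(key = c("seed", "variant_association", "motif_residue",
                         "motif_offset", "motif_effect",
                         "missing_midpoint", "missing_scale"),
                 value = c(sim$truth$seed, sim$truth$variant_association,
                           sim$truth$motif$residue, sim$truth$motif$offset,
                           sim$truth$motif$effect,
                           sim$truth$missing_model["midpoint"],
                           sim$truth$missing_model["scale"])),
      "truth/params.tsv")
  invisible(dir)
}
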