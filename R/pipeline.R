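#' Run the full analysis on in-memory inputs
#'
#' Executes the stage sequence ingest -> quantify -> cluster -> enrichment
#' -> motif -> structure -> variants on already-parsed inputs. Stages whose
#' inputs are absent are skipped and listed in `skipped`.
#'
#' @param sites An `acetyl_sites` object (unfiltered records).
#' @param proteome Named character vector of protein sequences (for the
#'   motif background), or NULL to skip the motif stage.
#' @param ontology An `ontology_dag`, or NULL to skip enrichment stages.
#' @param annotations Direct protein -> term list (closure is applied
#'   here).
#' @param universe Protein universe for tissue enrichment; defaults to the
#'   annotation names when NULL and `cfg$enrichment_universe = "proteome"`.
#' @param structures Named list protein -> per-residue structure table
#'   (from [residue_structure()]), or atom tables (SASA and pLDDT computed
#'   here), or NULL to skip.
#' @param variants Variant data frame, or NULL to skip.
#' @param cfg An [atlas_config()].
#' @return A list of per-stage results (class `atlas_analysis`).
#' @export
run_analysis <- function(sites, proteome = NULL, ontology = NULL,
                         annotations = NULL, universe = NULL,
                         structures = NULL, variants = NULL,
                         cfg = atlas_config()) {
  skipped <- character()

  ## ingest
  filtered <- filter_acetyl_sites(sites, cfg)
  collapsed <- collapse_unique_sites(filtered)

  ## quantify
  raw <- build_matrix(collapsed)
  df <- detection_filter(raw, cfg)
  lg <- log2_transform(df$matrix)
  norm <- median_normalize(lg, cfg)
  imp <- impute_left_shifted(norm, cfg)
  summarized <- summarize_tissue_sex(norm, imp)
  standardized <- standardize_rows(summarized)

  ## cluster
  hc <- cluster_rows(standardized, cfg)
  groups <- cut_groups(hc, min(cfg$n_cut_groups, nrow(standardized)))
  pca <- pca_sites(standardized)
  site_protein <- setNames(collapsed$meta$protein_id,
                           collapsed$meta$collapse_key)

  enrich <- NULL; ora <- NULL
  if (!is.null(ontology) && !is.null(annotations)) {
    closed <- ancestor_closure(ontology, annotations)
    ora <- group_ora(groups, site_protein, closed, cfg)
    if (is.null(universe))
      universe <- names(annotations)
    if (cfg$enrichment_universe == "acetyl")
      universe <- intersect(universe, unique(unname(site_protein)))
    tp <- tissue_acetyl_proteins(df$detection, site_protein)
    em <- tissue_enrichment(tp, closed, universe, cfg)
    selected <- select_variable_terms(em, cfg)
    acetyl_prot <- unique(unname(site_protein[rownames(df$detection$detected)]))
    term_proteins <- lapply(setNames(selected, selected), function(t)
      acetyl_prot[vapply(closed[acetyl_prot],
                         function(s) t %in% s, logical(1))])
    pruned <- prune_overlapping_terms(selected, term_proteins, em, cfg)
    pruned <- prune_parent_child(pruned, ontology)
    uniq <- lapply(setNames(colnames(em$p), colnames(em$p)), function(t)
      rank_unique_terms(em, t, cfg))
    enrich <- list(closed = closed, tissue_proteins = tp, matrix = em,
                   selected = selected, pruned = pruned,
                   unique_terms = uniq)
  } else skipped <- c(skipped, "enrichment")

  motif <- NULL
  if (!is.null(proteome)) {
    fore <- build_logo(site_flanks(collapsed))
    back <- build_logo(extract_background_flanks(proteome, cfg))
    motif <- list(foreground = fore, background = back,
                  enrichment = compare_logos(fore, back))
  } else skipped <- c(skipped, "motif")

  struct <- NULL
  if (!is.null(structures) && length(structures)) {
    restabs <- lapply(structures, function(s) {
      if (is.data.frame(s) && "sasa" %in% names(s)) return(s)
      pl <- plddt_per_residue(s)
      sa <- residue_sasa(shrake_rupley(s, probe = cfg$sasa_probe_radius,
                                       n_points = cfg$sasa_n_points,
                                       include_hydrogens = cfg$sasa_include_hydrogens))
      resno <- sort(unique(s$residue_index))
      data.frame(residue_index = resno,
                 aa = {
                   a <- unname(.aa3to1[s$resname[match(resno, s$residue_index)]])
                   a[is.na(a)] <- "X"; a
                 },
                 plddt = unname(pl[as.character(resno)]),
                 sasa = unname(sa[as.character(resno)]),
                 stringsAsFactors = FALSE)
    })
    struct <- list(residues = restabs,
                   site_context = join_site_structure(collapsed, restabs))
  } else skipped <- c(skipped, "structure")

  var_res <- NULL
  if (!is.null(variants)) {
    joined <- flag_acetyl_mimics(join_sites_variants(collapsed, variants))
    abund <- site_mean_abundance(norm)
    path_keys <- unique(joined$collapse_key[joined$significance == "pathogenic"])
    curve <- abundance_rank_enrichment(abund, path_keys, cfg)
    var_res <- list(joined = joined, fold_curve = curve,
                    site_abundance = abund)
  } else skipped <- c(skipped, "variants")

  structure(list(filtered = filtered, collapsed = collapsed,
                 raw = raw, detection = df$detection, normalized = norm,
                 imputed = imp, summarized = summarized,
                 standardized = standardized,
                 hclust = hc, groups = groups, ora = ora, pca = pca,
                 enrichment = enrich, motif = motif, structure = struct,
                 variants = var_res, skipped = skipped, cfg = cfg),
            class = "atlas_analysis")
}

#' @export
print.atlas_analysis <- function(x, ...) {
  cat(sprintf("atlas_analysis: %d sites after filtering, %d runs\n",
              nrow(x$collapsed$meta), ncol(x$raw$values)))
  if (length(x$skipped))
    cat("  skipped stages:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full analysis on a simulated atlas
#'
#' Convenience wrapper: converts an [simulate_atlas()] result to pipeline
#' inputs and calls [run_analysis()] on every stage.
#'
#' @param sim An `atlas_simulation`.
#' @param cfg An [atlas_config()].
#' @return An `atlas_analysis` object.
#' @export
run_atlas_simulation <- function(sim, cfg = atlas_config()) {
  stopifnot(inherits(sim, "atlas_simulation"))
  sites <- as_acetyl_sites(sim$report, sim$design, cfg)
  run_analysis(sites,
               proteome = sim$proteome,
               ontology = ontology_dag(sim$ontology_edges),
               annotations = sim$annotations,
               universe = sim$universe,
               structures = sim$structures,
               variants = {
                 v <- sim$variants
                 v$significance <- normalize_significance(v$significance)
                 v
               },
               cfg = cfg)
}

#' Run the pipeline on a directory of input files
#'
#' Reads the standard input layout (as written by [write_atlas_inputs()]),
#' runs every stage whose inputs are present, writes per-stage
#' tab-separated outputs under `output_dir`, and finishes with a
#' `manifest.tsv` recording the config snapshot, input checksums, completed
#' and skipped stages and the seed. The manifest is written last, via a
#' temporary file, so its presence marks a completed run.
#'
#' @param input_dir Directory containing `report.tsv` and `design.tsv`
#'   (required) and optionally `proteome.fasta`, `ontology_edges.tsv`,
#'   `annotations.tsv`, `universe.txt`, `structures/*.pdb`,
#'   `variants.tsv`.
#' @param output_dir Output directory (created).
#' @param cfg An [atlas_config()].
#' @return The analysis object, invisibly; outputs and manifest on disk.
#' @export
run_pipeline <- function(input_dir, output_dir, cfg = atlas_config()) {
  fp <- function(f) file.path(input_dir, f)
  if (!file.exists(fp("report.tsv")) || !file.exists(fp("design.tsv")))
    stop("input directory must contain report.tsv and design.tsv")
  design <- read_sample_design(fp("design.tsv"))
  sites <- read_site_report(fp("report.tsv"), design, cfg)
  proteome <- if (file.exists(fp("proteome.fasta"))) {
    aa <- Biostrings::readAAStringSet(fp("proteome.fasta"))
    setNames(as.character(aa), names(aa))
  }
  ontology <- if (file.exists(fp("ontology_edges.tsv")))
    read_ontology(fp("ontology_edges.tsv"))
  annotations <- if (file.exists(fp("annotations.tsv")))
    read_annotations(fp("annotations.tsv"))
  universe <- if (file.exists(fp("universe.txt")))
    readLines(fp("universe.txt"))
  sdir <- fp("structures")
  structures <- NULL
  if (dir.exists(sdir)) {
    pdbs <- list.files(sdir, pattern = "\\.pdb$", full.names = TRUE)
    structures <- lapply(pdbs, residue_structure, cfg = cfg)
    names(structures) <- sub("\\.pdb$", "", basename(pdbs))
  }
  variants <- if (file.exists(fp("variants.tsv")))
    read_variant_table(fp("variants.tsv"))

  res <- run_analysis(sites, proteome = proteome, ontology = ontology,
                      annotations = annotations, universe = universe,
                      structures = structures, variants = variants,
                      cfg = cfg)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  op <- function(f) file.path(output_dir, f)
  wt <- function(x, f, rn = FALSE) utils::write.table(
    x, op(f), sep = "\t", quote = FALSE, row.names = rn,
    col.names = if (rn) NA else TRUE)
  wt(res$collapsed$meta, "sites.tsv")
  wt(res$summarized, "summarized_tissue_sex.tsv", rn = TRUE)
  wt(res$standardized, "standardized.tsv", rn = TRUE)
  wt(res$imputed$values, "imputed.tsv", rn = TRUE)
  wt(res$imputed$imputed_mask * 1L, "imputed_mask.tsv", rn = TRUE)
  wt(data.frame(collapse_key = names(res$groups), group = res$groups),
     "cluster_groups.tsv")
  if (!is.null(res$ora)) wt(res$ora, "group_ora.tsv")
  wt(res$pca$scores, "pca_scores.tsv", rn = TRUE)
  wt(res$pca$loadings, "pca_loadings.tsv", rn = TRUE)
  if (!is.null(res$enrichment)) {
    wt(res$enrichment$matrix$neglog, "tissue_enrichment_neglog10p.tsv",
       rn = TRUE)
    writeLines(res$enrichment$pruned, op("selected_terms.txt"))
    uni <- do.call(rbind, lapply(names(res$enrichment$unique_terms),
                                 function(t) cbind(tissue = t,
                                                   res$enrichment$unique_terms[[t]])))
    wt(uni, "unique_terms.tsv")
  }
  if (!is.null(res$motif)) {
    wt(res$motif$foreground$prob, "logo_foreground_prob.tsv", rn = TRUE)
    wt(res$motif$background$prob, "logo_background_prob.tsv", rn = TRUE)
    wt(res$motif$enrichment, "logo_enrichment_log2.tsv", rn = TRUE)
  }
  if (!is.null(res$structure))
    wt(res$structure$site_context, "site_structure.tsv")
  if (!is.null(res$variants)) {
    wt(res$variants$joined, "variants_joined.tsv")
    wt(res$variants$fold_curve, "variant_fold_curve.tsv")
  }

  inputs <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(
    key = c("seed", "completed_stages", "skipped_stages",
            paste0("md5.", list.files(input_dir, recursive = TRUE)),
            paste0("cfg.", setdiff(names(cfg), "column_map"))),
    value = c(cfg$rng_seed,
              paste(setdiff(c("ingest", "quantify", "cluster", "enrichment",
                              "motif", "structure", "variants"),
                            res$skipped), collapse = ","),
              paste(res$skipped, collapse = ","),
              unname(tools::md5sum(inputs)),
              vapply(cfg[setdiff(names(cfg), "column_map")],
                     function(v) paste(format(v), collapse = ","),
                     character(1))),
    stringsAsFactors = FALSE)
  tmp <- op(".manifest.tmp")
  utils::write.table(manifest, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  file.rename(tmp, op("manifest.tsv"))
  invisible(res)
}
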