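test_that("design generation produces the full crossed layout", {
  d <- generate_design(15, c("female", "male"), 3)
  expect_equal(nrow(d), 90)
  expect_equal(length(unique(d$run_id)), 90)
  expect_equal(length(unique(d$tissue)), 15)
  d1 <- generate_design(1, "female", 1)
  expect_equal(nrow(d1), 1)
})

test_that("simulations are pure functions of the seed", {
  a <- simulate_atlas(n_tissues = 3, n_sites = 120, n_proteins = 40,
                      planted_per_tissue = 3, n_structure_proteins = 3,
                      seed = 17)
  b <- simulate_atlas(n_tissues = 3, n_sites = 120, n_proteins = 40,
                      planted_per_tissue = 3, n_structure_proteins = 3,
                      seed = 17)
  expect_identical(a$report, b$report)
  expect_identical(a$proteome, b$proteome)
  expect_identical(a$structures, b$structures)
  expect_identical(a$variants, b$variants)
  c2 <- simulate_atlas(n_tissues = 3, n_sites = 120, n_proteins = 40,
                       planted_per_tissue = 3, n_structure_proteins = 3,
                       seed = 18)
  expect_false(identical(a$report, c2$report))
})

test_that("missingness decreases across intensity terciles", {
  sim <- simulate_atlas(n_tissues = 5, n_sites = 2000, n_proteins = 300,
                        planted_per_tissue = 5, n_structure_proteins = 2,
                        seed = 19)
  x <- as_acetyl_sites(sim$report, sim$design)
  m <- build_matrix(collapse_unique_sites(filter_acetyl_sites(x)))
  st <- sim$truth$site_table
  base <- st$base_abundance[match(rownames(m$values), st$collapse_key)]
  terc <- cut(base, quantile(base, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
              labels = FALSE)
  # restrict to expressed cells: compare overall row missingness by tercile
  miss <- rowMeans(is.na(m$values))
  rates <- tapply(miss, terc, mean)
  expect_true(rates[1] > rates[2] && rates[2] > rates[3])
})

test_that("with no planted filter failures every row passes the identification filter", {
  sim <- simulate_atlas(n_tissues = 2, n_sites = 100, n_proteins = 30,
                        planted_per_tissue = 2, n_structure_proteins = 2,
                        filter_fail_fraction = 0, dup_fraction = 0, seed = 20)
  x <- as_acetyl_sites(sim$report, sim$design)
  expect_equal(nrow(filter_acetyl_sites(x)$meta), nrow(sim$report))
})

test_that("planted pLDDT values survive the PDB write-parse round trip", {
  sim <- simulate_atlas(n_tissues = 2, n_sites = 80, n_proteins = 30,
                        planted_per_tissue = 2, n_structure_proteins = 2,
                        seed = 21)
  p <- names(sim$structures)[1]
  f <- tempfile(fileext = ".pdb")
  write_pdb(sim$structures[[p]], f)
  pl <- plddt_per_residue(parse_pdb(f))
  L <- nchar(sim$proteome[[p]])
  expect_equal(unname(pl[as.character(1:L)]), sim$truth$plddt[[p]],
               tolerance = 1e-6)
  unlink(f)
})

test_that("generated ontology is acyclic and closure of a leaf is its ancestor path", {
  sim <- simulate_atlas(n_tissues = 2, n_sites = 80, n_proteins = 30,
                        planted_per_tissue = 2, n_structure_proteins = 2,
                        seed = 22)
  dag <- ontology_dag(sim$ontology_edges)   # construction validates acyclicity
  anc <- term_ancestors(dag)
  leaf <- setdiff(dag$terms, sim$ontology_edges$parent)[1]
  expect_setequal(anc[[leaf]], bf_ancestors(sim$ontology_edges, leaf))
  expect_true("ROOT" %in% anc[[leaf]])
})

test_that("written inputs round-trip through the file readers", {
  sim <- simulate_atlas(n_tissues = 2, n_sites = 60, n_proteins = 25,
                        planted_per_tissue = 2, n_structure_proteins = 2,
                        seed = 23)
  dir <- tempfile()
  write_atlas_inputs(sim, dir)
  design <- read_sample_design(file.path(dir, "design.tsv"))
  expect_equal(design$run_id, sim$design$run_id)
  sites <- read_site_report(file.path(dir, "report.tsv"), design)
  expect_equal(nrow(sites$meta), nrow(sim$report))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  expect_setequal(names(ann), names(sim$annotations))
  dag <- read_ontology(file.path(dir, "ontology_edges.tsv"))
  expect_setequal(dag$terms, ontology_dag(sim$ontology_edges)$terms)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(sim$variants))
  unlink(dir, recursive = TRUE)
})

test_that("OBO-format ontologies parse their is_a stanzas", {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:0000002", "name: child",
               "is_a: GO:0000001 ! parent", "",
               "[Term]", "id: GO:0000001", "name: root", "",
               "[Typedef]", "id: part_of"), f)
  dag <- read_ontology(f)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002"))
  expect_equal(term_ancestors(dag)[["GO:0000002"]], "GO:0000001")
  unlink(f)
})
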