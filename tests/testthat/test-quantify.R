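test_that("matrix construction treats zero intensity as missing", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 3)
  inten <- matrix(c(8, 0, 2, 4, NA, 16), 2, byrow = TRUE,
                  dimnames = list(NULL, d$run_id))
  x <- make_sites(d, c("P1_K1", "P2_K2"), intensities = inten)
  m <- build_matrix(x)
  expect_true(is.na(m$values[1, 2]))
  expect_equal(m$values[1, 1], 8)
  expect_equal(sum(is.na(m$values)), 2)
})

test_that("detection requires min replicates within one tissue and sex", {
  d <- tiny_design(tissues = c("liver", "brain"))
  v <- matrix(NA_real_, 3, nrow(d), dimnames = list(
    c("P1_K1", "P2_K2", "P3_K3"), d$run_id))
  # site 1: 2 of 3 female-liver replicates -> retained, detected in liver
  v["P1_K1", c("run_liver_female_1", "run_liver_female_2")] <- 100
  # site 2: exactly once in each tissue x sex -> removed
  v["P2_K2", c("run_liver_female_1", "run_liver_male_1",
               "run_brain_female_1", "run_brain_male_1")] <- 100
  # site 3: fully observed -> retained everywhere
  v["P3_K3", ] <- 100
  m <- make_abundance(v, d, log2 = FALSE)
  out <- detection_filter(m)
  expect_equal(rownames(out$matrix$values), c("P1_K1", "P3_K3"))
  expect_true(out$detection$detected["P1_K1", "liver"])
  expect_false(out$detection$detected["P1_K1", "brain"])
  expect_equal(unname(out$detection$n_tissues_detected["P3_K3"]), 2)
})

test_that("detection filter is monotone in added observations", {
  d <- tiny_design(tissues = c("liver", "brain"))
  set.seed(11)
  v <- matrix(ifelse(runif(20 * nrow(d)) < 0.4, 100, NA), 20,
              dimnames = list(sprintf("S%02d", 1:20), d$run_id))
  kept1 <- rownames(detection_filter(make_abundance(v, d, FALSE))$matrix$values)
  v2 <- v
  v2[is.na(v2) & runif(length(v2)) < 0.3] <- 100   # add observations
  kept2 <- rownames(detection_filter(make_abundance(v2, d, FALSE))$matrix$values)
  expect_true(all(kept1 %in% kept2))
})

test_that("log2 transform maps values and preserves missing", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 3)
  v <- matrix(c(8, 1, NA), 1, dimnames = list("S1", d$run_id))
  m <- log2_transform(make_abundance(v, d, log2 = FALSE))
  expect_equal(unname(m$values[1, 1:2]), c(3, 0))
  expect_true(is.na(m$values[1, 3]))
  bad <- make_abundance(matrix(c(-1, 2, 3), 1,
                               dimnames = list("S1", d$run_id)), d, FALSE)
  expect_error(log2_transform(bad), "onpositive")
})

test_that("median normalization aligns runs to the tissue pooled median, shift-only", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 2)
  v <- matrix(c(19, 21,
                21, 23), 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), d$run_id))
  m <- median_normalize(make_abundance(v, d))
  # run medians 20 and 22, pooled median 21 -> shifts +1 and -1
  expect_equal(unname(attr(m, "shifts")), c(1, -1))
  expect_equal(unname(m$values[, 1]), c(20, 22))
  # within-run differences preserved
  expect_equal(diff(m$values[, 1]), diff(v[, 1]))
  # already-aligned matrix unchanged
  m2 <- median_normalize(m)
  expect_equal(m2$values, m$values)
})

test_that("single-run tissue gets zero shift", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 1)
  v <- matrix(c(20, 22), 2, 1, dimnames = list(c("S1", "S2"), d$run_id))
  m <- median_normalize(make_abundance(v, d))
  expect_equal(unname(attr(m, "shifts")), 0)
})

test_that("imputation draws match the downshifted normal and leave observed cells intact", {
  n_miss <- 10000
  d <- data.frame(run_id = sprintf("r%05d", seq_len(3 + n_miss)),
                  tissue = "liver", sex = "female",
                  replicate = seq_len(3 + n_miss), enriched = TRUE)
  v <- matrix(c(19, 20, 21, rep(NA_real_, n_miss)), 1,
              dimnames = list("S1", d$run_id))   # mu = 20, sd = 1
  cfg <- atlas_config(rng_seed = 99)
  m <- impute_left_shifted(make_abundance(v, d), cfg)
  draws <- m$values[1, m$imputed_mask[1, ]]
  expect_equal(length(draws), n_miss)
  expect_equal(mean(draws), 18.2, tolerance = 0.03 / 18.2)
  expect_equal(sd(draws), 0.3, tolerance = 0.02 / 0.3)
  ks <- suppressWarnings(ks.test(draws, "pnorm", 18.2, 0.3))
  expect_gt(ks$p.value, 0.01)
  expect_equal(unname(m$values[1, 1:3]), c(19, 20, 21))
  # determinism: identical seeds give identical draws
  m2 <- impute_left_shifted(make_abundance(v, d), cfg)
  expect_identical(m$values, m2$values)
})

test_that("imputation refuses rows with fewer than two observed values", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 3)
  v <- matrix(c(20, NA, NA), 1, dimnames = list("S1", d$run_id))
  expect_error(impute_left_shifted(make_abundance(v, d)), "detection_filter")
})

test_that("tissue-sex summarization prefers observed means and falls back to imputed", {
  d <- tiny_design(tissues = "liver", sexes = "female", replicates = 3)
  obs <- matrix(c(3, 5, NA,
                  NA, NA, NA), 2, byrow = TRUE,
                dimnames = list(c("S1", "S2"), d$run_id))
  imp <- matrix(c(3, 5, 1,
                  7, 8, 9), 2, byrow = TRUE,
                dimnames = list(c("S1", "S2"), d$run_id))
  det <- make_abundance(obs, d)
  impm <- make_abundance(imp, d)
  s <- summarize_tissue_sex(det, impm)
  expect_equal(unname(s["S1", "liver.female"]), 4)  # imputed 1 ignored
  expect_equal(unname(s["S2", "liver.female"]), 8)  # all-missing -> imputed mean
  expect_false(anyNA(s))
})

test_that("row standardization gives mean zero, unit sd, and is idempotent", {
  x <- matrix(c(1, 2, 3,
                5, 5, 5), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("c1", "c2", "c3")))
  z <- suppressWarnings(standardize_rows(x))
  expect_equal(unname(rowMeans(z)), c(0, 0))
  expect_equal(unname(sqrt(rowMeans(z^2))), c(1, 0))  # population sd
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_warning(standardize_rows(x), "constant")
  expect_equal(suppressWarnings(standardize_rows(z)), z)  # z of z = z
})
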