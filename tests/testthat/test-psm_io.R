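test_that("digest type encodes terminus conformity as full/half/none = 2/1/0", {
  enc <- encode_digest_type(c(TRUE, TRUE, FALSE, FALSE),
                            c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(as.character(enc$category), c("full", "half", "half", "none"))
  expect_equal(enc$code, c(2L, 1L, 1L, 0L))
  expect_equal(digest_code(c("full", "half", "none")), c(2, 1, 0))
  expect_equal(digest_code(c(2, 0)), c(2, 0))
  expect_error(digest_code("partial"), "digest_type")
})

test_that("a well-formed table reads back with order and fields intact", {
  coll <- make_coll(xcorr = c(3.1, 2.0, 0.5),
                    is_decoy = c(FALSE, FALSE, TRUE),
                    digest_type = c(2, 1, 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(coll, path)
  back <- read_psm_table(path)
  expect_s3_class(back, "psm_collection")
  expect_equal(nrow(back), 3L)
  expect_equal(back$psm_id, coll$psm_id)
  expect_identical(back$xcorr, coll$xcorr)
  expect_identical(back$digest_type, coll$digest_type)
  expect_identical(back$is_decoy, coll$is_decoy)
  # round trip again: bit-exact
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("decoy status can come from an accession prefix", {
  coll <- make_coll(xcorr = c(3, 2, 1), is_decoy = c(FALSE, FALSE, FALSE))
  df <- as.data.frame(coll)
  df$is_decoy <- NULL
  df$protein <- c("sp|P1", "DECOY_sp|P2", "sp|P3")
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_psm_table(path, psm_dialect(accession_column = "protein",
                                           decoy_prefix = "DECOY_"))
  expect_identical(back$is_decoy, c(FALSE, TRUE, FALSE))
})

test_that("missing mandatory columns and empty tables are hard errors", {
  coll <- make_coll(xcorr = c(3, 2), is_decoy = c(FALSE, TRUE))
  df <- as.data.frame(coll)
  df$is_decoy <- as.integer(df$is_decoy)
  df$sprank <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_psm_table(path), "sprank")

  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df[0, ], path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_psm_table(path2), "empty")
})

test_that("rows with unparseable numeric fields are rejected with a count", {
  coll <- make_coll(xcorr = c(3, 2, 1), is_decoy = c(FALSE, TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(coll, path)
  lines <- readLines(path)
  lines[3] <- sub("^(p002\ts002\tNA\t1\t)2", "\\1not_a_number", lines[3])
  writeLines(lines, path)
  expect_message(back <- read_psm_table(path), "1 row")
  expect_equal(nrow(back), 2L)
  expect_equal(attr(back, "n_rejected"), 1L)
})

test_that("feature matrix is z-scored with population variance, then weighted", {
  coll <- make_coll(xcorr = c(1, 2, 3), is_decoy = c(FALSE, FALSE, TRUE))
  cfg <- preprocess_config(attribute_weights = c(xcorr = 1),
                           include_columns = "xcorr")
  X <- build_feature_matrix(coll, cfg)
  expect_equal(as.numeric(X), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(as.numeric(X), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  # weight 2 doubles the standardized values
  X2 <- build_feature_matrix(coll, preprocess_config(
    attribute_weights = c(xcorr = 2), include_columns = "xcorr"))
  expect_equal(as.numeric(X2), 2 * as.numeric(X), tolerance = 1e-12)
})

test_that("default weights double xcorr, delta_cn and digest_type only", {
  cfg <- preprocess_config()
  expect_equal(unname(cfg$attribute_weights[c("xcorr", "delta_cn",
                                              "digest_type")]), c(2, 2, 2))
  expect_equal(unname(cfg$attribute_weights[c("ions", "sprank",
                                              "calc_neutral_pep_mass")]),
               c(1, 1, 1))
})

test_that("constant columns become zero and normalization is idempotent", {
  coll <- make_coll(xcorr = c(5, 5, 5), is_decoy = c(FALSE, FALSE, TRUE))
  cfg <- preprocess_config(attribute_weights = c(xcorr = 1),
                           include_columns = "xcorr")
  X <- build_feature_matrix(coll, cfg)
  expect_equal(as.numeric(X), c(0, 0, 0))

  coll2 <- make_coll(xcorr = rnorm(20), is_decoy = rep(c(FALSE, TRUE), 10))
  Z1 <- build_feature_matrix(coll2, cfg)
  coll3 <- coll2
  coll3$xcorr <- as.numeric(Z1)
  Z2 <- build_feature_matrix(coll3, cfg)
  expect_equal(as.numeric(Z2), as.numeric(Z1), tolerance = 1e-9)
})

test_that("non-constant columns have mean 0 and unit variance before weighting", {
  set.seed(7)
  coll <- make_coll(xcorr = rnorm(50, 2, 0.5), is_decoy = rep(c(FALSE, TRUE), 25),
                    digest_type = sample(0:2, 50, replace = TRUE))
  X <- build_feature_matrix(coll)
  W <- attr(X, "attribute_weights")
  Zn <- sweep(unclass(X), 2L, W, `/`)
  keep <- attr(X, "column_sds") > 0
  expect_true(all(abs(colMeans(Zn[, keep])) < 1e-9))
  expect_true(all(abs(colMeans(Zn[, keep]^2) - 1) < 1e-6))
  expect_identical(colnames(X), preprocess_config()$include_columns)
})
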