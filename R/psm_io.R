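#' @title PSM table input/output and feature construction
#' @name psm_io
#' @description
#' Functions to read and write tab-separated PSM (peptide-spectrum match)
#' tables, encode the tryptic digest type, and build the normalized,
#' attribute-weighted feature matrix used by the classifier and the
#' silhouette index.
NULL

# The six canonical PSM attributes, in canonical column order.
.fcr_attributes <- c("xcorr", "delta_cn", "ions", "sprank",
                     "calc_neutral_pep_mass", "digest_type")

.fcr_mandatory <- c("psm_id", "spectrum_ref", .fcr_attributes)

#' Table dialect for PSM input
#'
#' Describes how a tab-separated PSM table encodes its decoy status. Decoys
#' are flagged either by an explicit 0/1 column or by an accession prefix
#' (for example `"DECOY_"`) on a protein/accession column.
#'
#' @param sep Field separator (default tab).
#' @param decoy_column Name of a 0/1 (or TRUE/FALSE) column flagging decoys.
#'   Ignored when `accession_column` is given.
#' @param accession_column Optional name of a protein/accession column; rows
#'   whose accession starts with `decoy_prefix` are decoys.
#' @param decoy_prefix Accession prefix marking decoys (used with
#'   `accession_column`).
#' @param truth_column Name of the optional synthetic ground-truth column.
#' @return A list of class `"psm_dialect"`.
#' @export
psm_dialect <- function(sep = "\t", decoy_column = "is_decoy",
                        accession_column = NULL, decoy_prefix = "DECOY_",
                        truth_column = "truth") {
  structure(list(sep = sep, decoy_column = decoy_column,
                 accession_column = accession_column,
                 decoy_prefix = decoy_prefix,
                 truth_column = truth_column),
            class = "psm_dialect")
}

#' Preprocessing configuration
#'
#' Attribute weights applied after per-column standardization. X-correlation,
#' delta-cn and the digest type carry a weight of 2.0 by default; the other
#' attributes a weight of 1.0.
#'
#' @param attribute_weights Named numeric vector of positive per-column
#'   weights.
#' @param include_columns Ordered character vector of feature columns.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(
    attribute_weights = c(xcorr = 2, delta_cn = 2, ions = 1, sprank = 1,
                          calc_neutral_pep_mass = 1, digest_type = 2),
    include_columns = .fcr_attributes) {
  if (length(include_columns) == 0L)
    stop("no feature columns selected (q = 0)")
  w <- rep(1, length(include_columns))
  names(w) <- include_columns
  known <- intersect(names(attribute_weights), include_columns)
  w[known] <- attribute_weights[known]
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all attribute weights must be positive and finite")
  structure(list(attribute_weights = w, include_columns = include_columns),
            class = "preprocess_config")
}

#' Construct a PSM collection from a data frame
#'
#' Validates column presence and types and attaches the
#' `"psm_collection"` class. `digest_type` may be given as the category
#' labels `full`/`half`/`none` or as the numeric codes 2/1/0; it is stored
#' as the numeric code.
#'
#' @param df A data frame with columns `psm_id`, `spectrum_ref`, `xcorr`,
#'   `delta_cn`, `ions`, `sprank`, `calc_neutral_pep_mass`, `digest_type`,
#'   `is_decoy`, and optionally `peptide` and `truth`.
#' @return The validated data frame with class `"psm_collection"`.
#' @export
psm_collection <- function(df) {
  missing_cols <- setdiff(c(.fcr_mandatory, "is_decoy"), names(df))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) stop("empty PSM table")
  df$digest_type <- digest_code(df$digest_type)
  df$is_decoy <- as.logical(df$is_decoy)
  if (any(is.na(df$is_decoy))) stop("is_decoy contains missing values")
  if ("truth" %in% names(df)) {
    df$truth <- as.logical(df$truth)
    if (any(df$truth & df$is_decoy))
      stop("truth can be TRUE only for target records")
  }
  if (!"peptide" %in% names(df)) df$peptide <- NA_character_
  rownames(df) <- NULL
  class(df) <- c("psm_collection", "data.frame")
  df
}

#' @export
print.psm_collection <- function(x, ...) {
  cat(sprintf("PSM collection: %d PSMs (%d targets, %d decoys)%s\n",
              nrow(x), length(target_indices(x)), length(decoy_indices(x)),
              if ("truth" %in% names(x)) " [synthetic truth present]" else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Indices of target / decoy PSMs
#'
#' @param coll A `psm_collection`.
#' @return Integer row indices of target (`target_indices`) or decoy
#'   (`decoy_indices`) PSMs.
#' @export
target_indices <- function(coll) which(!coll$is_decoy)

#' @rdname target_indices
#' @export
decoy_indices <- function(coll) which(coll$is_decoy)

#' Class labels y
#'
#' @param coll A `psm_collection`.
#' @return +1 for targets, -1 for decoys, per record.
#' @export
psm_labels <- function(coll) ifelse(coll$is_decoy, -1, 1)

#' Encode the tryptic digest type of a peptide
#'
#' A peptide is full-digested when both termini satisfy the enzyme
#' specificity rule, half-digested when exactly one does, and none-digested
#' otherwise. The numeric codes are 2, 1 and 0 respectively.
#'
#' @param n_term_conforms,c_term_conforms Logical vectors: does each
#'   terminus conform to the enzyme specificity rule?
#' @return A data frame with columns `category` (factor with levels
#'   `none` < `half` < `full`) and `code` (0, 1 or 2).
#' @export
encode_digest_type <- function(n_term_conforms, c_term_conforms) {
  stopifnot(is.logical(n_term_conforms), is.logical(c_term_conforms),
            length(n_term_conforms) == length(c_term_conforms))
  code <- as.integer(n_term_conforms) + as.integer(c_term_conforms)
  data.frame(category = factor(c("none", "half", "full")[code + 1L],
                               levels = c("none", "half", "full")),
             code = code)
}

#' Numeric digest-type codes from labels or codes
#'
#' @param x Character labels in `{full, half, none}` or numeric codes in
#'   `{2, 1, 0}`.
#' @return Numeric codes 2/1/0.
#' @export
digest_code <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, 2))) stop("digest_type codes must be 0, 1 or 2")
    return(as.numeric(x))
  }
  x <- as.character(x)
  map <- c(full = 2, half = 1, none = 0, "2" = 2, "1" = 1, "0" = 0)
  out <- unname(map[x])
  if (any(is.na(out)))
    stop("digest_type must be one of full/half/none (or 2/1/0); got: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Read a PSM table
#'
#' Reads a tab-separated PSM table with a header row. Rows with unparseable
#' numeric attribute fields are dropped; the number of rejected rows is
#' reported via a message and stored in the `"n_rejected"` attribute.
#'
#' @param path Path to the table.
#' @param dialect A [psm_dialect()] describing the decoy encoding.
#' @return A [psm_collection()] in original row order.
#' @export
read_psm_table <- function(path, dialect = psm_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty PSM table: ", path)
  missing_cols <- setdiff(.fcr_mandatory, names(raw))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))

  if (!is.null(dialect$accession_column)) {
    if (!dialect$accession_column %in% names(raw))
      stop("missing accession column: ", dialect$accession_column)
    raw$is_decoy <- startsWith(raw[[dialect$accession_column]],
                               dialect$decoy_prefix)
  } else {
    if (!dialect$decoy_column %in% names(raw))
      stop("missing mandatory column(s): ", dialect$decoy_column)
    raw$is_decoy <- .parse_flag(raw[[dialect$decoy_column]])
  }

  num_cols <- setdiff(.fcr_attributes, "digest_type")
  parsed <- lapply(raw[num_cols], function(v) suppressWarnings(as.numeric(v)))
  bad <- Reduce(`|`, lapply(parsed, is.na))
  bad <- bad | !(raw$digest_type %in% c("full", "half", "none", "0", "1", "2"))
  if (any(bad)) {
    message(sum(bad), " row(s) with unparseable fields rejected")
    raw <- raw[!bad, , drop = FALSE]
    parsed <- lapply(parsed, function(v) v[!bad])
    if (nrow(raw) == 0L) stop("no parseable rows in PSM table: ", path)
  }
  df <- data.frame(psm_id = raw$psm_id, spectrum_ref = raw$spectrum_ref,
                   stringsAsFactors = FALSE)
  df$peptide <- if ("peptide" %in% names(raw)) raw$peptide else NA_character_
  df$is_decoy <- raw$is_decoy
  for (cn in num_cols) df[[cn]] <- parsed[[cn]]
  df$digest_type <- digest_code(raw$digest_type)
  if (dialect$truth_column %in% names(raw))
    df$truth <- .parse_flag(raw[[dialect$truth_column]])
  coll <- psm_collection(df)
  attr(coll, "n_rejected") <- sum(bad)
  coll
}

.parse_flag <- function(v) {
  out <- rep(NA, length(v))
  out[v %in% c("1", "TRUE", "true", "T")] <- TRUE
  out[v %in% c("0", "FALSE", "false", "F")] <- FALSE
  if (any(is.na(out))) stop("flag column must be 0/1 or TRUE/FALSE")
  out
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: emits the tab-separated dialect with
#' `is_decoy`/`truth` as 0/1 and `digest_type` as the numeric code.
#'
#' @param coll A `psm_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(coll, path) {
  out <- as.data.frame(coll)
  cols <- c("psm_id", "spectrum_ref", "peptide", "is_decoy", .fcr_attributes)
  if ("truth" %in% names(out)) cols <- c(cols, "truth")
  out <- out[cols]
  out$is_decoy <- as.integer(out$is_decoy)
  if ("truth" %in% names(out)) out$truth <- as.integer(out$truth)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the normalized, weighted feature matrix
#'
#' Each selected attribute column is standardized to zero mean and unit
#' variance over all PSMs (targets and decoys jointly, population 1/N
#' variance) and then multiplied by its attribute weight. Constant columns
#' map to all-zero columns. The recorded means, standard deviations and
#' weights are stored as attributes for audit.
#'
#' @param coll A `psm_collection`.
#' @param cfg A [preprocess_config()].
#' @return A numeric matrix of class `"feature_matrix"`, rows aligned with
#'   `coll`, with attributes `column_means`, `column_sds` and
#'   `attribute_weights`.
#' @export
build_feature_matrix <- function(coll, cfg = preprocess_config()) {
  stopifnot(inherits(coll, "psm_collection"))
  if (length(cfg$include_columns) == 0L) stop("no feature columns selected")
  absent <- setdiff(cfg$include_columns, names(coll))
  if (length(absent) > 0L)
    stop("feature column(s) not in collection: ", paste(absent, collapse = ", "))
  X <- as.matrix(as.data.frame(coll)[cfg$include_columns])
  storage.mode(X) <- "double"
  n <- nrow(X)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))  # population variance
  scale_by <- ifelse(sdev > 0, sdev, Inf)     # constant column -> all zero
  Z <- sweep(sweep(X, 2L, mu), 2L, scale_by, `/`)
  Z <- sweep(Z, 2L, cfg$attribute_weights, `*`)
  structure(Z, column_means = mu, column_sds = sdev,
            attribute_weights = cfg$attribute_weights,
            class = c("feature_matrix", class(Z)))
}
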