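#' Validate a count matrix
#'
#' A count matrix is a base integer matrix of read counts with unique gene
#' ids as rownames and unique sample ids as colnames. All entries must be
#' non-negative integers (integer storage or whole doubles).
#'
#' @param counts Matrix to validate.
#' @return The validated matrix with integer storage mode, invisibly usable
#'   downstream.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(!is.finite(counts))) stop("counts contain non-finite values")
  if (any(counts < 0)) stop("counts contain negative values")
  if (is.double(counts) && any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count %s at gene '%s', sample '%s'",
                 format(counts[bad[1], bad[2]]),
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a gene x sample count matrix
#'
#' Two on-disk formats are supported: a tab-separated table (`tsv`) with a
#' header row of sample ids and gene ids in the first column, and 1-based
#' MatrixMarket coordinate format (`mtx`) with plain-text sidecar files
#' `<path>.rownames` and `<path>.colnames` holding one id per line
#' (genes = rows, the de facto genomics convention).
#'
#' @param path File path.
#' @param format `"tsv"` or `"mtx"`.
#' @return Validated integer count matrix.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character")
    if (ncol(tab) < 2) stop("malformed header in ", path,
                            ": need a gene-id column plus >= 1 sample column")
    gene_ids <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    if (any(is.na(num) & !is.na(vals))) {
      bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric cell '%s' at gene '%s' (row %d), sample '%s'",
                   vals[bad[1], bad[2]], gene_ids[bad[1]], bad[1] + 1L,
                   colnames(vals)[bad[2]]))
    }
    if (any(num != round(num), na.rm = TRUE)) {
      bad <- which(num != round(num), arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer count '%s' at gene '%s' (row %d), sample '%s'",
                   vals[bad[1], bad[2]], gene_ids[bad[1]], bad[1] + 1L,
                   colnames(vals)[bad[2]]))
    }
    dimnames(num) <- list(gene_ids, colnames(vals))
    validate_counts(num)
  } else {
    rn_path <- paste0(path, ".rownames")
    cn_path <- paste0(path, ".colnames")
    if (!file.exists(rn_path) || !file.exists(cn_path))
      stop("mtx sidecar files missing: expected ", rn_path, " and ", cn_path)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rn_path)
    cn <- readLines(cn_path)
    if (length(rn) != nrow(m))
      stop("rowname sidecar has ", length(rn), " ids for ", nrow(m), " rows")
    if (length(cn) != ncol(m))
      stop("colname sidecar has ", length(cn), " ids for ", ncol(m), " columns")
    dimnames(m) <- list(rn, cn)
    validate_counts(m)
  }
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; the tsv writer round-trips byte-identically
#' (UTF-8, tab separator, first column `gene_id`).
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"mtx"`.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  counts <- validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' Build and validate sample metadata
#'
#' @param df Data frame with columns `sample_id`, `maternal_morph`,
#'   `paternal_morph` (each `"PL"` or `"SB"`), `time_point` (150 or 200,
#'   tau-somite units), `family_id`, and optionally `batch`.
#' @return Data frame with derived `cross_type` (maternal x paternal) and
#'   `group` (`cross_type` x `time_point`) columns.
#' @export
as_sample_metadata <- function(df) {
  req <- c("sample_id", "maternal_morph", "paternal_morph", "time_point", "family_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("metadata missing required columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (col in c("maternal_morph", "paternal_morph")) {
    bad <- setdiff(unique(as.character(df[[col]])), MORPHS)
    if (length(bad))
      stop("unknown morph code in ", col, ": ", paste(bad, collapse = ", "))
  }
  tp <- suppressWarnings(as.integer(as.character(df$time_point)))
  bad_tp <- unique(df$time_point[is.na(tp) | !tp %in% TIME_POINTS])
  if (length(bad_tp))
    stop("unknown time point: ", paste(bad_tp, collapse = ", "),
         " (expected ", paste(TIME_POINTS, collapse = " or "), ")")
  df$time_point <- tp
  if (is.null(df$batch)) df$batch <- NA_character_
  df$cross_type <- paste0(df$maternal_morph, "x", df$paternal_morph)
  df$group <- paste(df$cross_type, df$time_point, sep = "_")
  rownames(df) <- NULL
  df
}

#' Read sample metadata from a delimited file
#'
#' Accepts tab- or comma-separated files (sniffed from the header line).
#'
#' @param path File path.
#' @return Validated metadata data frame (see [as_sample_metadata()]).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  as_sample_metadata(read.delim(path, sep = sep, stringsAsFactors = FALSE))
}

#' Check a count matrix against its metadata and the expected cross design
#'
#' Verifies one metadata row per sample, reports replicate counts per
#' cross-type x time-point group, errors on groups that are entirely absent
#' from the full 4 x 2 design, and flags groups below a minimum replicate
#' number.
#'
#' @param counts Count matrix.
#' @param meta Metadata data frame.
#' @param min_replicates Minimum replicates per group before flagging
#'   (default 3).
#' @param require_full_design Error when any of the 8 cross-type x time-point
#'   groups has no samples (default TRUE).
#' @return Data frame with columns `group`, `cross_type`, `time_point`,
#'   `n_replicates`, `flagged`; sample order has no effect on the result.
#' @export
validate_design <- function(counts, meta, min_replicates = 3L,
                            require_full_design = TRUE) {
  counts <- validate_counts(counts)
  meta <- as_sample_metadata(meta)
  no_meta <- setdiff(colnames(counts), meta$sample_id)
  if (length(no_meta))
    stop("samples without metadata: ", paste(no_meta, collapse = ", "))
  no_counts <- setdiff(meta$sample_id, colnames(counts))
  if (length(no_counts))
    stop("metadata rows without samples: ", paste(no_counts, collapse = ", "))
  groups <- analysis_groups()
  n <- vapply(groups, function(g) sum(meta$group == g), integer(1))
  absent <- groups[n == 0L]
  if (require_full_design && length(absent))
    stop("design is missing group(s): ", paste(absent, collapse = ", "))
  out <- data.frame(
    group = groups,
    cross_type = sub("_[0-9]+$", "", groups),
    time_point = as.integer(sub("^.*_", "", groups)),
    n_replicates = unname(n),
    flagged = unname(n < min_replicates),
    stringsAsFactors = FALSE
  )
  if (any(out$flagged & out$n_replicates > 0))
    warning("under-replicated group(s): ",
            paste(out$group[out$flagged & out$n_replicates > 0], collapse = ", "))
  out
}

#' Write a tabular result deterministically
#'
#' Tab-separated, no quoting, fixed column order as supplied; identical
#' input yields byte-identical files.
#'
#' @param records Non-empty data frame or matrix.
#' @param path Output path.
#' @export
write_table_tsv <- function(records, path) {
  if (is.matrix(records)) records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.data.frame(records) || nrow(records) == 0L || ncol(records) == 0L)
    stop("records must be a non-empty data frame")
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seed and md5 digests of the input files of a
#' pipeline stage, for reproducibility of stochastic stages.
#'
#' @param path Output JSON path.
#' @param config Named list of stage parameters.
#' @param seed Integer seed used.
#' @param inputs Character vector of input file paths to digest.
#' @export
write_manifest <- function(path, config = list(), seed = NA_integer_,
                           inputs = character()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(config = config, seed = seed, input_md5 = digests,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
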