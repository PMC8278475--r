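#' Construct an omics matrix
#'
#' The universal carrier for one omics block: a feature-by-sample numeric
#' matrix with per-feature type tags and per-sample metadata.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Row names are feature IDs, column names are sample barcodes/IDs.
#' @param feature_type Character scalar or per-feature vector; one of
#'   `"protein_coding"`, `"ncRNA"`, `"cpg_probe"`, `"methylated_gene"`.
#' @param data_scale One of `"counts"`, `"beta"`, `"log2_expr"`.
#' @param samples Optional data frame of sample metadata as returned by
#'   [parse_tcga_barcode()]; defaults to parsing the column names.
#' @return An object of class `omics_matrix`: a list with elements
#'   `values`, `feature_type`, `data_scale`, `samples`.
#' @export
omics_matrix <- function(values,
                         feature_type = c("protein_coding", "ncRNA",
                                          "cpg_probe", "methylated_gene"),
                         data_scale = c("counts", "beta", "log2_expr"),
                         samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature IDs as row names and sample IDs as column names")
  if (length(feature_type) == 1L)
    feature_type <- match.arg(feature_type)
  else if (length(feature_type) != nrow(values))
    stop("'feature_type' must be scalar or one tag per feature")
  data_scale <- match.arg(data_scale)
  if (data_scale == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("beta-scale values must lie in [0, 1]")
  }
  if (is.null(samples)) samples <- parse_tcga_barcode(colnames(values))
  if (nrow(samples) != ncol(values))
    stop("'samples' must have one row per matrix column")
  structure(
    list(values = values,
         feature_type = rep_len(feature_type, nrow(values)),
         data_scale = data_scale,
         samples = samples),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples [%s, %s scale]\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$feature_type), collapse = "/"), x$data_scale))
  if (!all(is.na(x$samples$label)))
    cat(sprintf("  labels: %d tumor (+1), %d normal (-1)\n",
                sum(x$samples$label == 1, na.rm = TRUE),
                sum(x$samples$label == -1, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Parse TCGA-style sample barcodes
#'
#' Extracts the patient ID (first three dash-separated fields) and the
#' two-digit sample type code (first two characters of the fourth field).
#' Code `"01"` is primary tumor, `"11"` solid tissue normal, `"06"`
#' metastatic. Barcodes with fewer than four fields get code `"unknown"`
#' with a warning.
#'
#' @param barcode Character vector of barcodes.
#' @return Data frame with columns `barcode`, `patient_id`,
#'   `sample_type_code`, `label` (`+1` tumor / `-1` normal / `NA`).
#' @examples
#' parse_tcga_barcode("TCGA-BH-A1ES-06A-12D-A244-05")
#' @export
parse_tcga_barcode <- function(barcode) {
  fields <- strsplit(barcode, "-", fixed = TRUE)
  patient_id <- vapply(fields, function(f) {
    if (length(f) >= 3L) paste(f[1:3], collapse = "-") else paste(f, collapse = "-")
  }, character(1))
  code <- vapply(fields, function(f) {
    if (length(f) >= 4L && nchar(f[[4]]) >= 2L) substr(f[[4]], 1L, 2L) else "unknown"
  }, character(1))
  if (any(code == "unknown"))
    warning(sprintf("%d barcode(s) have fewer than 4 fields; sample_type_code set to \"unknown\"",
                    sum(code == "unknown")))
  label <- ifelse(code == "01", 1L, ifelse(code == "11", -1L, NA_integer_))
  data.frame(barcode = barcode, patient_id = patient_id,
             sample_type_code = code, label = label,
             stringsAsFactors = FALSE)
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample barcodes, the first column holding
#' feature IDs, and numeric or empty (missing) cells. Duplicate feature
#' rows are read as-is; deduplication happens in [preprocess_features()].
#'
#' @param path Path to a tab-separated file.
#' @inheritParams omics_matrix
#' @return An [omics_matrix()].
#' @export
read_matrix_tsv <- function(path, feature_type, data_scale) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("matrix TSV needs a feature column and >= 1 sample column")
  sample_ids <- colnames(df)[-1L]
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample columns: ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature row %d, sample column '%s'",
                 bad[1, 1], sample_ids[bad[1, 2]]))
  rownames(num) <- df[[1L]]
  colnames(num) <- sample_ids
  omics_matrix(num, feature_type = feature_type, data_scale = data_scale)
}

#' Write an omics matrix to TSV
#'
#' Inverse of [read_matrix_tsv()]; missing values are written as empty cells.
#'
#' @param m An `omics_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  df <- data.frame(feature_id = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Keep primary-tumor and solid-normal samples and assign labels
#'
#' Retains samples with type code `"01"` (primary tumor, label `+1`) or
#' `"11"` (solid tissue normal, label `-1`); all other codes (metastatic
#' `"06"` among them) are dropped. When a patient contributes several
#' retained samples with the same code, the lexicographically smallest
#' full barcode survives. An explicit label table overrides barcode-derived
#' labels for non-TCGA data.
#'
#' @param m An `omics_matrix`.
#' @param labels Optional data frame with columns `sample_id` and `label`
#'   (`"tumor"`/`"normal"`), overriding barcode parsing.
#' @return A labeled `omics_matrix` with only tumor/normal samples.
#' @export
filter_and_label_samples <- function(m, labels = NULL) {
  stopifnot(inherits(m, "omics_matrix"))
  s <- m$samples
  if (!is.null(labels)) {
    idx <- match(s$barcode, labels$sample_id)
    lab <- labels$label[idx]
    s$label <- ifelse(lab == "tumor", 1L, ifelse(lab == "normal", -1L, NA_integer_))
    s$sample_type_code <- ifelse(s$label == 1L, "01",
                                 ifelse(s$label == -1L, "11", s$sample_type_code))
  }
  keep <- which(s$sample_type_code %in% c("01", "11"))
  s <- s[keep, , drop = FALSE]
  # one sample per (patient, code): lexicographically smallest barcode
  ord <- order(s$patient_id, s$sample_type_code, s$barcode)
  s <- s[ord, , drop = FALSE]
  s <- s[!duplicated(s[, c("patient_id", "sample_type_code")]), , drop = FALSE]
  if (!any(s$sample_type_code == "01")) stop("no primary tumor samples after filtering")
  if (!any(s$sample_type_code == "11")) stop("no normal samples after filtering")
  s$label <- ifelse(s$sample_type_code == "01", 1L, -1L)
  keep_cols <- match(s$barcode, colnames(m$values))
  omics_matrix(m$values[, keep_cols, drop = FALSE],
               feature_type = m$feature_type, data_scale = m$data_scale,
               samples = s)
}

#' Preprocess features: deduplicate, drop empty, impute, normalize
#'
#' Collapses duplicate feature IDs (first occurrence kept), removes
#' features missing in 100% of samples, mean-imputes partial missingness,
#' and quantile-normalizes expression-scale matrices across samples
#' (beta matrices, already bounded ratios, are left unnormalized).
#'
#' @param m An `omics_matrix`.
#' @param normalization `"quantile"` (default for counts/log2_expr) or
#'   `"none"`.
#' @return A complete, duplicate-free `omics_matrix`.
#' @export
preprocess_features <- function(m, normalization = c("quantile", "none")) {
  stopifnot(inherits(m, "omics_matrix"))
  normalization <- match.arg(normalization)
  v <- m$values
  ft <- m$feature_type
  dup <- duplicated(rownames(v))
  if (any(dup)) {
    v <- v[!dup, , drop = FALSE]
    ft <- ft[!dup]
  }
  all_missing <- rowSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    v <- v[!all_missing, , drop = FALSE]
    ft <- ft[!all_missing]
  }
  if (nrow(v) == 0L) stop("no features remain after preprocessing")
  if (anyNA(v)) {
    means <- rowMeans(v, na.rm = TRUE)
    idx <- which(is.na(v), arr.ind = TRUE)
    v[idx] <- means[idx[, 1L]]
  }
  if (normalization == "quantile" && m$data_scale != "beta") {
    dn <- dimnames(v)
    v <- limma::normalizeQuantiles(v)
    dimnames(v) <- dn
  }
  omics_matrix(v, feature_type = ft, data_scale = m$data_scale,
               samples = m$samples)
}

sample_key <- function(samples) {
  paste(samples$patient_id, samples$sample_type_code, sep = ".")
}

#' Assemble the triple dataset
#'
#' Restricts the protein-coding, ncRNA and methylation blocks to their
#' shared samples and aligns them on one label vector. Samples are joined
#' on patient ID plus sample type code (aliquot fields differ across
#' assays) and ordered by sorted key.
#'
#' @param pc,nc,meth Preprocessed, labeled `omics_matrix` blocks.
#' @return An object of class `triple_dataset`: list with `blocks`
#'   (named list of the three aligned blocks), `y` (labels in `{-1, +1}`)
#'   and `sample_ids`.
#' @export
assemble_triple <- function(pc, nc, meth) {
  blocks <- list(pc = pc, nc = nc, meth = meth)
  keys <- lapply(blocks, function(b) sample_key(b$samples))
  shared <- sort(Reduce(intersect, keys))
  if (length(shared) == 0L) stop("no samples shared across the three blocks")
  labs <- lapply(names(blocks), function(nm) {
    b <- blocks[[nm]]
    b$samples$label[match(shared, sample_key(b$samples))]
  })
  for (i in 2:3)
    if (!identical(labs[[1]], labs[[i]]))
      stop("conflicting labels for the same sample ID across blocks")
  y <- labs[[1]]
  if (length(unique(y)) < 2L) stop("both classes must be present in the shared samples")
  aligned <- lapply(blocks, function(b) {
    idx <- match(shared, sample_key(b$samples))
    om <- omics_matrix(b$values[, idx, drop = FALSE],
                       feature_type = b$feature_type, data_scale = b$data_scale,
                       samples = b$samples[idx, , drop = FALSE])
    colnames(om$values) <- shared
    om
  })
  structure(list(blocks = aligned, y = stats::setNames(y, shared),
                 sample_ids = shared),
            class = "triple_dataset")
}

#' @export
print.triple_dataset <- function(x, ...) {
  cat(sprintf("<triple_dataset> %d shared samples (%d tumor / %d normal)\n",
              length(x$y), sum(x$y == 1), sum(x$y == -1)))
  for (nm in names(x$blocks))
    cat(sprintf("  %-4s %6d features [%s]\n", nm, nrow(x$blocks[[nm]]$values),
                x$blocks[[nm]]$data_scale))
  invisible(x)
}

#' Read a CpG probe-to-gene manifest
#'
#' Two-column TSV in the 450K-manifest dialect: probe ID, then a
#' semicolon-separated gene list. Pairs are flattened and deduplicated;
#' probes with an empty gene field are dropped (count reported via message).
#'
#' @param path Path to the manifest TSV.
#' @return A `probe_gene_map`: data frame with columns `probe_id`, `gene_id`.
#' @export
read_probe_gene_map <- function(path) {
  lines <- readLines(path)
  if (length(lines) && startsWith(lines[1L], "probe_id")) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 1L | !nzchar(vapply(parts, `[`, "", 1L)))
  if (length(bad)) stop("malformed manifest line ", bad[1L])
  probes <- vapply(parts, `[`, "", 1L)
  genes <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  empty <- !nzchar(genes)
  if (any(empty))
    message(sum(empty), " probe(s) with empty gene field dropped")
  gl <- strsplit(genes[!empty], ";", fixed = TRUE)
  pairs <- data.frame(
    probe_id = rep(probes[!empty], lengths(gl)),
    gene_id = unlist(gl, use.names = FALSE),
    stringsAsFactors = FALSE)
  pairs <- pairs[nzchar(pairs$gene_id), , drop = FALSE]
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  structure(pairs, class = c("probe_gene_map", "data.frame"))
}

#' Write a probe-to-gene manifest
#'
#' @param map A `probe_gene_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_gene_map <- function(map, path) {
  genes <- vapply(split(map$gene_id, map$probe_id),
                  paste, "", collapse = ";")
  writeLines(c("probe_id\tgenes",
               paste(names(genes), genes, sep = "\t")), path)
  invisible(path)
}
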