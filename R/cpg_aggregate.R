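#' Aggregate CpG probe beta values into methylated-gene features
#'
#' Stage-1 feature selection. For each gene the methylated-gene value in a
#' sample is the arithmetic mean of the beta values of all CpG probes
#' mapped to that gene (non-missing entries only). A probe mapped to
#' several genes contributes to every one of them, so the many-to-many
#' probe-gene relation is preserved rather than treated as redundancy.
#' Probes in the map but absent from the matrix are ignored; genes left
#' with no present probe are omitted. On a 450K-scale input this reduces
#' hundreds of thousands of probe dimensions to gene scale. The step is
#' unsupervised (labels never enter), so it can be computed once outside
#' any cross-validation loop without leakage.
#'
#' @param meth An `omics_matrix` with `feature_type = "cpg_probe"` and
#'   beta scale.
#' @param map A `probe_gene_map` (columns `probe_id`, `gene_id`).
#' @return An `omics_matrix` with `feature_type = "methylated_gene"`,
#'   rows ordered by gene ID, plus a `provenance` attribute: data frame
#'   `gene_id`, `n_probes`, `probes` (semicolon-joined contributing probes).
#' @export
aggregate_cpg_to_genes <- function(meth, map) {
  stopifnot(inherits(meth, "omics_matrix"))
  if (!all(meth$feature_type == "cpg_probe"))
    stop("'meth' must hold cpg_probe features")
  present <- map$probe_id %in% rownames(meth$values)
  if (!any(present))
    stop("no probe in the map is present in the methylation matrix")
  n_absent <- length(unique(map$probe_id[!present]))
  if (n_absent)
    message(n_absent, " mapped probe(s) absent from the matrix; ignored")
  map <- map[present, , drop = FALSE]
  by_gene <- split(map$probe_id, map$gene_id)
  genes <- sort(names(by_gene))
  vals <- t(vapply(genes, function(g) {
    colMeans(meth$values[by_gene[[g]], , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(meth$values))))
  vals[is.nan(vals)] <- NA
  dimnames(vals) <- list(genes, colnames(meth$values))
  out <- omics_matrix(vals, feature_type = "methylated_gene",
                      data_scale = "beta", samples = meth$samples)
  attr(out, "provenance") <- data.frame(
    gene_id = genes,
    n_probes = lengths(by_gene)[genes],
    probes = vapply(by_gene[genes], paste, "", collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Write the aggregation provenance side-car table
#'
#' @param mg Result of [aggregate_cpg_to_genes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(mg, path) {
  prov <- attr(mg, "provenance")
  if (is.null(prov)) stop("no provenance attribute on this matrix")
  utils::write.table(prov, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
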