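#' Specification for a synthetic triple-omics dataset
#'
#' Defines a two-class (tumor/normal) study with negative-binomial
#' expression counts carrying planted log2 fold changes, Beta-distributed
#' CpG probe methylation with planted gene-level mean shifts, and a
#' many-to-many probe-to-gene map. Defaults emulate a small but realistic
#' tumor/normal cohort: an imbalanced 60/20 design, a few percent of
#' features differential, and moderate biological noise.
#'
#' @param n_tumor,n_normal Samples per class (each >= 2).
#' @param n_pc,n_nc Protein-coding and ncRNA feature counts.
#' @param n_genes_meth Number of methylated genes.
#' @param probes_per_gene_mean Mean probes per gene (>= 1; count is
#'   `1 + Poisson(mean - 1)`).
#' @param frac_shared_probes Fraction of probes additionally mapped to a
#'   second random gene (the many-to-many relation).
#' @param d_pc,d_nc,d_meth Planted differential feature counts per block.
#' @param planted_log2fc Log2 fold change planted in tumor samples
#'   (sign alternates between up- and down-regulation across planted features).
#' @param planted_delta_beta Beta-value mean shift planted in tumors, in (0, 1).
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param base_mean Median baseline expression mean.
#' @param beta_precision Beta distribution precision `phi`
#'   (`Beta(mu * phi, (1 - mu) * phi)`).
#' @param seed Integer seed; all sampling is reproducible under it.
#' @return A validated list of class `synth_spec`.
#' @export
synth_spec <- function(n_tumor = 60, n_normal = 20,
                       n_pc = 2000, n_nc = 1000, n_genes_meth = 500,
                       probes_per_gene_mean = 3, frac_shared_probes = 0.2,
                       d_pc = 50, d_nc = 25, d_meth = 25,
                       planted_log2fc = 4, planted_delta_beta = 0.3,
                       nb_dispersion = 0.3, base_mean = 100,
                       beta_precision = 30, seed = 1L) {
  spec <- list(n_tumor = n_tumor, n_normal = n_normal, n_pc = n_pc,
               n_nc = n_nc, n_genes_meth = n_genes_meth,
               probes_per_gene_mean = probes_per_gene_mean,
               frac_shared_probes = frac_shared_probes,
               d_pc = d_pc, d_nc = d_nc, d_meth = d_meth,
               planted_log2fc = planted_log2fc,
               planted_delta_beta = planted_delta_beta,
               nb_dispersion = nb_dispersion, base_mean = base_mean,
               beta_precision = beta_precision, seed = as.integer(seed))
  if (n_tumor < 2 || n_normal < 2) stop("need >= 2 samples per class")
  if (d_pc > n_pc || d_nc > n_nc || d_meth > n_genes_meth)
    stop("planted feature counts cannot exceed block sizes")
  if (probes_per_gene_mean < 1) stop("probes_per_gene_mean must be >= 1")
  if (frac_shared_probes < 0 || frac_shared_probes > 1)
    stop("frac_shared_probes must be in [0, 1]")
  if (planted_delta_beta < 0 || planted_delta_beta >= 1)
    stop("planted_delta_beta must be in [0, 1)")
  if (nb_dispersion <= 0 || base_mean <= 0 || beta_precision <= 0)
    stop("dispersion, base_mean and beta_precision must be positive")
  structure(spec, class = "synth_spec")
}

#' Generate a many-to-many probe-to-gene map
#'
#' Every gene receives at least one probe (`1 + Poisson(mean - 1)` probes);
#' a `frac_shared_probes` fraction of probes is additionally mapped to a
#' second random gene, so one CpG site can modify several genes.
#'
#' @param spec A [synth_spec()].
#' @return A `probe_gene_map` data frame (`probe_id`, `gene_id`).
#' @export
make_probe_gene_map <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  genes <- sprintf("geneM%04d", seq_len(spec$n_genes_meth))
  n_probes_per_gene <- 1L + stats::rpois(spec$n_genes_meth,
                                         spec$probes_per_gene_mean - 1)
  n_probes <- sum(n_probes_per_gene)
  probes <- sprintf("cg%08d", seq_len(n_probes))
  pairs <- data.frame(probe_id = probes,
                      gene_id = rep(genes, n_probes_per_gene),
                      stringsAsFactors = FALSE)
  shared <- which(stats::runif(n_probes) < spec$frac_shared_probes)
  if (length(shared)) {
    second <- vapply(pairs$gene_id[shared], function(g) {
      sample(setdiff(genes, g), 1L)
    }, character(1))
    pairs <- rbind(pairs, data.frame(probe_id = probes[shared],
                                     gene_id = second,
                                     stringsAsFactors = FALSE))
  }
  pairs <- unique(pairs)
  rownames(pairs) <- NULL
  structure(pairs, class = c("probe_gene_map", "data.frame"))
}

#' Simulate a triple-omics dataset with known ground truth
#'
#' Expression counts are gamma-Poisson (negative binomial) with per-feature
#' baseline means spread around `base_mean`; planted features get their
#' tumor mean multiplied by `2^(+/- planted_log2fc)`. CpG probe beta values
#' are drawn from `Beta(mu * phi, (1 - mu) * phi)` around a gene-level mean
#' `mu`, shifted by `planted_delta_beta` in tumor samples for planted genes,
#' so probe-to-gene mean aggregation is the correct recovery operator by
#' construction. The methylation block is probe-level (`cpg_probe` scale).
#'
#' @param spec A [synth_spec()].
#' @return List with elements `dataset` (a `triple_dataset` whose `meth`
#'   block holds probe-level betas), `map` (the `probe_gene_map`), and
#'   `truth` (list of planted feature IDs per block; `meth` holds gene IDs).
#' @export
simulate_triple <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  mu_shift <- spec$planted_delta_beta
  set.seed(spec$seed)
  map <- make_probe_gene_map(spec)
  set.seed(spec$seed + 1L)

  n <- spec$n_tumor + spec$n_normal
  tumor <- c(rep(TRUE, spec$n_tumor), rep(FALSE, spec$n_normal))
  ids <- c(sprintf("TCGA-SY-%04d-01A", seq_len(spec$n_tumor)),
           sprintf("TCGA-SY-%04d-11A", seq_len(spec$n_normal)))

  sim_counts <- function(n_feat, d, prefix) {
    fid <- sprintf("%s%05d", prefix, seq_len(n_feat))
    base <- spec$base_mean * 2^stats::runif(n_feat, -2, 2)
    planted <- fid[seq_len(d)]
    sign_fc <- rep_len(c(1, -1), d)
    mu <- matrix(base, n_feat, n, dimnames = list(fid, ids))
    if (d > 0)
      mu[seq_len(d), tumor] <- base[seq_len(d)] *
        2^(sign_fc * spec$planted_log2fc)
    counts <- matrix(stats::rnbinom(n_feat * n, mu = mu,
                                    size = 1 / spec$nb_dispersion),
                     n_feat, n, dimnames = dimnames(mu))
    list(values = counts, planted = planted)
  }

  pc <- sim_counts(spec$n_pc, spec$d_pc, "genePC")
  nc <- sim_counts(spec$n_nc, spec$d_nc, "geneNC")

  genes <- sort(unique(map$gene_id))
  gene_mu <- stats::setNames(stats::runif(length(genes), 0.1, 0.6), genes)
  planted_genes <- genes[seq_len(spec$d_meth)]
  if (any(gene_mu[planted_genes] + mu_shift >= 1 - 1e-6) ||
      any(gene_mu[planted_genes] + mu_shift <= 1e-6))
    stop("degenerate Beta parameters: planted mean shift leaves (0, 1)")
  probes <- unique(map$probe_id)
  # a probe mapped to several genes takes the mean of its genes' mu
  probe_mu_base <- vapply(split(map$gene_id, map$probe_id)[probes],
                          function(g) mean(gene_mu[g]), numeric(1))
  probe_shift <- vapply(split(map$gene_id, map$probe_id)[probes],
                        function(g) mean(g %in% planted_genes) * mu_shift,
                        numeric(1))
  mu_mat <- matrix(probe_mu_base, length(probes), n,
                   dimnames = list(probes, ids))
  mu_mat[, tumor] <- pmin(mu_mat[, tumor] + probe_shift, 1 - 1e-6)
  phi <- spec$beta_precision
  betas <- matrix(stats::rbeta(length(probes) * n,
                               shape1 = mu_mat * phi,
                               shape2 = (1 - mu_mat) * phi),
                  length(probes), n, dimnames = dimnames(mu_mat))
  betas <- pmin(pmax(betas, 1e-6), 1 - 1e-6)

  mk <- function(values, feature_type, data_scale)
    omics_matrix(values, feature_type = feature_type, data_scale = data_scale)
  dataset <- assemble_triple(
    pc = mk(pc$values, "protein_coding", "counts"),
    nc = mk(nc$values, "ncRNA", "counts"),
    meth = mk(betas, "cpg_probe", "beta"))
  list(dataset = dataset, map = map,
       truth = list(pc = pc$planted, nc = nc$planted, meth = planted_genes))
}

#' Write a simulated dataset as a TSV fixture directory
#'
#' Emits the standard matrix TSV dialect for the three blocks, the probe
#' manifest, a label table, and the ground truth as JSON, so the fixture
#' reads back into an equal dataset with [read_fixture()].
#'
#' @param sim Result of [simulate_triple()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param missing_frac Fraction of expression cells blanked out to emulate
#'   missingness.
#' @param seed Seed for the missingness injection.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, overwrite = FALSE, missing_frac = 0,
                          seed = 1L) {
  ds <- sim$dataset
  if (length(ds$sample_ids) == 0L) stop("dataset has no samples")
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory exists and is non-empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- ds$blocks
  if (missing_frac > 0) {
    set.seed(seed)
    for (nm in c("pc", "nc")) {
      v <- blocks[[nm]]$values
      n_blank <- round(missing_frac * length(v))
      idx <- sample(length(v), n_blank)
      v[idx] <- NA
      blocks[[nm]]$values <- v
    }
  }
  # write barcodes (not join keys) so read-back exercises barcode parsing
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    colnames(b$values) <- b$samples$barcode
    write_matrix_tsv(b, file.path(dir, paste0(nm, ".tsv")))
  }
  write_probe_gene_map(sim$map, file.path(dir, "probe_gene_map.tsv"))
  lab <- data.frame(sample_id = blocks$pc$samples$barcode,
                    label = ifelse(ds$y == 1, "tumor", "normal"))
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a fixture directory back into a dataset
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `dataset`, `map`, and `truth` (if present).
#' @export
read_fixture <- function(dir) {
  pc <- read_matrix_tsv(file.path(dir, "pc.tsv"), "protein_coding", "counts")
  nc <- read_matrix_tsv(file.path(dir, "nc.tsv"), "ncRNA", "counts")
  meth <- read_matrix_tsv(file.path(dir, "meth.tsv"), "cpg_probe", "beta")
  map <- read_probe_gene_map(file.path(dir, "probe_gene_map.tsv"))
  truth_path <- file.path(dir, "ground_truth.json")
  truth <- if (file.exists(truth_path))
    lapply(jsonlite::read_json(truth_path), unlist)
  dataset <- assemble_triple(pc = filter_and_label_samples(pc),
                             nc = filter_and_label_samples(nc),
                             meth = filter_and_label_samples(meth))
  list(dataset = dataset, map = map, truth = truth)
}
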