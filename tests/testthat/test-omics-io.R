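test_that("TCGA barcodes parse into patient, sample-type code and label", {
  s <- parse_tcga_barcode(c("TCGA-BH-A1ES-06A-12D-A244-05",
                            "TCGA-AA-0000-01A",
                            "TCGA-AA-0000-11A"))
  expect_equal(s$patient_id[1], "TCGA-BH-A1ES")
  expect_equal(s$sample_type_code, c("06", "01", "11"))
  expect_equal(s$label, c(NA, 1L, -1L))
  expect_warning(short <- parse_tcga_barcode("TCGA-XX-0001"),
                 "unknown")
  expect_equal(short$sample_type_code, "unknown")
})

test_that("matrix TSV reading handles shape, missing cells and duplicates", {
  path <- write_tsv_by_hand(c(
    "feature_id\tTCGA-AA-0001-01A\tTCGA-AA-0002-11A",
    "g1\t5\t7",
    "g2\t\t",
    "g1\t1\t2"))
  m <- read_matrix_tsv(path, "protein_coding", "counts")
  expect_equal(dim(m$values), c(3L, 2L))
  # duplicated feature row read as-is; dedup deferred to preprocess
  expect_equal(rownames(m$values), c("g1", "g2", "g1"))
  # all-empty row retained as all-missing
  expect_true(all(is.na(m$values[2, ])))
  # independent line-by-line check of the numeric payload
  expect_equal(unname(m$values[1, ]), c(5, 7))
  expect_equal(unname(m$values[3, ]), c(1, 2))

  dup_cols <- write_tsv_by_hand(c("feature_id\tS-0-1-01A\tS-0-1-01A", "g1\t1\t2"))
  expect_error(read_matrix_tsv(dup_cols, "protein_coding", "counts"),
               "duplicate sample columns")
  bad_cell <- write_tsv_by_hand(c("feature_id\tS-0-1-01A", "g1\tabc"))
  expect_error(read_matrix_tsv(bad_cell, "protein_coding", "counts"),
               "non-numeric cell")
})

test_that("complete matrices round-trip through TSV bit-identically", {
  set.seed(1)
  m <- tiny_matrix(round(runif(12), 6), paste0("g", 1:4),
                   sprintf("TCGA-AA-%04d-01A", 1:3))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  m2 <- read_matrix_tsv(path, "protein_coding", "counts")
  expect_identical(m2$values, m$values)
})

test_that("sample filtering keeps 01/11, labels them, dedups aliquots", {
  m <- tiny_matrix(1:12, c("g1", "g2"),
                   c("TCGA-AA-0001-01A", "TCGA-AA-0001-06A",
                     "TCGA-AA-0002-11A", "TCGA-AA-0003-01B",
                     "TCGA-AA-0003-01A", "TCGA-AA-0004-11A"))
  f <- filter_and_label_samples(m)
  # metastatic 06 dropped; two 01 aliquots of patient 0003 deduplicated
  expect_setequal(f$samples$sample_type_code, c("01", "11"))
  expect_equal(sum(f$samples$patient_id == "TCGA-AA-0003"), 1L)
  # survivor is the lexicographically smallest barcode
  expect_true("TCGA-AA-0003-01A" %in% f$samples$barcode)
  expect_false("TCGA-AA-0003-01B" %in% f$samples$barcode)
  expect_equal(sort(unique(f$samples$label)), c(-1L, 1L))
  # values follow their samples
  expect_equal(unname(f$values[, f$samples$barcode == "TCGA-AA-0002-11A"]),
               c(5, 6))

  all_tumor <- tiny_matrix(1:4, c("g1", "g2"),
                           c("TCGA-AA-0001-01A", "TCGA-AA-0002-01A"))
  expect_error(filter_and_label_samples(all_tumor), "no normal samples")
})

test_that("label override table assigns classes for non-TCGA IDs", {
  m <- tiny_matrix(1:4, c("g1", "g2"), c("X-1-1-01A", "X-2-2-01A"))
  lab <- data.frame(sample_id = c("X-1-1-01A", "X-2-2-01A"),
                    label = c("tumor", "normal"))
  f <- filter_and_label_samples(m, labels = lab)
  expect_equal(sort(f$samples$label), c(-1L, 1L))
})

test_that("preprocessing dedups, drops empty features, imputes and normalizes", {
  barcodes <- sprintf("TCGA-AA-%04d-01A", 1:3)
  v <- matrix(c(1, 2, 3,
                NA, NA, NA,
                4, NA, 6,
                9, 9, 9), 4, 3, byrow = TRUE,
              dimnames = list(c("g1", "gEmpty", "g2", "g1"), barcodes))
  m <- omics_matrix(v, "protein_coding", "counts")
  p <- preprocess_features(m, normalization = "none")
  expect_equal(rownames(p$values), c("g1", "g2"))   # dup collapsed to first, empty dropped
  expect_equal(unname(p$values["g2", 2]), 5)        # mean-imputed
  expect_false(anyNA(p$values))
  expect_equal(unname(p$values["g1", ]), c(1, 2, 3))  # values otherwise unchanged
})

test_that("quantile normalization matches the sort/mean/unsort oracle", {
  set.seed(9)
  barcodes <- sprintf("TCGA-AA-%04d-01A", 1:3)
  v <- matrix(sample(1:100, 12), 4, 3,
              dimnames = list(paste0("g", 1:4), barcodes))
  m <- omics_matrix(v, "protein_coding", "counts")
  p <- preprocess_features(m, normalization = "quantile")
  expect_equal(unname(p$values), unname(qn_oracle(v)), tolerance = 1e-12)
  # post-normalization, all columns share one sorted value multiset
  sorted_cols <- apply(p$values, 2, sort)
  expect_equal(sorted_cols[, 2], sorted_cols[, 1])
  expect_equal(sorted_cols[, 3], sorted_cols[, 1])
})

test_that("triple assembly intersects samples on patient + type code", {
  mk <- function(patients, codes, type, scale, nf = 2) {
    barcodes <- sprintf("TCGA-AA-%04d-%s%s", patients, codes,
                        sample(c("A", "B"), length(patients), replace = TRUE))
    vals <- if (scale == "beta") runif(nf * length(patients)) else
      seq_len(nf * length(patients))
    m <- tiny_matrix(vals, paste0(type, 1:nf), barcodes,
                     feature_type = type, data_scale = scale)
    filter_and_label_samples(m)
  }
  set.seed(3)
  pc <- mk(c(1, 2, 3, 4), c("01", "01", "11", "11"), "protein_coding", "counts")
  nc <- mk(c(1, 2, 3), c("01", "01", "11"), "ncRNA", "counts")
  meth <- mk(c(1, 2, 3, 5), c("01", "01", "11", "11"), "cpg_probe", "beta")
  td <- assemble_triple(pc, nc, meth)
  # brute-force three-way intersection of the join keys
  expected <- sort(Reduce(intersect, list(
    paste0("TCGA-AA-000", c(1, 2, 3), ".", c("01", "01", "11")),
    paste0("TCGA-AA-000", c(1, 2, 3), ".", c("01", "01", "11")),
    paste0("TCGA-AA-000", c(1, 2, 3, 5), ".", c("01", "01", "11", "11")))))
  expect_equal(td$sample_ids, expected)
  expect_equal(unname(td$y), c(1L, 1L, -1L))
  for (b in td$blocks) expect_equal(colnames(b$values), td$sample_ids)
})

test_that("triple assembly is insensitive to input column order", {
  sim <- small_sim(seed = 11L)
  pc <- sim$dataset$blocks$pc
  perm <- sample(ncol(pc$values))
  pc_perm <- omics_matrix(pc$values[, perm], feature_type = pc$feature_type,
                          data_scale = pc$data_scale,
                          samples = pc$samples[perm, ])
  td2 <- assemble_triple(pc_perm, sim$dataset$blocks$nc,
                         sim$dataset$blocks$meth)
  expect_equal(td2$sample_ids, sim$dataset$sample_ids)
  expect_equal(td2$blocks$pc$values, sim$dataset$blocks$pc$values)
  expect_equal(td2$y, sim$dataset$y)
})

test_that("probe manifest parsing flattens and dedups gene lists", {
  path <- write_tsv_by_hand(c("probe_id\tgenes",
                              "cg001\tTP53;TP53;WRAP53",
                              "cg002\t",
                              "cg003\tBRCA1"))
  expect_message(map <- read_probe_gene_map(path), "1 probe")
  expect_equal(nrow(map), 3L)
  expect_setequal(map$gene_id[map$probe_id == "cg001"], c("TP53", "WRAP53"))
  expect_false("cg002" %in% map$probe_id)
})

test_that("a 100-line synthetic manifest matches an independent pair recount", {
  set.seed(21)
  genes <- replicate(100, paste(sample(LETTERS, sample(1:3, 1)), collapse = ";"))
  lines <- paste0(sprintf("cg%03d", 1:100), "\t", genes)
  path <- write_tsv_by_hand(lines)
  map <- read_probe_gene_map(path)
  # awk-style oracle: split every line by hand and count unique pairs
  expected <- unique(do.call(rbind, lapply(seq_along(lines), function(i) {
    gs <- unique(strsplit(genes[i], ";")[[1]])
    data.frame(probe_id = sprintf("cg%03d", i), gene_id = gs)
  })))
  expect_equal(nrow(map), nrow(expected))
  expect_setequal(paste(map$probe_id, map$gene_id),
                  paste(expected$probe_id, expected$gene_id))
})
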