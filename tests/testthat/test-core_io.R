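test_that("cell map round-trips through CSV/TSV and validates its schema", {
  cm <- cell_map(c("a", "b", "c"), c("s1", "s1", "s2"),
                 c(0, 1.5, 2), c(0, -1, 3), c("iCAF", "mCAF", "iCAF"))
  expect_equal(nrow(cm), 3)
  expect_equal(length(unique(cm$slice_id)), 2)
  for (dialect in c("csv", "tsv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_cell_map(cm, path, dialect)
    back <- read_cell_map(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(cm))
  }
  # duplicated cell_id within one slice is rejected; across slices allowed
  expect_error(cell_map(c("a", "a"), "s1", 0:1, 0:1, "t"),
               "duplicated cell_id")
  expect_silent(cell_map(c("a", "a"), c("s1", "s2"), 0:1, 0:1, "t"))
})

test_that("cell map reader names the missing column and the bad row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,slice_id,x,y", "a,s1,0,0"), path)
  expect_error(read_cell_map(path), "cell_type")
  writeLines(c("cell_id,slice_id,x,y,cell_type",
               "a,s1,0,0,t", "b,s1,oops,1,t"), path)
  expect_error(read_cell_map(path), "row 2")
})

test_that("expression readers handle dense CSV and Matrix Market triplets", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "G1,1,0", "G2,3,2"), path)
  e <- read_expression(path)
  expect_equal(unname(cell_totals(e)), c(4, 2))

  # mtx with sidecars, including the all-zero degenerate case
  dir <- withr::local_tempdir()
  m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(3, 2))
  Matrix::writeMM(m, file.path(dir, "mat.mtx"))
  writeLines(c("G1", "G2", "G3"), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  e0 <- read_expression(file.path(dir, "mat.mtx"))
  expect_equal(dim(e0), c(3L, 2L))
  expect_equal(sum(e0$values), 0)

  # sidecar mismatch is a format error
  writeLines(c("G1", "G2"), file.path(dir, "genes.tsv"))
  expect_error(read_expression(file.path(dir, "mat.mtx")), "do not match")

  # negative values violate the container invariant
  writeLines(c("gene,c1", "G1,-1"), path)
  expect_error(read_expression(path), "non-negative")
})

test_that("expression matrix round-trips through both writer formats", {
  e <- toy_expr(matrix(c(0, 2, 5, 0, 1, 7), 3, 2))
  for (fmt in c("csv", "mtx")) {
    dir <- withr::local_tempdir()
    path <- file.path(dir, paste0("m.", fmt))
    write_expression(e, path)
    back <- read_expression(path)
    expect_equal(as.matrix(back$values), as.matrix(e$values),
                 ignore_attr = TRUE)
    expect_equal(back$genes, e$genes)
    expect_equal(back$cells, e$cells)
  }
})

test_that("qc_filter removes cells by the first failed criterion, in order", {
  # columns: over-UMI, under-genes, over-mito, clean, exactly-at-threshold
  n_genes <- 600
  vals <- matrix(0, n_genes, 5)
  genes <- c("MT-CO1", sprintf("G%03d", seq_len(n_genes - 1)))
  vals[2:521, 1] <- 77  # 520 genes, 40040 UMI -> umi failure fires first
  vals[2:500, 2] <- 1   # 499 genes detected -> min_genes
  vals[1, 3] <- 30; vals[2:521, 3] <- 1  # 30/550 mito = 5.4%... make it fail:
  vals[1, 3] <- 300                      # 300/820 = 36% mito
  vals[2:521, 4] <- 2   # clean: 520 genes, 1040 UMI
  vals[2:501, 5] <- 80  # exactly 500 genes, 40000 UMI: retained
  e <- toy_expr(vals, genes = genes)
  res <- qc_filter(e, qc_thresholds(40000, 500, 5000, 0.20))
  expect_equal(res$report$reason, c("umi", "min_genes", "mito", NA, NA))
  expect_equal(res$expr$cells, c("c04", "c05"))

  # idempotence: filtering a filtered matrix removes nothing
  res2 <- qc_filter(res$expr, qc_thresholds(40000, 500, 5000, 0.20))
  expect_equal(res2$expr$cells, res$expr$cells)
  expect_true(all(res2$report$keep))

  # log-units input is refused
  el <- toy_expr(vals, genes = genes, units = "log")
  expect_error(qc_filter(el), "counts")
})

test_that("qc_filter reports max_genes before mito when both fail", {
  vals <- matrix(1, 60, 1)
  genes <- c("MT-CO1", sprintf("G%03d", 1:59))
  vals[1, 1] <- 1000  # high mito AND all genes detected
  e <- toy_expr(vals, genes = genes)
  res <- qc_filter(e, qc_thresholds(max_umi = 1e6, min_genes = 2,
                                    max_genes = 50, max_mito = 0.2))
  expect_equal(res$report$reason, "max_genes")
})

test_that("find_markers flags forced separation and not identical genes", {
  set.seed(11)
  vals <- rbind(c(rep(5, 10), rep(0, 10)),          # perfect A marker
                rep(seq(0.1, 2, length.out = 20), 1), # same values both groups
                matrix(runif(3 * 20), 3))
  e <- toy_expr(vals, units = "log")
  groups <- rep(c("A", "B"), each = 10)
  mk <- find_markers(e, groups, lfc_min = 1, alpha = 0.05)
  a <- mk[mk$group == "A", ]
  expect_equal(a$log2fc[a$gene == "G01"], 5.0)
  expect_true(a$significant[a$gene == "G01"])
  expect_false(a$significant[a$gene == "G02"])
  expect_equal(top_markers(mk, "A", 5), "G01")

  # invariant to cell order and to adding a constant to all log values
  perm <- sample(20)
  e_perm <- toy_expr(vals[, perm], cells = sprintf("c%02d", perm),
                     units = "log")
  mk_perm <- find_markers(e_perm, groups[perm])
  expect_equal(mk_perm$log2fc, mk$log2fc, tolerance = 1e-12)
  expect_equal(mk_perm$p, mk$p, tolerance = 1e-12)
  e_shift <- toy_expr(vals + 3, units = "log")
  mk_shift <- find_markers(e_shift, groups)
  expect_equal(mk_shift$log2fc, mk$log2fc, tolerance = 1e-12)
  expect_equal(mk_shift$p, mk$p, tolerance = 1e-12)

  # BH adjusted p is monotone in raw p within a group
  for (g in c("A", "B")) {
    sub <- mk[mk$group == g, ]
    ord <- order(sub$p)
    expect_true(all(diff(sub$p_adj[ord]) >= -1e-12))
    expect_true(all(sub$p_adj >= sub$p - 1e-12))
  }
})

test_that("rank-sum p matches exact enumeration on a 3-gene 6-cell toy", {
  set.seed(42)
  vals <- matrix(c(1.2, 3.4, 0.5, 2.2, 5.1, 4.4,
                   9.9, 0.1, 3.3, 1.1, 2.2, 7.7,
                   0.3, 0.6, 0.9, 1.2, 1.5, 1.8), 3, byrow = TRUE)
  e <- toy_expr(vals, units = "log")
  groups <- rep(c("A", "B"), each = 3)
  mk <- find_markers(e, groups)
  a <- mk[mk$group == "A", ]
  for (g in seq_len(3)) {
    expected <- wilcox_enum(vals[g, 1:3], vals[g, 4:6])
    expect_equal(a$p[a$gene == sprintf("G%02d", g)], expected,
                 tolerance = 1e-12)
  }
})

test_that("find_markers rejects undersized groups and wrong units", {
  e <- toy_expr(matrix(runif(20), 4), units = "log")
  expect_error(find_markers(e, c("A", rep("B", 4))), "A")
  ec <- toy_expr(matrix(1, 4, 5), units = "counts")
  expect_error(find_markers(ec, rep(c("A", "B"), c(2, 3))), "log")
})

test_that("gene sets load from GMT and weighted TSV", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("CYT\tcytolytic\tGZMA\tPRF1",
               "TLS\ttls sig\tCCL19\tCCL21\tCXCL13"), path)
  gs <- read_gmt(path)
  expect_equal(sort(names(gs$sets)), c("CYT", "TLS"))
  expect_equal(gs$sets$CYT, c("GZMA", "PRF1"))

  wpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tweight", "CCL5\t0.5", "CD27\t1.25"), wpath)
  ws <- read_weighted_set(wpath, "tcell_inflamed")
  expect_equal(ws$weights$tcell_inflamed, c(0.5, 1.25))
  expect_error(gene_set_collection(list(EMPTY = character())), "empty")
})
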