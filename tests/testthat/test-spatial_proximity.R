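test_that("k_distance reproduces hand-computed Euclidean means", {
  cm <- toy_map(c(0, 3, 6, 0), c(0, 0, 0, 4),
                c("ref", "ref", "ref", "query"))
  kd <- k_distance(cm, "ref", k = 2)
  # query at (0,4): distances 4, 5, sqrt(52) -> mean(4, 5) = 4.5
  expect_equal(kd$k_distance[kd$cell_type == "query"], 4.5)
  # ref cell at (0,0): others at 3 and 6 -> mean 4.5 (self excluded)
  expect_equal(kd$k_distance[1], 4.5)

  # query coincident with k reference cells at its own position -> 0
  cm0 <- toy_map(c(1, 1, 1, 5), c(2, 2, 2, 5),
                 c("ref", "ref", "query", "ref"))
  kd0 <- k_distance(cm0, "ref", k = 2)
  expect_equal(kd0$k_distance[3], 0)
})

test_that("k_distance equals brute force exactly, including k = 1", {
  set.seed(101)
  n <- 300
  cm <- cell_map(sprintf("c%03d", sample(n)),  # shuffled ids stress tie-break
                 rep(c("s1", "s2"), each = n / 2),
                 runif(n, 0, 100), runif(n, 0, 100),
                 sample(c("ref", "A", "B"), n, replace = TRUE))
  for (k in c(1, 4, 10)) {
    kd <- k_distance(cm, "ref", k = k)
    expect_equal(kd$k_distance, brute_kdist(cm, "ref", k), tolerance = 0)
  }
})

test_that("slices with too few reference cells are skipped and flagged", {
  cm <- cell_map(c("a", "b", "c", "d"), c("s1", "s1", "s2", "s2"),
                 c(0, 1, 0, 1), c(0, 0, 0, 0),
                 c("ref", "A", "A", "A"))
  warns <- capture_warnings(kd <- k_distance(cm, "ref", k = 2))
  expect_match(warns, "skipped", all = TRUE)
  expect_length(warns, 2)
  expect_equal(attr(kd, "skipped_slices"), c("s1", "s2"))
  expect_true(all(is.na(kd$k_distance)))
})

test_that("distance outputs are invariant to translation and rotation", {
  set.seed(55)
  n <- 120
  cm <- toy_map(runif(n, 0, 50), runif(n, 0, 50),
                sample(c("ref", "A", "B"), n, replace = TRUE))
  kd <- k_distance(cm, "ref", k = 3)
  theta <- 0.7
  xr <- cos(theta) * cm$x - sin(theta) * cm$y + 11
  yr <- sin(theta) * cm$x + cos(theta) * cm$y - 4
  cmr <- cell_map(cm$cell_id, cm$slice_id, xr, yr, cm$cell_type)
  kdr <- k_distance(cmr, "ref", k = 3)
  expect_equal(kdr$k_distance, kd$k_distance, tolerance = 1e-9)

  # uniform rescaling scales distances but leaves partitions unchanged
  cms <- cell_map(cm$cell_id, cm$slice_id, 3 * cm$x, 3 * cm$y, cm$cell_type)
  kds <- k_distance(cms, "ref", k = 3)
  expect_equal(kds$k_distance, 3 * kd$k_distance, tolerance = 1e-9)
  expect_equal(proximal_partition(kds, 0.2)$region,
               proximal_partition(kd, 0.2)$region)
})

test_that("proximity ranking orders planted neighbours before repelled ones", {
  cfg <- simulation_config(
    n_slices = 4, cells_per_slice = 240, seed = 17,
    spatial_rules = list(
      spatial_rule("Endothelial", "iCAF", "attract", strength = 1, range = 5),
      spatial_rule("Epithelial", "iCAF", "repel", strength = 4, range = 30)))
  rl <- celltype_proximity_ranking(simulate_collection(cfg)$cells,
                                   "iCAF", k = 5)
  for (l in rl$lists) {
    expect_lt(match("Endothelial", l), match("Epithelial", l))
  }

  # permuting cell-type labels permutes the ranking identically
  cm <- simulate_collection(cfg)$cells
  swap <- c(Endothelial = "Epithelial", Epithelial = "Endothelial",
            iCAF = "iCAF", mCAF = "mCAF")
  cm2 <- cell_map(cm$cell_id, cm$slice_id, cm$x, cm$y, swap[cm$cell_type])
  rl2 <- celltype_proximity_ranking(cm2, "iCAF", k = 5)
  for (s in names(rl$lists)) {
    expect_equal(unname(swap[rl$lists[[s]]]), rl2$lists[[s]])
  }
})

test_that("singleton non-reference type yields a singleton ranking", {
  cm <- toy_map(c(0, 1, 2, 5), c(0, 0, 0, 1),
                c("ref", "ref", "ref", "A"))
  rl <- celltype_proximity_ranking(cm, "ref", k = 2)
  expect_equal(rl$lists[[1]], "A")
})

test_that("proximal partition obeys the floor rule and breaks ties by id", {
  # 10 eligible cells, fraction 0.10 -> exactly the single closest cell
  cm <- toy_map(c(0, 0, 1:10), c(0, 0.5, rep(0, 10)),
                c("ref", "ref", rep("A", 10)))
  part <- proximal_partition(k_distance(cm, "ref", k = 2), 0.10)
  elig <- part[!is.na(part$region), ]
  expect_equal(sum(elig$region == "proximal"), 1)
  expect_equal(elig$cell_id[elig$region == "proximal"],
               elig$cell_id[which.min(elig$k_distance)])

  # fraction 0.5 with 4 distinct-distance cells -> floor(2) proximal
  cm4 <- toy_map(c(0, 0, 1, 2, 3, 4), c(0, 1, 0, 0, 0, 0),
                 c("ref", "ref", rep("A", 4)))
  part4 <- proximal_partition(k_distance(cm4, "ref", k = 2), 0.5)
  expect_equal(sum(part4$region == "proximal", na.rm = TRUE), 2)

  # all k-distances equal (coincident cells): lexicographically first ids
  # become proximal, and the partition is still deterministic
  cme <- cell_map(c("r1", "r2", "b", "a", "d", "c"), "s1",
                  c(0, 0, 1, 1, 1, 1), c(1, -1, 0, 0, 0, 0),
                  c("ref", "ref", "A", "A", "A", "A"))
  kde <- k_distance(cme, "ref", k = 2)
  expect_equal(length(unique(kde$k_distance[3:6])), 1)
  parte <- proximal_partition(kde, 0.5)
  expect_equal(sort(parte$cell_id[which(parte$region == "proximal")]),
               c("a", "b"))

  # reference cells are never eligible
  expect_true(all(is.na(parte$region[parte$cell_type == "ref"])))

  # partition invariants: union of regions = eligible cells, disjoint
  expect_equal(sum(!is.na(parte$region)), 4)
})

test_that("proximity enrichment recovers planted attraction and repulsion", {
  cfg <- simulation_config(
    n_slices = 6, cells_per_slice = 240, seed = 23,
    spatial_rules = list(
      spatial_rule("Endothelial", "iCAF", "attract", strength = 0.9,
                   range = 10),
      spatial_rule("Epithelial", "iCAF", "repel", strength = 4, range = 30)))
  et <- proximity_enrichment(simulate_collection(cfg)$cells, "iCAF",
                             k = 5, fraction = 0.10)
  endo <- et[et$cell_type == "Endothelial", ]
  epi <- et[et$cell_type == "Epithelial", ]
  expect_equal(endo$direction, "proximal-enriched")
  expect_lt(endo$p, 0.01)
  expect_equal(epi$direction, "distal-enriched")
  sig <- significant_enrichment(et)
  expect_true("Endothelial" %in% sig$cell_type)

  # invariant to slice ordering
  cells <- simulate_collection(cfg)$cells
  shuffled <- validate_cell_map(cells[rev(seq_len(nrow(cells))), ])
  et2 <- proximity_enrichment(shuffled, "iCAF", k = 5, fraction = 0.10)
  expect_equal(et2[order(et2$cell_type), ]$p, et[order(et$cell_type), ]$p,
               tolerance = 1e-12)
})

test_that("constant paired differences are flagged degenerate with p = 0", {
  # hand-built partition-level scenario: proportions differ by exactly 0.2
  # in each of 3 slices -> sd(d) = 0, mean(d) != 0
  make_slice <- function(s, n_a_prox) {
    # 10 eligible cells per region; type A gets n_a_prox in proximal, 1 in
    # distal; filler type B takes the rest
    x_ref <- c(0, 0.1)
    x_prox <- seq(1, 1.9, length.out = 10)
    x_dist <- seq(50, 59, length.out = 10)
    types <- c("ref", "ref",
               rep(c("A", "B"), c(n_a_prox, 10 - n_a_prox)),
               rep(c("A", "B"), c(1, 9)))
    cell_map(sprintf("%s_c%02d", s, 1:22), s,
             c(x_ref, x_prox, x_dist), rep(0, 22), types)
  }
  cells <- validate_cell_map(rbind(make_slice("s1", 3), make_slice("s2", 3),
                                   make_slice("s3", 3)))
  et <- proximity_enrichment(cells, "ref", k = 2, fraction = 0.5)
  a <- et[et$cell_type == "A", ]
  expect_equal(a$mean_diff, 0.2, tolerance = 1e-12)
  expect_true(a$degenerate)
  expect_equal(a$p, 0)
  expect_equal(a$direction, "proximal-enriched")
})
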