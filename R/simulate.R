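#' Spatial placement rule for a simulated cell type
#'
#' Describes how cells of `type` are placed relative to cells of `target`
#' within each slice. `"attract"` puts each cell at a Gaussian offset
#' (sd = `range`) from a uniformly chosen target cell with probability
#' `strength`, and uniformly otherwise; `"repel"` draws candidate positions
#' uniformly and accepts them with probability increasing in the distance to
#' the nearest target cell (`strength` controls the steepness); `"neutral"`
#' is uniform placement.
#'
#' @param type the cell type being placed.
#' @param target the reference cell type the rule points at.
#' @param mode `"attract"`, `"repel"` or `"neutral"`.
#' @param strength non-negative real; for `"attract"` the attachment
#'   probability in `[0, 1]`, for `"repel"` the steepness exponent.
#' @param range length scale of the interaction, in field units.
#' @return A `spatial_rule` list.
#' @export
spatial_rule <- function(type, target, mode = c("attract", "repel", "neutral"),
                         strength = 1, range = 20) {
  mode <- match.arg(mode)
  stopifnot(strength >= 0, range > 0)
  structure(list(type = type, target = target, mode = mode,
                 strength = strength, range = range),
            class = "spatial_rule")
}

#' Configuration for a synthetic multi-slice spatial collection
#'
#' Defines the study conditions for the synthetic test bed: a set of tissue
#' slices, each populated with cell types at given abundances, anchor types
#' laid out as Thomas-style cluster processes (Poisson cluster centers with
#' isotropic Gaussian scatter, emulating the dense cell-type patches of real
#' sections), rule-governed types placed by [spatial_rule()]s, and
#' negative-binomial expression with planted per-type marker genes.
#'
#' @param n_slices number of tissue slices.
#' @param cell_types named numeric vector of abundance weights (summing to 1).
#' @param cells_per_slice expected number of cells per slice.
#' @param field_size width/height of the square field, in length units.
#' @param spatial_rules list of [spatial_rule()]s; types without a rule are
#'   anchors laid out as Thomas cluster processes.
#' @param n_genes number of simulated genes.
#' @param markers_per_type number of marker genes planted per cell type.
#' @param marker_log2_effect log2 fold change of a marker in its own type.
#' @param nb_dispersion negative-binomial size parameter (smaller = noisier).
#' @param baseline_mean baseline negative-binomial mean per gene.
#' @param seed master seed; each slice draws from its own substream so that
#'   adding slices does not perturb earlier ones.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_slices = 10,
                              cell_types = c(iCAF = 0.25, mCAF = 0.25,
                                             Endothelial = 0.25,
                                             Epithelial = 0.25),
                              cells_per_slice = 400,
                              field_size = c(1000, 1000),
                              spatial_rules = list(),
                              n_genes = 200,
                              markers_per_type = 10,
                              marker_log2_effect = 2,
                              nb_dispersion = 2,
                              baseline_mean = 5,
                              seed = 1L) {
  stopifnot(is_count(n_slices), is_count(cells_per_slice), is_count(n_genes),
            is_count(markers_per_type), nb_dispersion > 0, baseline_mean > 0,
            length(field_size) == 2, all(field_size > 0))
  if (abs(sum(cell_types) - 1) > 1e-8) {
    stop_cafscape("cell_type abundance weights must sum to 1",
                  "cafscape_config_error")
  }
  for (r in spatial_rules) {
    if (!r$type %in% names(cell_types) || !r$target %in% names(cell_types)) {
      stop_cafscape(sprintf("spatial rule references absent type ('%s' -> '%s')",
                            r$type, r$target), "cafscape_config_error")
    }
  }
  if (n_genes < markers_per_type * length(cell_types)) {
    stop_cafscape("n_genes too small for the requested markers_per_type",
                  "cafscape_config_error")
  }
  structure(list(n_slices = n_slices, cell_types = cell_types,
                 cells_per_slice = cells_per_slice, field_size = field_size,
                 spatial_rules = spatial_rules, n_genes = n_genes,
                 markers_per_type = markers_per_type,
                 marker_log2_effect = marker_log2_effect,
                 nb_dispersion = nb_dispersion, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Place n points uniformly on the field.
runif_field <- function(n, field) {
  cbind(stats::runif(n, 0, field[1]), stats::runif(n, 0, field[2]))
}

clamp_field <- function(xy, field) {
  xy[, 1] <- pmin(pmax(xy[, 1], 0), field[1])
  xy[, 2] <- pmin(pmax(xy[, 2], 0), field[2])
  xy
}

# Thomas-style cluster placement: Poisson number of cluster centers
# (at least one) uniform on the field, cells scattered around a uniformly
# chosen center with isotropic Gaussian dispersion.
place_thomas <- function(n, field, center_rate = 3, sd_frac = 0.05) {
  n_centers <- max(1L, stats::rpois(1L, center_rate))
  centers <- runif_field(n_centers, field)
  pick <- sample.int(n_centers, n, replace = TRUE)
  sdv <- sd_frac * min(field)
  xy <- centers[pick, , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, sdv), ncol = 2)
  list(xy = clamp_field(xy, field), centers = centers)
}

place_attract <- function(n, field, target_xy, strength, range) {
  attach <- stats::runif(n) < strength
  xy <- runif_field(n, field)
  k <- sum(attach)
  if (k > 0 && nrow(target_xy) > 0) {
    pick <- sample.int(nrow(target_xy), k, replace = TRUE)
    xy[attach, ] <- target_xy[pick, , drop = FALSE] +
      matrix(stats::rnorm(2 * k, 0, range), ncol = 2)
  }
  clamp_field(xy, field)
}

place_repel <- function(n, field, target_xy, strength, range, max_tries = 50) {
  xy <- matrix(0, n, 2)
  d_scale <- range * 5
  for (i in seq_len(n)) {
    cand <- runif_field(1, field)
    for (try in seq_len(max_tries)) {
      cand <- runif_field(1, field)
      d <- sqrt(min((target_xy[, 1] - cand[1])^2 + (target_xy[, 2] - cand[2])^2))
      # acceptance probability rises with distance; strength = 0 accepts all
      if (stats::runif(1) < (1 - exp(-d / d_scale))^strength) break
    }
    xy[i, ] <- cand
  }
  xy
}

#' Simulate a multi-slice spatial single-cell collection
#'
#' Generates a [cell_map()] across `n_slices` slices with planted spatial
#' attraction/repulsion between cell types, a raw-count
#' [expression_matrix()] with negative-binomial noise and planted per-type
#' marker genes, and the ground truth needed to validate recovery.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A list with elements `cells` (cell_map), `expr`
#'   (expression_matrix of counts), and `truth` (per-type marker gene lists,
#'   rules, per-slice cluster centers).
#' @export
simulate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  types <- names(cfg$cell_types)
  ruled <- vapply(cfg$spatial_rules, `[[`, "", "type")
  anchors <- setdiff(types, ruled)
  maps <- vector("list", cfg$n_slices)
  centers <- vector("list", cfg$n_slices)
  for (s in seq_len(cfg$n_slices)) {
    set.seed(derive_seed(cfg$seed, s))
    counts <- as.vector(stats::rmultinom(1, cfg$cells_per_slice,
                                         cfg$cell_types))
    names(counts) <- types
    xy_by_type <- list()
    ctr <- list()
    for (tp in anchors) {
      if (counts[[tp]] == 0) next
      pl <- place_thomas(counts[[tp]], cfg$field_size)
      xy_by_type[[tp]] <- pl$xy
      ctr[[tp]] <- pl$centers
    }
    for (r in cfg$spatial_rules) {
      n <- counts[[r$type]]
      if (n == 0) next
      tgt <- xy_by_type[[r$target]]
      if (r$mode == "neutral" || is.null(tgt) || nrow(tgt) == 0) {
        xy_by_type[[r$type]] <- runif_field(n, cfg$field_size)
      } else if (r$mode == "attract") {
        xy_by_type[[r$type]] <- place_attract(n, cfg$field_size, tgt,
                                              r$strength, r$range)
      } else {
        xy_by_type[[r$type]] <- place_repel(n, cfg$field_size, tgt,
                                            r$strength, r$range)
      }
    }
    slice <- sprintf("slice%02d", s)
    dfs <- lapply(types[counts > 0 & types %in% names(xy_by_type)],
                  function(tp) {
      xy <- xy_by_type[[tp]]
      data.frame(slice_id = slice, x = xy[, 1], y = xy[, 2], cell_type = tp,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, dfs)
    df$cell_id <- sprintf("%s_c%04d", slice, seq_len(nrow(df)))
    maps[[s]] <- df[, c("cell_id", "slice_id", "x", "y", "cell_type")]
    centers[[s]] <- ctr
  }
  cells <- validate_cell_map(do.call(rbind, maps))

  # Expression: NB counts, per-type planted markers.
  set.seed(derive_seed(cfg$seed, 0L))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  markers <- stats::setNames(vector("list", length(types)), types)
  for (i in seq_along(types)) {
    idx <- ((i - 1) * cfg$markers_per_type + 1):(i * cfg$markers_per_type)
    markers[[types[i]]] <- genes[idx]
  }
  mu <- matrix(cfg$baseline_mean, cfg$n_genes, nrow(cells))
  for (tp in types) {
    gi <- match(markers[[tp]], genes)
    ci <- which(cells$cell_type == tp)
    mu[gi, ci] <- mu[gi, ci] * 2^cfg$marker_log2_effect
  }
  vals <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion),
                 nrow = cfg$n_genes)
  expr <- expression_matrix(vals, genes, cells$cell_id, units = "counts")
  truth <- list(markers = markers, rules = cfg$spatial_rules,
                centers = centers, seed = cfg$seed)
  list(cells = cells, expr = expr, truth = truth)
}

#' Simulate a regulon-activity matrix with planted specificity
#'
#' Assigns each regulon a target cell type round-robin and draws
#' Beta-distributed activities with mean `specificity` in target-type cells
#' and mean `(1 - specificity) * 0.2` elsewhere, so `specificity = 1` gives
#' near-zero off-target activity and `specificity = 0.2/1.2` approaches no
#' contrast.
#'
#' @param n_regulons number of regulons (at least the number of cell types).
#' @param cell_types character vector of type labels.
#' @param cells_per_type cells simulated per type.
#' @param specificity target-type mean activity, in `[0, 1]`.
#' @param seed integer seed.
#' @param concentration Beta concentration (shape1 + shape2).
#' @return A list with `ras` (a [regulon_activity()]) and `truth`, the named
#'   regulon -> target-type map.
#' @export
simulate_regulon_activity <- function(n_regulons, cell_types,
                                      cells_per_type = 50,
                                      specificity = 0.9, seed = 1L,
                                      concentration = 10) {
  if (specificity < 0 || specificity > 1) {
    stop_cafscape("specificity must lie in [0, 1]", "cafscape_config_error")
  }
  if (n_regulons < length(cell_types)) {
    stop_cafscape("need at least one regulon per cell type",
                  "cafscape_config_error")
  }
  set.seed(as.integer(seed))
  n_cells <- cells_per_type * length(cell_types)
  type_of <- rep(cell_types, each = cells_per_type)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  regulons <- sprintf("REG%03d(+)", seq_len(n_regulons))
  target <- cell_types[((seq_len(n_regulons) - 1) %% length(cell_types)) + 1]
  act <- matrix(0, n_regulons, n_cells, dimnames = list(regulons, cells))
  rbeta_mean <- function(n, m) {
    m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
    stats::rbeta(n, m * concentration, (1 - m) * concentration)
  }
  off_mean <- (1 - specificity) * 0.2
  for (i in seq_len(n_regulons)) {
    in_t <- type_of == target[i]
    act[i, in_t] <- rbeta_mean(sum(in_t), specificity)
    act[i, !in_t] <- rbeta_mean(sum(!in_t), off_mean)
  }
  list(ras = regulon_activity(act, type_of),
       truth = stats::setNames(target, regulons))
}

#' Simulate per-slice ranked lists with planted consensus items
#'
#' Each list is a permutation of a common universe. A planted item with
#' consensus strength `s` is promoted toward the top of every list by
#' drawing its position uniformly from the first `ceiling((1 - s) * U)`
#' slots (at least 1, so strength 1 pins the item at rank 1); remaining
#' items fill the other slots uniformly at random.
#'
#' @param n_lists number of lists (slices).
#' @param universe_size number of items.
#' @param planted_items named numeric vector: item name -> strength in `[0, 1]`.
#'   Names must be members of the generated universe `item001..itemNNN`, or
#'   new names, which are substituted for the last universe items.
#' @param seed integer seed.
#' @return A [ranked_lists()] object.
#' @export
simulate_ranked_lists <- function(n_lists, universe_size,
                                  planted_items = numeric(), seed = 1L) {
  if (length(planted_items) > 0 &&
      (any(planted_items < 0) || any(planted_items > 1))) {
    stop_cafscape("consensus strengths must lie in [0, 1]",
                  "cafscape_config_error")
  }
  universe <- sprintf("item%03d", seq_len(universe_size))
  new_names <- setdiff(names(planted_items), universe)
  if (length(new_names) > 0) {
    universe[universe_size - seq_along(new_names) + 1L] <- new_names
  }
  set.seed(as.integer(seed))
  # strongest items claim their slots first so windows are honoured
  planted_items <- sort(planted_items, decreasing = TRUE)
  lists <- lapply(seq_len(n_lists), function(l) {
    pos <- rep(NA_character_, universe_size)
    for (nm in names(planted_items)) {
      win <- max(1L, ceiling((1 - planted_items[[nm]]) * universe_size))
      free <- which(is.na(pos[seq_len(win)]))
      slot <- if (length(free) > 0) free[sample.int(length(free), 1L)] else
        which(is.na(pos))[1L]
      pos[slot] <- nm
    }
    rest <- setdiff(universe, names(planted_items))
    pos[is.na(pos)] <- sample(rest)
    pos
  })
  names(lists) <- sprintf("list%02d", seq_len(n_lists))
  ranked_lists(lists, universe = universe)
}

#' Simulate a bulk expression cohort with a planted group effect
#'
#' Log-normal expression across `n_genes`; the genes of `signature` are
#' multiplied by `2^group_effect_log2` in the "high" group. Samples are
#' split evenly into "high" and "low".
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes (`GENE0001...`), or a character vector of
#'   gene names to use as the universe.
#' @param signature character vector of signature genes (must be members of
#'   the gene universe).
#' @param group_effect_log2 planted log2 effect size.
#' @param seed integer seed.
#' @return A list with `expr` (a linear-scale [expression_matrix()]) and
#'   `groups`, a named character vector of planted labels.
#' @export
simulate_bulk_cohort <- function(n_samples, n_genes, signature,
                                 group_effect_log2 = 2, seed = 1L) {
  genes <- if (is.character(n_genes)) n_genes else
    sprintf("GENE%04d", seq_len(n_genes))
  if (!all(signature %in% genes)) {
    stop_cafscape(sprintf("signature gene(s) not in universe: %s",
                          paste(setdiff(signature, genes), collapse = ", ")),
                  "cafscape_config_error")
  }
  set.seed(as.integer(seed))
  samples <- sprintf("sample%03d", seq_len(n_samples))
  groups <- stats::setNames(
    sample(rep(c("high", "low"), length.out = n_samples)), samples)
  logv <- matrix(stats::rnorm(length(genes) * n_samples, mean = 3, sd = 1),
                 nrow = length(genes), dimnames = list(genes, samples))
  gi <- match(signature, genes)
  logv[gi, groups == "high"] <- logv[gi, groups == "high"] + group_effect_log2
  expr <- expression_matrix(2^logv, genes, samples, units = "linear")
  list(expr = expr, groups = groups)
}
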