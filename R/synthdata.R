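#' Specification for a synthetic single-cell UMI experiment
#'
#' Defines a negative-binomial UMI simulation with planted cell-type
#' clusters (marker genes up-shifted per type), an optional condition
#' module (e.g. an interferon-stimulated-gene block up-regulated in
#' IFN-treated conditions), and mitochondrial genes receiving a stated
#' fraction of each cell's counts in expectation.
#'
#' @param n_cell_types number of planted cell types.
#' @param cells_per_type either a scalar/vector (cells per type per
#'   condition) or an `n_cell_types x length(conditions)` matrix giving the
#'   number of cells of each type under each condition.
#' @param n_genes total genes, including mitochondrial genes.
#' @param conditions condition labels.
#' @param mean_log,sd_log log-normal parameters of baseline per-gene mean
#'   expression (counts per cell).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param markers_per_type number of marker genes planted per type.
#' @param marker_fc fold change of a type's markers in that type.
#' @param module_genes number of genes in the condition module.
#' @param module_fc named fold change per condition applied to the module
#'   (names must cover `conditions`); scalar 1 disables the module.
#' @param n_mito_genes mitochondrial genes (symbols prefixed `mt-`).
#' @param mito_fraction expected fraction of a cell's counts on
#'   mitochondrial genes.
#' @param seed RNG seed making the simulation reproducible.
#' @return an `sc_sim_spec` list, validated.
#' @export
sc_sim_spec <- function(n_cell_types = 4, cells_per_type = 50,
                        n_genes = 1000,
                        conditions = c("CTRL", "ALL", "IFN+ALL"),
                        mean_log = 0, sd_log = 1, dispersion = 0.1,
                        markers_per_type = 25, marker_fc = 8,
                        module_genes = 30,
                        module_fc = c("CTRL" = 1, "ALL" = 1, "IFN+ALL" = 6),
                        n_mito_genes = 10, mito_fraction = 0.05,
                        seed = 1L) {
  if (is.matrix(cells_per_type)) {
    stopifnot(nrow(cells_per_type) == n_cell_types,
              ncol(cells_per_type) == length(conditions))
    cells <- cells_per_type
  } else {
    cells <- matrix(rep_len(cells_per_type, n_cell_types * length(conditions)),
                    nrow = n_cell_types)
  }
  if (length(module_fc) == 1 && is.null(names(module_fc))) {
    module_fc <- stats::setNames(rep(module_fc, length(conditions)), conditions)
  }
  spec <- list(n_cell_types = n_cell_types, cells = cells,
               n_genes = n_genes, conditions = conditions,
               mean_log = mean_log, sd_log = sd_log,
               dispersion = dispersion,
               markers_per_type = markers_per_type, marker_fc = marker_fc,
               module_genes = module_genes, module_fc = module_fc,
               n_mito_genes = n_mito_genes, mito_fraction = mito_fraction,
               seed = as.integer(seed))
  validate_sc_spec(spec)
  structure(spec, class = "sc_sim_spec")
}

validate_sc_spec <- function(s) {
  if (s$n_cell_types < 1 || s$n_genes < 1 || any(s$cells < 1)) {
    stop("cell-type, gene and cell counts must all be >= 1")
  }
  if (s$marker_fc <= 0 || any(s$module_fc <= 0)) stop("fold changes must be > 0")
  if (s$mito_fraction <= 0 || s$mito_fraction >= 1) {
    stop("mito_fraction must lie in (0, 1)")
  }
  if (!all(s$conditions %in% names(s$module_fc))) {
    stop("module_fc must name every condition")
  }
  needed <- s$n_mito_genes + s$n_cell_types * s$markers_per_type + s$module_genes
  if (needed > s$n_genes) stop("n_genes too small for markers + module + mito")
  invisible(s)
}

#' Simulate a single-cell UMI count matrix with planted structure
#'
#' Counts are drawn gene-wise from a negative binomial whose mean is a
#' baseline log-normal per-gene level, multiplied by the marker fold
#' change in the gene's own cell type and the condition-module fold change
#' in module genes. Mitochondrial gene means are rescaled so their
#' expected share of a cell's counts equals `mito_fraction`. Deterministic
#' given the spec's seed.
#'
#' @param spec an [sc_sim_spec].
#' @return list with `counts` (a [sparse_counts]) and `truth`: per-cell
#'   `type` labels, `markers` (list of marker genes per type),
#'   `module_genes`, and the per-gene baseline means.
#' @export
simulate_sc <- function(spec) {
  if (!inherits(spec, "sc_sim_spec")) stop("spec must be an sc_sim_spec")
  validate_sc_spec(spec)
  set.seed(spec$seed)
  G <- spec$n_genes
  n_mito <- spec$n_mito_genes
  genes <- c(sprintf("mt-Gene%02d", seq_len(n_mito)),
             sprintf("Gene%04d", seq_len(G - n_mito)))
  base <- stats::rlnorm(G, meanlog = spec$mean_log, sdlog = spec$sd_log)
  # endogenous genes first in the assignment pool
  endo <- setdiff(seq_len(G), seq_len(n_mito))
  marker_idx <- split(endo[seq_len(spec$n_cell_types * spec$markers_per_type)],
                      rep(seq_len(spec$n_cell_types), each = spec$markers_per_type))
  used <- unlist(marker_idx)
  module_idx <- setdiff(endo, used)[seq_len(spec$module_genes)]
  # scale mito means so expected mito share of a cell is mito_fraction
  endo_mass <- sum(base[endo])
  base[seq_len(n_mito)] <- base[seq_len(n_mito)] /
    sum(base[seq_len(n_mito)]) * endo_mass * spec$mito_fraction /
    (1 - spec$mito_fraction)

  type_of <- integer(0)
  cond_of <- character(0)
  for (ty in seq_len(spec$n_cell_types)) {
    for (ci in seq_along(spec$conditions)) {
      n <- spec$cells[ty, ci]
      type_of <- c(type_of, rep(ty, n))
      cond_of <- c(cond_of, rep(spec$conditions[ci], n))
    }
  }
  n_cells <- length(type_of)
  size <- 1 / spec$dispersion
  total_mass <- sum(base)
  cols <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    mu <- base
    mu[marker_idx[[type_of[j]]]] <- mu[marker_idx[[type_of[j]]]] * spec$marker_fc
    fc <- spec$module_fc[[cond_of[j]]]
    if (fc != 1) mu[module_idx] <- mu[module_idx] * fc
    # cell types share the depth distribution: markers shift composition,
    # not total RNA content
    mu <- mu * total_mass / sum(mu)
    cnt <- stats::rnbinom(G, mu = mu, size = size)
    nz <- which(cnt > 0)
    cols[[j]] <- list(i = nz, x = cnt[nz])
  }
  ii <- unlist(lapply(cols, `[[`, "i"))
  jj <- rep(seq_len(n_cells), vapply(cols, function(c) length(c$i), 0L))
  xx <- unlist(lapply(cols, `[[`, "x"))
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(G, n_cells),
                            dimnames = list(genes,
                                            sprintf("cell%05d", seq_len(n_cells))))
  counts <- sparse_counts(m, condition = cond_of,
                          sample = paste0("s_", cond_of))
  list(counts = counts,
       truth = list(type = paste0("type", type_of),
                    markers = lapply(marker_idx, function(i) genes[i]),
                    module_genes = genes[module_idx],
                    base_mean = stats::setNames(base, genes)))
}

#' Specification for a synthetic TCR repertoire cohort
#'
#' Clone frequencies follow a power law `f_i ~ i^-alpha`. The first
#' `n_public` templates (the top ranks) are shared across all mice,
#' emulating public, tumor-reactive clones; remaining clones are private.
#' At each timepoint the top `expanded_clones` frequencies are multiplied
#' by that timepoint's expansion factor and renormalized, then counts are
#' drawn multinomially at the specified read depth (per-sample totals are
#' exact).
#'
#' @param n_mice mice in the cohort.
#' @param timepoints ordinal timepoint labels.
#' @param clones_per_mouse clones per mouse (>= 1).
#' @param alpha power-law exponent (> 0).
#' @param expansion expansion factor per timepoint (each >= 1), recycled
#'   to `length(timepoints)`.
#' @param expanded_clones number of top-rank clones expanded.
#' @param n_public templates shared across mice (occupying the top ranks).
#' @param reads reads drawn per sample.
#' @param seed RNG seed.
#' @return a `rep_sim_spec` list, validated.
#' @export
rep_sim_spec <- function(n_mice = 8, timepoints = c("T0", "T1", "T2"),
                         clones_per_mouse = 1000, alpha = 1,
                         expansion = c(1, 1, 50), expanded_clones = 3,
                         n_public = 50, reads = 1e5, seed = 1L) {
  spec <- list(n_mice = n_mice, timepoints = timepoints,
               clones_per_mouse = clones_per_mouse, alpha = alpha,
               expansion = rep_len(expansion, length(timepoints)),
               expanded_clones = expanded_clones,
               n_public = n_public, reads = reads, seed = as.integer(seed))
  if (spec$clones_per_mouse < 1) stop("clones_per_mouse must be >= 1")
  if (spec$reads <= 0) stop("reads must be > 0")
  if (spec$alpha <= 0) stop("alpha must be > 0")
  if (any(spec$expansion < 1)) stop("expansion factors must be >= 1")
  if (spec$n_public > spec$clones_per_mouse) {
    stop("n_public cannot exceed clones_per_mouse")
  }
  if (spec$expanded_clones > spec$clones_per_mouse) {
    stop("expanded_clones cannot exceed clones_per_mouse")
  }
  structure(spec, class = "rep_sim_spec")
}

#' Simulate a clonally structured TCR repertoire cohort
#'
#' @param spec a [rep_sim_spec].
#' @return list of [repertoire_table]s (one per mouse per timepoint),
#'   ordered by mouse then timepoint.
#' @export
simulate_repertoire <- function(spec) {
  if (!inherits(spec, "rep_sim_spec")) stop("spec must be a rep_sim_spec")
  set.seed(spec$seed)
  n <- spec$clones_per_mouse
  base <- seq_len(n)^(-spec$alpha)
  base <- base / sum(base)
  out <- list()
  for (mi in seq_len(spec$n_mice)) {
    templates <- character(n)
    pub <- seq_len(spec$n_public)
    templates[pub] <- sprintf("CASSPUB%04d", pub)
    priv <- setdiff(seq_len(n), pub)
    templates[priv] <- sprintf("CASSM%02dX%05d", mi, seq_along(priv))
    for (ti in seq_along(spec$timepoints)) {
      f <- base
      k <- spec$expanded_clones
      f[seq_len(k)] <- f[seq_len(k)] * spec$expansion[ti]
      f <- f / sum(f)
      cnt <- as.vector(stats::rmultinom(1, size = spec$reads, prob = f))
      keep <- cnt > 0
      out[[length(out) + 1]] <- repertoire_table(
        templates[keep], cnt[keep],
        sample_id = sprintf("m%02d_%s", mi, spec$timepoints[ti]),
        mouse_id = sprintf("m%02d", mi),
        timepoint = spec$timepoints[ti])
    }
  }
  out
}

#' Simulate bulk reference expression profiles per cell type
#'
#' Negative-binomial replicate profiles for several sorted cell
#' populations, each with a planted set of marker genes up-shifted by
#' `fold_change` in that population only. These emulate the reference
#' compendium used to derive cell-type gene signatures.
#'
#' @param n_cell_types populations (>= 2).
#' @param n_genes total genes.
#' @param markers_per_type planted markers per type.
#' @param fold_change marker fold change (> 1 for signal; 1 for null).
#' @param replicates replicate profiles per type (>= 2).
#' @param seed RNG seed.
#' @param base_mean_log,base_sd_log log-normal baseline mean parameters.
#' @param dispersion NB dispersion.
#' @param lib_size library-depth multiplier on the baseline gene means;
#'   the default yields a few million reads per profile, matching the
#'   per-gene depth of a typical bulk library, so that shot noise does
#'   not dominate biological dispersion.
#' @param marker_sets optional list (one character vector per type) of
#'   gene names to use as truth markers; must be disjoint subsets of
#'   `gene_names`.
#' @param gene_names optional gene names (length `n_genes`).
#' @param cell_types optional type labels.
#' @return list with `profiles` (a [bulk_counts] whose condition is the
#'   cell type) and `truth_markers` (list per type).
#' @export
simulate_reference_profiles <- function(n_cell_types = 5, n_genes = 2000,
                                        markers_per_type = 20,
                                        fold_change = 16, replicates = 4,
                                        seed = 1L,
                                        base_mean_log = 3, base_sd_log = 1,
                                        dispersion = 0.04, lib_size = 50,
                                        marker_sets = NULL, gene_names = NULL,
                                        cell_types = NULL) {
  if (replicates < 2) stop("at least 2 replicates per cell type are required")
  if (n_cell_types < 2) stop("at least 2 cell types are required")
  if (fold_change <= 0) stop("fold_change must be > 0")
  set.seed(as.integer(seed))
  if (is.null(gene_names)) gene_names <- sprintf("Gene%04d", seq_len(n_genes))
  stopifnot(length(gene_names) == n_genes)
  if (is.null(cell_types)) cell_types <- paste0("type", seq_len(n_cell_types))
  if (is.null(marker_sets)) {
    idx <- split(seq_len(n_cell_types * markers_per_type),
                 rep(seq_len(n_cell_types), each = markers_per_type))
    marker_sets <- lapply(idx, function(i) gene_names[i])
  }
  names(marker_sets) <- cell_types
  stopifnot(all(unlist(marker_sets) %in% gene_names),
            !anyDuplicated(unlist(marker_sets)))
  base <- stats::rlnorm(n_genes, base_mean_log, base_sd_log) * lib_size
  names(base) <- gene_names
  size <- 1 / dispersion
  cols <- list()
  labels <- character(0)
  for (ty in cell_types) {
    mu <- base
    mu[marker_sets[[ty]]] <- mu[marker_sets[[ty]]] * fold_change
    for (r in seq_len(replicates)) {
      cols[[length(cols) + 1]] <- stats::rnbinom(n_genes, mu = mu, size = size)
      labels <- c(labels, ty)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- gene_names
  colnames(m) <- sprintf("%s_rep%d", labels,
                         stats::ave(seq_along(labels), labels, FUN = seq_along))
  list(profiles = bulk_counts(m, condition = labels),
       truth_markers = marker_sets)
}
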