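#' Rescale a repertoire to counts per million
#'
#' Each template's value becomes `count * 1e6 / total`, so values sum to
#' one million.
#'
#' @param table a [repertoire_table].
#' @return the table with cpm-scaled counts.
#' @export
to_cpm <- function(table) {
  stopifnot(inherits(table, "repertoire_table"))
  total <- sum(table$count)
  if (total <= 0) stop("cannot cpm-scale an all-zero repertoire")
  out <- table
  out$count <- table$count * 1e6 / total
  out
}

#' Repertoire clonality (1 - Pielou's evenness)
#'
#' Clonality is `C = 1 - H'/H` where `H'` is the Shannon entropy (nats) of
#' the template frequency distribution, computed over templates with count
#' greater than zero, and `H = ln(S)` is the maximal entropy for `S`
#' distinct observed templates. `C` is 0 for a perfectly even repertoire
#' and approaches 1 for a monoclonal one; it is invariant under rescaling
#' of the counts (raw counts and cpm give the same value).
#'
#' A monoclonal sample (`S = 1`) makes `H = 0` and the ratio undefined;
#' it is returned as `C = 1` (the monoclonal limit) with a warning.
#'
#' @param table a [repertoire_table] (raw counts or cpm).
#' @return a one-row data.frame: `sample_id`, `mouse_id`, `timepoint`,
#'   `S` (distinct templates), `H_prime`, `H_max` (both nats), `clonality`.
#' @export
clonality <- function(table) {
  stopifnot(inherits(table, "repertoire_table"))
  x <- table$count[table$count > 0]
  if (length(x) == 0) stop("repertoire has no template with count > 0")
  S <- length(x)
  p <- x / sum(x)
  H_prime <- -sum(p * log(p))
  H_max <- log(S)
  if (S == 1) {
    warning("monoclonal repertoire (S = 1): clonality defined as 1")
    C <- 1
  } else if (all(x == x[1])) {
    # uniform support: evenness is exactly 1, avoid rounding residue
    H_prime <- H_max
    C <- 0
  } else {
    C <- min(max(1 - H_prime / H_max, 0), 1)
  }
  data.frame(sample_id = rep_attr(table, "sample_id"),
             mouse_id = rep_attr(table, "mouse_id"),
             timepoint = rep_attr(table, "timepoint"),
             S = S, H_prime = H_prime, H_max = H_max,
             clonality = C, stringsAsFactors = FALSE)
}

#' Similarity of a template abundance vector to a mean vector
#'
#' One minus the Bray-Curtis distance,
#' `1 - sum(|s_i - m_i|) / sum(s_i + m_i)`, over a shared template
#' universe. On presence/absence (0/1) vectors this equals the
#' Sorensen-Dice index.
#'
#' @param s,m non-negative abundance vectors on the same universe.
#' @return similarity in \[0, 1\].
#' @export
bray_curtis_similarity <- function(s, m) {
  stopifnot(length(s) == length(m), all(s >= 0), all(m >= 0))
  denom <- sum(s + m)
  if (denom == 0) stop("similarity undefined for two empty vectors")
  1 - sum(abs(s - m)) / denom
}

#' Similarity of a repertoire sample to the timepoint mean
#'
#' Computes `S_t = 1 - Bray-Curtis(sample, mean)` where the mean is the
#' arithmetic mean of template abundances over all cohort samples at the
#' same timepoint, evaluated on the union of all templates observed in the
#' cohort at that timepoint. Abundances are cpm-scaled by default, which
#' removes sequencing-depth artifacts from the mean; the focal sample is
#' included in the mean (no exclusion is implied by the definition), with
#' a leave-one-out option.
#'
#' @param sample a [repertoire_table]; should be a member of `cohort`.
#' @param cohort list of [repertoire_table]s at one timepoint (including
#'   or excluding `sample`; if absent it is added for the universe).
#' @param normalize `"cpm"` (default) or `"none"` (use values as given).
#' @param include_self include the focal sample in the mean (default TRUE).
#' @return one-row data.frame: `sample_id`, `timepoint`, `similarity`,
#'   `universe_size`.
#' @export
similarity_to_timepoint_mean <- function(sample, cohort,
                                         normalize = c("cpm", "none"),
                                         include_self = TRUE) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(sample, "repertoire_table"), length(cohort) >= 1)
  ids <- vapply(cohort, rep_attr, "", which = "sample_id")
  self_id <- rep_attr(sample, "sample_id")
  if (!self_id %in% ids) cohort <- c(cohort, list(sample))
  if (normalize == "cpm") {
    cohort <- lapply(cohort, to_cpm)
    sample <- to_cpm(sample)
  }
  universe <- sort(unique(unlist(lapply(cohort, function(t) {
    t$template[t$count > 0]
  }))))
  if (length(universe) == 0) stop("empty template universe")
  vec <- function(t) {
    v <- numeric(length(universe))
    v[match(t$template, universe, nomatch = 0)] <-
      t$count[t$template %in% universe]
    v
  }
  mean_pool <- cohort
  if (!include_self) {
    keep <- vapply(mean_pool, rep_attr, "", which = "sample_id") != self_id
    if (!any(keep)) stop("leave-one-out mean requires another cohort sample")
    mean_pool <- mean_pool[keep]
  }
  mat <- vapply(mean_pool, vec, numeric(length(universe)))
  m <- rowMeans(mat)
  s <- vec(sample)
  data.frame(sample_id = self_id,
             timepoint = rep_attr(sample, "timepoint"),
             similarity = bray_curtis_similarity(s, m),
             universe_size = length(universe), stringsAsFactors = FALSE)
}

#' Longitudinal clonality/similarity summary for a repertoire cohort
#'
#' Computes clonality and similarity-to-timepoint-mean for every sample,
#' then per-mouse changes (arrows) between the first and last timepoint,
#' mirroring a before/after-rechallenge comparison.
#'
#' @param samples list of [repertoire_table]s with mouse/timepoint
#'   attributes; timepoints are ordered by their sorted labels.
#' @param include_self passed to [similarity_to_timepoint_mean].
#' @return list with `per_sample` (mouse, timepoint, S, clonality,
#'   similarity), `arrows` (per mouse: first/last timepoint values and
#'   `delta_clonality`, `delta_similarity`; single-timepoint mice carry NA
#'   deltas, with a warning) and `timepoint_means`.
#' @export
longitudinal_summary <- function(samples, include_self = TRUE) {
  stopifnot(length(samples) >= 1)
  tp <- vapply(samples, rep_attr, "", which = "timepoint")
  mouse <- vapply(samples, rep_attr, "", which = "mouse_id")
  per_sample <- do.call(rbind, lapply(seq_along(samples), function(i) {
    cl <- clonality(samples[[i]])
    cohort <- samples[tp == tp[i]]
    sim <- similarity_to_timepoint_mean(samples[[i]], cohort,
                                        include_self = include_self)
    cbind(cl[, c("sample_id", "mouse_id", "timepoint", "S", "clonality")],
          similarity = sim$similarity)
  }))
  per_sample <- per_sample[order(per_sample$mouse_id, per_sample$timepoint), ]
  rownames(per_sample) <- NULL
  tps <- sort(unique(tp))
  arrows <- do.call(rbind, lapply(sort(unique(mouse)), function(m) {
    sub <- per_sample[per_sample$mouse_id == m, ]
    sub <- sub[order(sub$timepoint), ]
    if (nrow(sub) < 2) {
      warning(sprintf("mouse %s has a single timepoint; deltas set to NA", m))
      return(data.frame(mouse_id = m, tp_first = sub$timepoint[1],
                        tp_last = sub$timepoint[1],
                        clonality_first = sub$clonality[1],
                        clonality_last = sub$clonality[1],
                        similarity_first = sub$similarity[1],
                        similarity_last = sub$similarity[1],
                        delta_clonality = NA_real_,
                        delta_similarity = NA_real_,
                        stringsAsFactors = FALSE))
    }
    n <- nrow(sub)
    data.frame(mouse_id = m, tp_first = sub$timepoint[1],
               tp_last = sub$timepoint[n],
               clonality_first = sub$clonality[1],
               clonality_last = sub$clonality[n],
               similarity_first = sub$similarity[1],
               similarity_last = sub$similarity[n],
               delta_clonality = sub$clonality[n] - sub$clonality[1],
               delta_similarity = sub$similarity[n] - sub$similarity[1],
               stringsAsFactors = FALSE)
  }))
  means <- do.call(rbind, lapply(tps, function(t) {
    sub <- per_sample[per_sample$timepoint == t, ]
    data.frame(timepoint = t, n = nrow(sub),
               mean_clonality = mean(sub$clonality),
               mean_similarity = mean(sub$similarity),
               stringsAsFactors = FALSE)
  }))
  list(per_sample = per_sample, arrows = arrows, timepoint_means = means)
}
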