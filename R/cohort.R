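.feature_names <- c("rmp", "input_resistance", "tau_m", "sag_ratio",
                    "sag_amplitude", "ap_threshold", "ap_amplitude",
                    "ap_half_width", "upstroke_downstroke_ratio",
                    "ahp_amplitude", "rheobase", "latency", "fi_slope",
                    "avg_rate_hero")

#' Assemble the 14-feature vector of one cell
#'
#' Maps passive, single-AP and spike-train features one-to-one onto the
#' standard 14-feature vector (five subthreshold features, seven features of
#' the first AP at rheobase including rheobase and latency, two train
#' features). Missing components are marked in the completeness mask, never
#' silently zeroed.
#'
#' @param passive a [passive_features()] result (or NULL).
#' @param ap an [ap_waveform_features()] result (or NULL).
#' @param train a [train_features()] result (or NULL).
#' @return object of class `feature_vector`: named numeric `values`
#'   (length 14) and logical `mask` of the same names.
#' @export
assemble_feature_vector <- function(passive = NULL, ap = NULL, train = NULL) {
  g <- function(x, f) if (is.null(x) || is.null(x[[f]])) NA_real_ else
    as.numeric(x[[f]])
  v <- c(rmp = g(passive, "rmp"),
         input_resistance = g(passive, "input_resistance"),
         tau_m = g(passive, "tau_m"),
         sag_ratio = g(passive, "sag_ratio"),
         sag_amplitude = g(passive, "sag_amplitude"),
         ap_threshold = g(ap, "threshold"),
         ap_amplitude = g(ap, "amplitude"),
         ap_half_width = g(ap, "half_width"),
         upstroke_downstroke_ratio = g(ap, "upstroke_downstroke_ratio"),
         ahp_amplitude = g(ap, "ahp_amplitude"),
         rheobase = g(train, "rheobase"),
         latency = g(ap, "latency"),
         fi_slope = g(train, "fi_slope"),
         avg_rate_hero = g(train, "avg_rate_hero"))
  structure(list(values = v, mask = !is.na(v)), class = "feature_vector")
}

#' Feature table from a list of feature vectors
#'
#' @param fvs named list of `feature_vector` objects (names = cell ids).
#' @return data frame, one row per cell: `cell_id`, the 14 feature columns,
#'   and `n_missing`.
#' @export
feature_table <- function(fvs) {
  rows <- lapply(names(fvs), function(id) {
    v <- fvs[[id]]$values
    cbind(data.frame(cell_id = id), as.data.frame(as.list(v)),
          data.frame(n_missing = sum(!fvs[[id]]$mask)))
  })
  do.call(rbind, rows)
}

#' Two-dimensional embedding of a cohort feature table
#'
#' Cells missing more than `max_missing` of the 14 features are dropped
#' (reported); remaining missing entries are imputed by the feature median.
#' Features are standardized to zero mean and unit variance, then embedded
#' with UMAP (default parameters), deterministically for a fixed seed.
#'
#' @param table data frame as from [feature_table()] (columns beyond the 14
#'   features are carried through as annotations).
#' @param seed integer seed.
#' @param max_missing maximum missing features per retained cell (default 2).
#' @param n_neighbors UMAP neighborhood size (default 15, capped below the
#'   cohort size).
#' @return object of class `embedding_result`: `coords` (data frame
#'   `cell_id`, `umap1`, `umap2` + annotations), `dropped` (cell ids),
#'   `seed`, `parameters`.
#' @export
embed_cohort <- function(table, seed = 0L, max_missing = 2, n_neighbors = 15) {
  stopifnot(all(.feature_names %in% names(table)))
  X <- as.matrix(table[, .feature_names])
  miss <- rowSums(is.na(X))
  keep <- miss <= max_missing
  dropped <- table$cell_id[!keep]
  X <- X[keep, , drop = FALSE]
  if (nrow(X) < 10) stop("need at least 10 cells with sufficient features")
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- median(X[, j], na.rm = TRUE)
  }
  keep_col <- apply(X, 2, sd) > 0
  Z <- scale(X[, keep_col, drop = FALSE])
  nn <- min(n_neighbors, nrow(Z) - 1)
  co <- with_seed(seed,
                  uwot::umap(Z, n_neighbors = nn, n_threads = 1,
                             n_sgd_threads = 1))
  ann <- table[keep, setdiff(names(table), .feature_names), drop = FALSE]
  coords <- cbind(data.frame(umap1 = co[, 1], umap2 = co[, 2]), ann)
  structure(list(coords = coords, dropped = dropped, seed = seed,
                 parameters = list(n_neighbors = nn, max_missing = max_missing,
                                   features = .feature_names[keep_col])),
            class = "embedding_result")
}

#' Rank-based two-group statistics
#'
#' Independent design: two-sided rank-sum (Mann-Whitney). Paired design:
#' Wilcoxon matched-pairs signed-rank (as used for before/after drug
#' comparisons). A paired comparison with no nonzero differences returns
#' p = 1.
#'
#' @param x,y numeric samples (equal length for paired).
#' @param design `"independent"` or `"paired"`.
#' @return list with `statistic` and `p_value`.
#' @export
group_stats <- function(x, y, design = c("independent", "paired")) {
  design <- match.arg(design)
  if (design == "paired") {
    if (length(x) != length(y))
      stop("paired design requires equal-length matched samples")
    if (all(x == y)) return(list(statistic = 0, p_value = 1))
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  } else {
    ht <- suppressWarnings(wilcox.test(x, y))
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}
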