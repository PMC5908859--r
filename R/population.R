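#' Relative scaling of a per-cell parameter
#'
#' Divides every value by the snapshot mean, so the rescaled column is
#' dimensionless with mean exactly 1. This is the transformation behind the
#' relative population parameters RCS, RCCA, RCLA, RCCD, and RCLD, and it
#' makes snapshots from different timepoints comparable on one axis.
#'
#' @param values Numeric vector of non-negative per-cell values, mean > 0.
#' @return Numeric vector of the same length with mean 1.
#' @export
relativize <- function(values) {
  if (length(values) < 1L) stop("empty input", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("degenerate-scale error: snapshot mean must be positive",
         call. = FALSE)
  values / m
}

#' Build a population snapshot
#'
#' Attaches the five relative columns to a per-cell table of one timepoint and
#' condition: RCS (relative cell size, from `pixel_count`), RCCA (chlorophyll
#' amount), RCLA (lipid amount), RCCD (chlorophyll density), and RCLD (lipid
#' density), each computed with [relativize()].
#'
#' @param records Data frame of cell records sharing one timepoint and
#'   condition.
#' @return The input data frame with columns `RCS`, `RCCA`, `RCLA`, `RCCD`,
#'   `RCLD` appended; class `population_snapshot`.
#' @export
build_snapshot <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) < 1L) stop("empty snapshot", call. = FALSE)
  tp <- unique(records$timepoint)
  cd <- unique(records$condition)
  if (length(tp[!is.na(tp)]) > 1L || length(cd[!is.na(cd)]) > 1L)
    stop("grouping error: records mix timepoints or conditions", call. = FALSE)
  records$RCS  <- relativize(records$pixel_count)
  records$RCCA <- relativize(records$chl_amount)
  records$RCLA <- relativize(records$lipid_amount)
  records$RCCD <- relativize(records$chl_density)
  records$RCLD <- relativize(records$lipid_density)
  class(records) <- c("population_snapshot", "data.frame")
  records
}

#' Spearman rank correlation
#'
#' Spearman's rho with mid-rank (average) tie handling: the Pearson
#' correlation of the two rank vectors.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("undefined-correlation error: zero rank variance", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Cell-to-cell heterogeneity
#'
#' The coefficient of variation (sample standard deviation over the mean), a
#' dimensionless dispersion measure comparable across parameters and
#' timepoints.
#'
#' @param values Numeric vector, n >= 2, mean > 0.
#' @return Non-negative scalar.
#' @export
heterogeneity <- function(values) {
  if (length(values) < 2L) stop("need at least two cells", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("degenerate error: mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

#' Pairwise Spearman correlations of the relative columns
#'
#' @param snapshot A `population_snapshot` with n >= 3 cells.
#' @param columns Which columns to correlate; defaults to the five relative
#'   parameters.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
correlation_matrix <- function(snapshot,
                               columns = c("RCS", "RCCA", "RCLA",
                                           "RCCD", "RCLD")) {
  stopifnot(inherits(snapshot, "population_snapshot"))
  if (nrow(snapshot) < 3L) stop("need n >= 3 cells", call. = FALSE)
  k <- length(columns)
  m <- diag(1, k)
  dimnames(m) <- list(columns, columns)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    rho <- spearman_rho(snapshot[[columns[i]]], snapshot[[columns[j]]])
    m[i, j] <- m[j, i] <- rho
  }
  m
}

#' Fit a transition-state model from a baseline population
#'
#' Transition states are bands of ABSOLUTE lipid density anchored at the
#' starting (day-0) population: the baseline statistic times the fold
#' thresholds partitions `[0, Inf)` into `length(folds) + 1` states. The
#' default folds `c(2, 10)` give the states "Start-RCLD", "2-fold", and
#' "10-fold". Anchoring uses absolute density, not the per-snapshot relative
#' RCLD, because each snapshot renormalizes to mean 1 and would erase the
#' day-0 reference.
#'
#' @param baseline A non-empty `population_snapshot` (or cell-record data
#'   frame) of the starting population.
#' @param folds Strictly increasing fold multipliers, all > 1.
#' @param baseline_fun Statistic summarizing the baseline lipid density;
#'   `"median"` (default, robust to the day-0 right tail) or `"mean"`.
#' @return A list of class `transition_state_model` with `baseline_stat`,
#'   `fold_thresholds` (absolute densities), and `state_labels`.
#' @export
fit_transition_model <- function(baseline, folds = c(2, 10),
                                 baseline_fun = c("median", "mean")) {
  baseline <- as.data.frame(baseline)
  if (nrow(baseline) < 1L) stop("model error: empty baseline", call. = FALSE)
  if (length(folds) < 1L || any(folds <= 1) || any(diff(folds) <= 0))
    stop("ordering error: folds must be strictly increasing and > 1",
         call. = FALSE)
  baseline_fun <- match.arg(baseline_fun)
  stat <- switch(baseline_fun,
                 median = stats::median(baseline$lipid_density),
                 mean = mean(baseline$lipid_density))
  labels <- c("Start-RCLD", paste0(format(folds, trim = TRUE), "-fold"))
  structure(list(baseline_stat = stat,
                 folds = folds,
                 fold_thresholds = stat * folds,
                 state_labels = labels,
                 baseline_fun = baseline_fun),
            class = "transition_state_model")
}

#' Assign cells to transition states
#'
#' Each cell is placed by its absolute lipid density into the interval
#' containing it; a cell exactly at a threshold belongs to the higher state
#' (a density of exactly twice the baseline is "2-fold").
#'
#' @param model A `transition_state_model`.
#' @param snapshot A non-empty `population_snapshot` or cell-record data
#'   frame.
#' @return Named numeric vector of per-state population fractions, summing
#'   to 1.
#' @export
assign_states <- function(model, snapshot) {
  stopifnot(inherits(model, "transition_state_model"))
  snapshot <- as.data.frame(snapshot)
  if (nrow(snapshot) < 1L) stop("empty snapshot", call. = FALSE)
  d <- snapshot$lipid_density
  # state index = 1 + number of thresholds at or below the density
  idx <- 1L + rowSums(outer(d, model$fold_thresholds, ">="))
  counts <- tabulate(idx, nbins = length(model$state_labels))
  stats::setNames(counts / length(d), model$state_labels)
}

#' Summarize a time course of per-cell records
#'
#' Splits a combined cell table by timepoint and condition, builds a snapshot
#' for each group, and reports population size, means, cell-to-cell
#' heterogeneity (CV) of each relative parameter, the pairwise Spearman
#' correlations, and the transition-state fractions anchored at the baseline
#' timepoint.
#'
#' @param records Combined cell-record data frame covering >= 1 timepoints.
#' @param baseline_time Timepoint (days) anchoring the transition-state model;
#'   must be present in `records`.
#' @param folds Fold thresholds, as in [fit_transition_model()].
#' @param exclude_saturated Drop cells with any lipid-channel saturation
#'   before analysis (default FALSE: saturated cells are kept but flagged in
#'   the per-cell table).
#' @return Data frame with one row per timepoint x condition.
#' @export
summarize_time_course <- function(records, baseline_time = 0, folds = c(2, 10),
                                  exclude_saturated = FALSE) {
  records <- as.data.frame(records)
  if (exclude_saturated)
    records <- records[records$saturated_fraction_lipid == 0, , drop = FALSE]
  records$condition <- ifelse(is.na(records$condition), "unspecified",
                              as.character(records$condition))
  if (!any(records$timepoint == baseline_time, na.rm = TRUE))
    stop("analysis error: baseline timepoint ", baseline_time,
         " not present in the table", call. = FALSE)
  groups <- split(records,
                  list(records$condition, records$timepoint), drop = TRUE)
  models <- list()
  for (g in groups) {
    if (isTRUE(unique(g$timepoint) == baseline_time))
      models[[unique(g$condition)]] <- fit_transition_model(build_snapshot(g),
                                                            folds)
  }
  rows <- lapply(groups, function(g) {
    snap <- build_snapshot(g)
    cond <- unique(g$condition)
    cm <- if (nrow(snap) >= 3L)
      tryCatch(correlation_matrix(snap), error = function(e) NULL) else NULL
    model <- models[[cond]]
    fr <- if (!is.null(model)) assign_states(model, snap) else NULL
    out <- data.frame(timepoint = unique(g$timepoint), condition = cond,
                      n = nrow(snap),
                      mean_pixel_count = mean(snap$pixel_count),
                      mean_chl_amount = mean(snap$chl_amount),
                      mean_lipid_amount = mean(snap$lipid_amount),
                      mean_chl_density = mean(snap$chl_density),
                      mean_lipid_density = mean(snap$lipid_density),
                      stringsAsFactors = FALSE)
    for (p in c("RCS", "RCCA", "RCLA", "RCCD", "RCLD"))
      out[[paste0("cv_", p)]] <-
        if (nrow(snap) >= 2L) heterogeneity(snap[[p]]) else NA_real_
    for (pair in list(c("RCS", "RCCA"), c("RCS", "RCLA"), c("RCS", "RCCD"),
                      c("RCS", "RCLD"), c("RCCD", "RCLD")))
      out[[paste0("rho_", pair[1L], "_", pair[2L])]] <-
        if (!is.null(cm)) cm[pair[1L], pair[2L]] else NA_real_
    if (!is.null(fr))
      for (s in seq_along(fr))
        out[[paste0("frac_state", s)]] <- fr[[s]]
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$condition, res$timepoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}
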