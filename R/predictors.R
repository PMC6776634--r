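#' Local unit density and basal rate under the probe
#'
#' `d5` counts units within `radius` electrode distances (Euclidean,
#' inclusive) of the indentation center; `r5` is the mean basal firing rate
#' of those units over `basal_interval` (`NA` when `d5 = 0`).
#'
#' @param spikes A `spike_train_set`.
#' @param center Indentation-center electrode coordinate (row, col).
#' @param radius Neighbourhood radius in electrode pitches.
#' @param basal_interval `c(t0, t1)` basal window, s; whole recording by
#'   default.
#' @return List with `d5` (count) and `r5` (Hz or `NA`).
#' @export
local_density_rate <- function(spikes, center, radius = 5,
                               basal_interval = NULL) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (is.null(basal_interval)) basal_interval <- c(0, spikes$duration_s)
  pos <- cbind(spikes$units$electrode_row, spikes$units$electrode_col)
  near <- electrode_distance(pos, center) <= radius
  d5 <- sum(near)
  r5 <- if (d5 == 0) NA_real_ else {
    span <- diff(basal_interval)
    mean(vapply(spikes$spikes[near], function(st) {
      sum(st >= basal_interval[1] & st < basal_interval[2]) / span
    }, numeric(1)))
  }
  list(d5 = d5, r5 = r5)
}

#' Assemble the per-trial feature table
#'
#' Joins, for every indentation trial, the physical predictors (Hertzian
#' contact area, strain, pressure, depth) with the electrophysiological
#' ones (d5, r5) and the binary outcome (firing-rate modulation detected).
#' Trials with any missing feature are dropped with a message.
#'
#' @param trials Data.frame with `trial_id`, `depth_um`, `max_load_un`,
#'   `probe_radius_um`, `center_row`, `center_col`, `outcome` (logical),
#'   and optionally `basal_start_s` / `basal_end_s`.
#' @param spikes A `spike_train_set` (for d5/r5).
#' @param radius Electrode radius for [local_density_rate()].
#' @return A `trial_feature_table` data.frame: `trial_id`,
#'   `contact_area_um2`, `strain`, `pressure_pa`, `depth_um`, `d5`, `r5`,
#'   `outcome`.
#' @export
build_feature_table <- function(trials, spikes, radius = 5) {
  req <- c("trial_id", "depth_um", "max_load_un", "probe_radius_um",
           "center_row", "center_col", "outcome")
  if (!all(req %in% names(trials))) {
    stop_invalid("trials must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(trials$trial_id)) {
    stop(structure(class = c("retinamech_consistency_error", "error", "condition"),
                   list(message = "duplicate trial ids", call = sys.call())))
  }
  if (!is.logical(trials$outcome)) stop_invalid("outcome must be logical")
  if (!nrow(trials)) {
    return(structure(data.frame(trial_id = integer(0), contact_area_um2 = numeric(0),
                                strain = numeric(0), pressure_pa = numeric(0),
                                depth_um = numeric(0), d5 = integer(0),
                                r5 = numeric(0), outcome = logical(0)),
                     class = c("trial_feature_table", "data.frame")))
  }
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    ps <- trial_pressure_strain(tr$max_load_un, tr$probe_radius_um, tr$depth_um)
    bi <- if (all(c("basal_start_s", "basal_end_s") %in% names(trials))) {
      c(tr$basal_start_s, tr$basal_end_s)
    } else NULL
    lr <- local_density_rate(spikes, c(tr$center_row, tr$center_col),
                             radius = radius, basal_interval = bi)
    data.frame(trial_id = tr$trial_id,
               contact_area_um2 = ps$contact_area_um2, strain = ps$strain,
               pressure_pa = ps$pressure_pa, depth_um = tr$depth_um,
               d5 = lr$d5, r5 = lr$r5, outcome = tr$outcome)
  })
  out <- do.call(rbind, rows)
  complete <- stats::complete.cases(out)
  if (any(!complete)) {
    message(sprintf("dropping %d trial(s) with missing features (ids: %s)",
                    sum(!complete),
                    paste(out$trial_id[!complete], collapse = ", ")))
    out <- out[complete, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("trial_feature_table", "data.frame")
  out
}

# one stratified 80/20 split of row indices by outcome class
stratified_split <- function(outcome, train_frac = 0.8) {
  idx <- seq_along(outcome)
  unlist(lapply(split(idx, outcome), function(g) {
    sample(g, max(1L, round(train_frac * length(g))))
  }), use.names = FALSE)
}

#' Decision-tree feature importance over repeated fits
#'
#' Fits a binary decision tree (Gini criterion, unlimited depth, minimum
#' leaf size 1, no surrogate or competitor splits) `n_repeats` times and
#' reports the mean and SD of the normalized Gini importances, i.e. each
#' feature's share of the total impurity decrease (importances sum to 1 per
#' repeat; features not used in a tree score 0). In mode `"split"` (default)
#' each repeat draws a stratified 80/20 train split with a repeat-specific
#' seed — the meaningful source of variation, since a tree on a fixed table
#' is deterministic; mode `"seed_only"` fits the full table every repeat.
#'
#' @param table A `trial_feature_table` (or data.frame with an `outcome`
#'   column; all other non-id numeric columns are predictors).
#' @param n_repeats Number of repeated fits.
#' @param seed Integer seed.
#' @param repeat_mode `"split"` or `"seed_only"`.
#' @return A `feature_importance` object: list with `importance`
#'   (data.frame: feature, mean_importance, sd_importance), `per_repeat`
#'   (repeats x features matrix), `n_repeats`, `repeat_mode`.
#' @export
feature_importance <- function(table, n_repeats = 1000, seed = NULL,
                               repeat_mode = c("split", "seed_only")) {
  repeat_mode <- match.arg(repeat_mode)
  stopifnot(is.data.frame(table), "outcome" %in% names(table))
  if (nrow(table) < 10) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "need >= 10 trials", call = sys.call())))
  }
  if (length(unique(table$outcome)) < 2) {
    stop(structure(class = c("retinamech_degenerate_outcome", "error", "condition"),
                   list(message = "outcome has a single class", call = sys.call())))
  }
  # canonical (sorted) feature order: tree tie-breaks then cannot depend on
  # the arrangement of the input columns
  feats <- sort(setdiff(names(table), c("outcome", "trial_id")))
  dat <- table[, c(feats, "outcome")]
  dat$outcome <- factor(dat$outcome)
  ctrl <- rpart::rpart.control(cp = 0, minsplit = 2, minbucket = 1,
                               maxsurrogate = 0, maxcompete = 0, xval = 0)
  one_fit <- function(d) {
    fit <- rpart::rpart(outcome ~ ., data = d, method = "class",
                        parms = list(split = "gini"), control = ctrl)
    imp <- fit$variable.importance
    out <- stats::setNames(numeric(length(feats)), feats)
    if (!is.null(imp)) out[names(imp)] <- imp
    s <- sum(out)
    if (s > 0) out / s else out + 1 / length(out)
  }
  per <- with_local_seed(seed, {
    t(vapply(seq_len(n_repeats), function(r) {
      d <- if (repeat_mode == "split") {
        dat[stratified_split(dat$outcome), , drop = FALSE]
      } else {
        dat
      }
      one_fit(d)
    }, numeric(length(feats))))
  })
  imp <- data.frame(feature = feats,
                    mean_importance = colMeans(per),
                    sd_importance = apply(per, 2, stats::sd),
                    row.names = NULL)
  imp <- imp[order(-imp$mean_importance), ]
  rownames(imp) <- NULL
  structure(list(importance = imp, per_repeat = per,
                 n_repeats = n_repeats, repeat_mode = repeat_mode),
            class = "feature_importance")
}

#' @export
print.feature_importance <- function(x, ...) {
  cat(sprintf("<feature_importance: %d repeats, mode '%s'>\n",
              x$n_repeats, x$repeat_mode))
  print(transform(x$importance,
                  mean_importance = round(mean_importance, 4),
                  sd_importance = round(sd_importance, 4)),
        row.names = FALSE)
  invisible(x)
}
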