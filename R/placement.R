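#' Pattern correlation between two normalized series
#'
#' Pearson product-moment correlation between the foot-pressure reference
#' pattern and an IMU roll trace, both already smoothed and standard-score
#' normalized. Equivalent to the sum of cross products of the standardized
#' samples divided by N - 1.
#'
#' @param f,m Numeric vectors or [ski_ts()] of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
pattern_correlation <- function(f, m) {
  fv <- ts_values(f); mv <- ts_values(m)
  if (length(fv) != length(mv))
    stop("series lengths differ (", length(fv), " vs ", length(mv), ")")
  if (length(fv) < 3L) stop("pattern correlation needs at least 3 samples")
  if (stats::sd(fv) == 0 || stats::sd(mv) == 0)
    stop("correlation undefined for a constant series")
  stats::cor(fv, mv)
}

# Per-trial reference pattern: insole ratio -> smooth -> regrid -> zscore
reference_pattern <- function(trial, window = 5L, total_floor = 1) {
  r <- foot_pressure_ratio(trial$insole_left, trial$insole_right,
                           total_floor = total_floor)
  r <- moving_average(r, window)
  r <- resample_to(r, trial$meta$imu_rate_hz)
  zscore(r)
}

#' Per-location, per-trial pattern correlation table
#'
#' For every trial, forms the foot-pressure ratio, smooths it (5-point moving
#' average), resamples it to the IMU grid and z-scores it; applies the same
#' smoothing and normalization to every location's roll trace; and computes
#' the Pearson correlation per location x trial. Row means and medians are
#' appended; the per-location median (robust to the occasional corrupted
#' trial) is the quantity carried into clustering and ranking.
#'
#' @param session A `ski_session` (see [simulate_session()]).
#' @param window Moving-average window (default 5).
#' @param total_floor Validity floor for the pressure ratio.
#' @return A data frame of class `correlation_table`: `location`, one column
#'   per recorded attempt, `mean`, `median`. Missing traces yield `NA` cells
#'   excluded from the summaries.
#' @export
correlation_table <- function(session, window = 5L, total_floor = 1) {
  stopifnot(inherits(session, "ski_session"))
  if (!length(session$trials)) stop("session contains no recorded trials")
  locations <- unique(unlist(lapply(session$trials,
                                    function(tr) names(tr$traces))))
  cols <- lapply(session$trials, function(tr) {
    f <- reference_pattern(tr, window, total_floor)
    n <- length(f$values)
    vapply(locations, function(loc) {
      m <- tr$traces[[loc]]
      if (is.null(m)) return(NA_real_)
      m <- zscore(moving_average(m, window))
      k <- min(n, length(m$values))
      pattern_correlation(f$values[seq_len(k)], m$values[seq_len(k)])
    }, numeric(1))
  })
  tab <- as.data.frame(cols)
  names(tab) <- names(session$trials)
  tab <- cbind(data.frame(location = locations), tab)
  trial_cols <- as.matrix(tab[, -1, drop = FALSE])
  tab$mean <- rowMeans(trial_cols, na.rm = TRUE)
  tab$median <- apply(trial_cols, 1, stats::median, na.rm = TRUE)
  rownames(tab) <- NULL
  class(tab) <- c("correlation_table", "data.frame")
  tab
}

# ---- centroid-linkage agglomerative clustering ------------------------------

# Agglomerative clustering with centroid linkage via the Lance-Williams update
# on squared distances. For points on a line this reproduces the absolute
# difference of cluster means exactly. Ties broken by lowest (i, j) pair in
# the current cluster ordering.
centroid_linkage <- function(d2, labels) {
  n <- nrow(d2)
  if (n < 2L) stop("clustering needs at least 2 leaves")
  size <- rep(1L, n)
  id <- -seq_len(n)          # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  merge_members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (a in seq_len(length(idx) - 1L)) for (b in (a + 1L):length(idx)) {
      i <- idx[a]; j <- idx[b]
      if (d2[i, j] < best_d - 1e-15) { best_d <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- sqrt(max(best_d, 0))
    ni <- size[i]; nj <- size[j]
    for (k in idx) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        (ni * d2[i, k] + nj * d2[j, k]) / (ni + nj) -
        ni * nj * best_d / (ni + nj)^2
    }
    size[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    merge_members[[step]] <- members[[i]]
    active[j] <- FALSE
    id[i] <- step
  }
  ord <- integer(0)
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(merge[node, 1]), leaf_order(merge[node, 2]))
  }
  ord <- leaf_order(n - 1L)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, members = merge_members,
                 method = "centroid"),
            class = "location_dendrogram")
}

#' Hierarchical clustering of body locations by correlation distance
#'
#' Groups candidate locations by how closely their roll pattern tracks the
#' foot-pressure reference, using correlation distance and centroid linkage
#' (inter-cluster distance = absolute difference of cluster centroids).
#'
#' Two readings of the correlation-distance construction are supported.
#' `"reference"` (default): each location is placed at the scalar coordinate
#' 1 - R_l, its median correlation distance to the foot-pressure pattern,
#' and the reference itself enters as a leaf at 0. `"pairwise"`: supply a
#' symmetric matrix of correlation distances among the signals themselves.
#'
#' @param x A `correlation_table` (mode `"reference"`) or a symmetric
#'   distance matrix with dimnames (mode `"pairwise"`).
#' @param mode `"reference"` or `"pairwise"`.
#' @param reference_label Leaf label for the foot-pressure pattern.
#' @return A `location_dendrogram` with hclust-style `merge`, `height`,
#'   `order` and `labels`; convert with [as.hclust()] or export with
#'   [dendrogram_newick()].
#' @export
cluster_locations <- function(x, mode = c("reference", "pairwise"),
                              reference_label = "foot_pressure") {
  mode <- match.arg(mode)
  if (mode == "reference") {
    if (!inherits(x, "correlation_table"))
      stop("reference mode expects a correlation_table")
    ok <- !is.na(x$median)
    if (sum(ok) < 1L) stop("no locations with a valid median correlation")
    coords <- c(0, 1 - x$median[ok])
    labels <- c(reference_label, x$location[ok])
    if (length(coords) < 2L) stop("clustering needs at least 2 leaves")
    d2 <- outer(coords, coords, function(a, b) (a - b)^2)
    dend <- centroid_linkage(d2, labels)
    dend$coordinates <- stats::setNames(coords, labels)
  } else {
    m <- as.matrix(x)
    if (nrow(m) != ncol(m) || is.null(rownames(m)))
      stop("pairwise mode expects a symmetric distance matrix with dimnames")
    dend <- centroid_linkage(m^2, rownames(m))
  }
  dend$mode <- mode
  dend
}

#' @export
print.location_dendrogram <- function(x, ...) {
  cat(sprintf("<location_dendrogram> %d leaves, centroid linkage (%s mode)\n",
              length(x$labels), x$mode))
  cat("merge heights:", paste(signif(x$height, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.hclust.location_dendrogram <- function(x, ...) {
  # centroid linkage can in principle invert; clamp for plotting only
  structure(list(merge = x$merge, height = cummax(x$height), order = x$order,
                 labels = x$labels, method = "centroid",
                 call = match.call(), dist.method = "correlation"),
            class = "hclust")
}

#' Export a dendrogram as Newick text
#'
#' @param x A `location_dendrogram`.
#' @return A single Newick string with merge heights as branch annotations.
#' @export
dendrogram_newick <- function(x) {
  stopifnot(inherits(x, "location_dendrogram"))
  rec <- function(node, parent_h) {
    if (node < 0L) {
      lab <- gsub("[ ,();:]", "_", x$labels[-node])
      return(sprintf("%s:%.6g", lab, parent_h))
    }
    h <- x$height[node]
    sprintf("(%s,%s):%.6g",
            rec(x$merge[node, 1], h), rec(x$merge[node, 2], h),
            max(parent_h - h, 0))
  }
  n <- length(x$labels)
  root <- n - 1L
  h <- x$height[root]
  paste0("(", rec(x$merge[root, 1], h), ",", rec(x$merge[root, 2], h), ");")
}

# ---- zero-crossing turn segmentation ----------------------------------------

#' Segment a roll trace into turns at zero crossings
#'
#' A turn is the interval of constant roll sign between consecutive sign
#' changes: positive roll (leaning right) is a right turn, negative a left
#' turn. A sample exactly at zero closes the preceding segment. Runs shorter
#' than `min_duration_s` are treated as jitter: each is merged into the
#' following run (the last into the preceding one) and same-sign neighbours
#' are coalesced, so a brief blip never splits a turn. `min_duration_s = 0`
#' reproduces raw zero-crossing counting.
#'
#' @param trace A [ski_ts()], normally already smoothed.
#' @param min_duration_s Minimum credible turn duration, seconds (default
#'   0.5).
#' @return Data frame of class `turn_segments`: `start`, `end` (sample
#'   indices), `side` (`"R"`/`"L"`), `duration_s`. Zero rows for an all-zero
#'   trace.
#' @export
zero_crossing_segments <- function(trace, min_duration_s = 0.5) {
  stopifnot(inherits(trace, "ski_ts"))
  if (min_duration_s < 0) stop("min_duration_s must be >= 0")
  v <- trace$values
  n <- length(v)
  empty <- data.frame(start = integer(0), end = integer(0),
                      side = character(0), duration_s = numeric(0))
  nz <- which(v != 0)
  if (!length(nz)) return(structure(empty, class = c("turn_segments", "data.frame")))
  s <- sign(v[nz])
  brk <- which(diff(s) != 0)              # last nz-index of each sign run
  run_first_nz <- nz[c(1L, brk + 1L)]     # first nonzero sample of each run
  run_sign <- s[c(1L, brk + 1L)]
  # segment k opens at the next run's first nonzero sample; any zeros in
  # between close (belong to) the preceding segment
  start <- c(1L, run_first_nz[-1L])
  end <- c(run_first_nz[-1L] - 1L, n)
  side <- ifelse(run_sign > 0, "R", "L")

  min_len <- min_duration_s * trace$rate_hz
  repeat {
    len <- end - start + 1L
    if (length(len) <= 1L) break
    k <- which(len < min_len)[1]
    if (is.na(k)) break
    if (k < length(len)) {            # merge into the following run
      start[k + 1L] <- start[k]
      start <- start[-k]; end <- end[-k]; side <- side[-k]
    } else {                          # trailing short run -> preceding
      end[k - 1L] <- end[k]
      start <- start[-k]; end <- end[-k]; side <- side[-k]
    }
    # coalesce neighbours that now share a side
    j <- 1L
    while (j < length(side)) {
      if (side[j] == side[j + 1L]) {
        end[j] <- end[j + 1L]
        start <- start[-(j + 1L)]; end <- end[-(j + 1L)]; side <- side[-(j + 1L)]
      } else j <- j + 1L
    }
  }
  structure(data.frame(start = start, end = end, side = side,
                       duration_s = (end - start + 1L) / trace$rate_hz),
            class = c("turn_segments", "data.frame"))
}

#' Turn-detection measure
#'
#' Detected turns divided by the actual turn count, as an integer
#' percentage. 100 exactly when detection is perfect; values above 100
#' indicate spurious zero crossings, below 100 missed turns.
#'
#' @param detected Number of detected turns (>= 0).
#' @param actual True number of turns (>= 1).
#' @return Integer percentage.
#' @examples
#' turn_detection_measure(7, 7)   # 100
#' turn_detection_measure(9, 7)   # 129
#' @export
turn_detection_measure <- function(detected, actual) {
  if (length(actual) != 1L || is.na(actual) || actual < 1)
    stop("actual turn count must be >= 1")
  if (detected < 0) stop("detected turn count must be >= 0")
  as.integer(round(detected / actual * 100))
}

#' Turn-detection table across locations and trials
#'
#' Smooths every location's trace, segments it at zero crossings and scores
#' the detection measure against the manifest's true turn count per trial.
#' `min_duration_s = 0` (raw crossing counting) matches field practice for
#' reporting; a positive value suppresses jitter crossings.
#'
#' @param session A `ski_session`.
#' @param min_duration_s Passed to [zero_crossing_segments()] (default 0).
#' @param window Moving-average window (default 5).
#' @return Data frame of class `detection_table`: `location`, one integer
#'   column per attempt, `average`.
#' @export
detection_table <- function(session, min_duration_s = 0, window = 5L) {
  stopifnot(inherits(session, "ski_session"))
  locations <- unique(unlist(lapply(session$trials,
                                    function(tr) names(tr$traces))))
  cols <- lapply(session$trials, function(tr) {
    actual <- tr$meta$n_turns
    vapply(locations, function(loc) {
      m <- tr$traces[[loc]]
      if (is.null(m)) return(NA_integer_)
      seg <- zero_crossing_segments(moving_average(m, window), min_duration_s)
      turn_detection_measure(nrow(seg), actual)
    }, integer(1))
  })
  tab <- as.data.frame(cols)
  names(tab) <- names(session$trials)
  tab <- cbind(data.frame(location = locations), tab)
  tab$average <- rowMeans(as.matrix(tab[, -1, drop = FALSE]), na.rm = TRUE)
  rownames(tab) <- NULL
  class(tab) <- c("detection_table", "data.frame")
  tab
}

#' Rank candidate IMU locations and select the best placement
#'
#' Flags each location for strong correlation (median pattern correlation at
#' or above `correlation_threshold`) and perfect detection (every trial and
#' the average at exactly 100). Ranking: both flags first, then higher median
#' correlation, then fewer sensors required (midline placements, which need a
#' single sensor, rank above left/right pairs), ties broken alphabetically.
#' The sensor-count rule is a computable proxy for the practical criteria
#' (attachment effort, distraction) that favour a single midline sensor.
#'
#' @param cor_table A [correlation_table()].
#' @param det_table A [detection_table()].
#' @param correlation_threshold Strong-correlation cutoff (default 0.80, the
#'   conventional bound for a strong correlation).
#' @param dendrogram Optional `location_dendrogram` carried into the report.
#' @return A list of class `placement_report`: `ranking` (data frame with
#'   flags), `selected` (best location or `NA` if no location passes both
#'   screens), `candidates`, plus the input tables.
#' @export
rank_locations <- function(cor_table, det_table, correlation_threshold = 0.80,
                           dendrogram = NULL) {
  stopifnot(inherits(cor_table, "correlation_table"),
            inherits(det_table, "detection_table"))
  med <- stats::setNames(cor_table$median, cor_table$location)
  trial_cols <- setdiff(names(det_table), c("location", "average"))
  det_cells <- as.matrix(det_table[, trial_cols, drop = FALSE])
  perfect <- apply(det_cells, 1, function(r) all(!is.na(r) & r == 100)) &
    det_table$average == 100
  loc <- det_table$location
  midline <- !grepl("_(L|R)$", loc)
  ranking <- data.frame(
    location = loc,
    median_correlation = as.numeric(med[loc]),
    strong_correlation = !is.na(med[loc]) & med[loc] >= correlation_threshold,
    perfect_detection = perfect,
    midline = midline)
  ranking$pass <- ranking$strong_correlation & ranking$perfect_detection
  ord <- order(-ranking$pass, -ranking$median_correlation, -ranking$midline,
               ranking$location)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  candidates <- ranking$location[ranking$pass]
  structure(list(ranking = ranking,
                 candidates = candidates,
                 selected = if (length(candidates)) candidates[1] else NA_character_,
                 correlation_threshold = correlation_threshold,
                 correlation_table = cor_table,
                 detection_table = det_table,
                 dendrogram = dendrogram),
            class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat("<placement_report>\n")
  if (is.na(x$selected)) {
    cat("no location passes both screens (threshold ",
        x$correlation_threshold, ")\n", sep = "")
  } else {
    cat("selected location:", x$selected, "\n")
  }
  print(x$ranking, digits = 3)
  invisible(x)
}
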