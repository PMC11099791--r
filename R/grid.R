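# Three-dimensional beat-interval density-grid classifier: 60 ms cubic
# cells over a 6000 ms per-axis domain, one occupancy count per diagnosis.

#' Density-grid geometry
#'
#' @param cell_edge Cell edge in ms (default 60).
#' @param axis_max Per-axis domain upper bound in ms, half-open (default
#'   6000, so the default grid has `(6000/60)^3` = 1,000,000 cells).
#' @return Object of class `grid_geometry` with `cell_edge`, `axis_max`,
#'   `n_bins` and `n_cells`.
#' @export
grid_geometry <- function(cell_edge = 60, axis_max = 6000) {
  stopifnot(cell_edge > 0, axis_max > 0)
  n_bins <- axis_max / cell_edge
  if (n_bins != round(n_bins)) {
    stop("axis_max must be a multiple of cell_edge", call. = FALSE)
  }
  structure(list(cell_edge = cell_edge, axis_max = axis_max,
                 n_bins = as.integer(n_bins),
                 n_cells = as.integer(round(n_bins^3))),
            class = "grid_geometry")
}

#' Cell index of interval triples
#'
#' Maps each triple to its zero-based `(i, j, k)` cell by floor division of
#' each interval by the cell edge. Triples with any interval outside the
#' half-open domain `[0, axis_max)` fall outside the grid (all-`NA` row)
#' and will receive no decision.
#'
#' @param triples Numeric matrix of triples (columns `rr1`, `rr2`, `rr3`)
#'   or a single length-3 vector.
#' @param geometry A [grid_geometry()].
#' @return Integer matrix with columns `i`, `j`, `k`; `NA` rows are outside.
#' @examples
#' cell_index(c(660, 2633, 1336))  # 11 43 22
#' @export
cell_index <- function(triples, geometry = grid_geometry()) {
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1)
  ijk <- floor(triples / geometry$cell_edge)
  outside <- rowSums(triples < 0 | triples >= geometry$axis_max) > 0
  ijk[outside, ] <- NA
  storage.mode(ijk) <- "integer"
  colnames(ijk) <- c("i", "j", "k")
  ijk
}

# linear cell key (0-based) from the index matrix; NA for outside
cell_key <- function(ijk, geometry) {
  n <- geometry$n_bins
  as.numeric(ijk[, 1]) + n * as.numeric(ijk[, 2]) + n^2 * as.numeric(ijk[, 3])
}

#' Train the Poincaré density grid
#'
#' Accumulates every in-domain interval triple of each labelled recording
#' into its cell under the recording's diagnosis. Out-of-domain triples are
#' tallied separately per class. Cells are stored sparsely.
#'
#' @param cohort List of labelled [rr_series()] (each with `label` set), or
#'   a list of `list(series, label)` pairs.
#' @param geometry A [grid_geometry()].
#' @return Object of class `grid_model`: sparse cell keys, a cells-by-class
#'   count matrix, per-class in-domain totals, per-class outside tallies,
#'   and the geometry.
#' @export
train_grid <- function(cohort, geometry = grid_geometry()) {
  classes <- diagnosis_levels()
  parts <- lapply(cohort, function(rec) {
    if (inherits(rec, "rr_series")) {
      list(series = rec, label = rec$label)
    } else {
      list(series = rec[[1]], label = rec[[2]])
    }
  })
  labels <- vapply(parts, function(p) {
    if (is.null(p$label)) NA_character_ else p$label
  }, "")
  if (anyNA(labels)) stop("every training recording needs a label", call. = FALSE)
  missing <- setdiff(classes, unique(labels))
  if (length(missing)) {
    stop(sprintf("training cohort is missing class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  outside <- stats::setNames(numeric(3), classes)
  keys_by_class <- stats::setNames(vector("list", 3), classes)
  for (p in parts) {
    tr <- extract_triples(p$series)
    if (!nrow(tr)) next
    k <- cell_key(cell_index(tr, geometry), geometry)
    outside[p$label] <- outside[p$label] + sum(is.na(k))
    keys_by_class[[p$label]] <- c(keys_by_class[[p$label]], k[!is.na(k)])
  }
  tabs <- lapply(keys_by_class, function(k) table(k))
  all_keys <- sort(unique(as.numeric(unlist(lapply(tabs, names)))))
  counts <- matrix(0, nrow = length(all_keys), ncol = 3,
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    tab <- tabs[[cl]]
    if (length(tab)) {
      counts[match(as.numeric(names(tab)), all_keys), cl] <- as.numeric(tab)
    }
  }
  structure(
    list(geometry = geometry, class_levels = classes,
         keys = all_keys, counts = counts,
         class_totals = colSums(counts), outside = outside),
    class = "grid_model")
}

#' @export
print.grid_model <- function(x, ...) {
  cat(sprintf("<grid_model> %d of %d cells occupied (%.0f ms cells)\n",
              length(x$keys), x$geometry$n_cells, x$geometry$cell_edge))
  tot <- x$class_totals
  for (cl in x$class_levels) {
    cat(sprintf("  %-9s %d in-domain triples (+%d outside)\n",
                cl, as.integer(tot[cl]), as.integer(x$outside[cl])))
  }
  invisible(x)
}

#' Classify interval triples with the density grid
#'
#' Each triple's cell is labelled by the class with the highest occupancy
#' there; with `normalize = TRUE` (default) occupancy is the per-class
#' density `count / class_total`, so a large training class cannot annex
#' shared cells by volume alone. Exact ties resolve in the fixed class
#' order. Triples in untouched cells, or outside the grid, get
#' `"NO_DECISION"` — the grid never guesses.
#'
#' @param model A trained [train_grid()] model.
#' @param triples Triple matrix (or length-3 vector).
#' @param normalize Use per-class normalised densities (default) rather
#'   than raw counts to label a cell.
#' @return Character vector over `c(diagnosis_levels(), "NO_DECISION")`.
#' @export
classify_triples <- function(model, triples, normalize = TRUE) {
  if (is.null(dim(triples))) triples <- matrix(triples, nrow = 1)
  out <- rep("NO_DECISION", nrow(triples))
  if (!nrow(triples)) return(out)
  k <- cell_key(cell_index(triples, model$geometry), model$geometry)
  row <- match(k, model$keys)
  hit <- !is.na(row)
  if (any(hit)) {
    cnt <- model$counts[row[hit], , drop = FALSE]
    score <- if (normalize) {
      sweep(cnt, 2, pmax(model$class_totals, 1), "/")
    } else {
      cnt
    }
    out[hit] <- model$class_levels[max.col(score, ties.method = "first")]
  }
  out
}

# Rolling-appraisal vote: interval i inherits the labels of the (up to 3)
# triples containing it; plurality ignoring NO_DECISION, exact ties to the
# fixed class order; all-abstaining -> NO_DECISION.
rolling_vote <- function(triple_labels, n_intervals, class_levels) {
  codes <- match(triple_labels, class_levels)  # NA = NO_DECISION
  pad <- function(pre, post) c(rep(NA_integer_, pre), codes, rep(NA_integer_, post))
  va <- pad(2, 0)[seq_len(n_intervals)]
  vb <- pad(1, 1)[seq_len(n_intervals)]
  vc <- pad(0, 2)[seq_len(n_intervals)]
  cnt <- vapply(seq_along(class_levels), function(cl) {
    (!is.na(va) & va == cl) + (!is.na(vb) & vb == cl) + (!is.na(vc) & vc == cl)
  }, numeric(n_intervals))
  if (n_intervals == 1L) cnt <- matrix(cnt, nrow = 1)
  any_vote <- rowSums(cnt) > 0
  lab <- rep("NO_DECISION", n_intervals)
  lab[any_vote] <- class_levels[max.col(cnt[any_vote, , drop = FALSE],
                                        ties.method = "first")]
  lab
}

make_classification_result <- function(interval_labels, class_levels) {
  lv <- c(class_levels, "NO_DECISION")
  fr <- table(factor(interval_labels, levels = lv)) / length(interval_labels)
  fractions <- stats::setNames(as.numeric(fr), lv)
  diagnosis <- if (all(fractions[class_levels] == 0)) {
    "NO_DECISION"  # every interval abstained
  } else {
    class_levels[which.max(fractions[class_levels])]
  }
  structure(list(interval_class = interval_labels, fractions = fractions,
                 diagnosis = diagnosis),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> diagnosis: %s\n", x$diagnosis))
  fr <- sort(x$fractions, decreasing = TRUE)
  for (nm in names(fr)) cat(sprintf("  %-12s %.3f\n", nm, fr[nm]))
  invisible(x)
}

#' Classify a recording with the density grid
#'
#' Runs the rolling three-position appraisal: every interval is judged in
#' the first, second and third slot of the overlapping triples that contain
#' it and receives the plurality of those (up to 3) cell labels, ignoring
#' abstentions; an interval whose every triple abstains is `NO_DECISION`.
#' The recording-level diagnosis is the class with the largest fraction of
#' intervals ("relative sureness"); abstentions count in the fractions but
#' never in the diagnosis.
#'
#' @param model A trained [train_grid()] model.
#' @param series [rr_series()] with at least 3 intervals.
#' @param normalize Passed to [classify_triples()].
#' @return A `classification_result`: per-interval classes, class
#'   fractions over `{BALANCED, HPLSM, SND, NO_DECISION}`, and `diagnosis`.
#' @export
classify_series <- function(model, series, normalize = TRUE) {
  n <- length(series$intervals)
  if (n < 3L) stop("need at least 3 intervals to classify", call. = FALSE)
  lab <- classify_triples(model, extract_triples(series), normalize = normalize)
  make_classification_result(rolling_vote(lab, n, model$class_levels),
                             model$class_levels)
}

#' Confusion matrix of recording diagnoses
#'
#' @param actual,predicted Equal-length vectors of diagnosis labels.
#' @return 3 x 3 integer matrix, predicted in rows, actual in columns
#'   (column sums are the actual class sizes).
#' @export
confusion_matrix <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  lv <- diagnosis_levels()
  tab <- table(factor(predicted, levels = lv), factor(actual, levels = lv))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(predicted = lv, actual = lv))
  m
}

#' Persist and restore a density-grid model
#'
#' The grid is stored as JSON: geometry header, per-class totals and
#' outside tallies, and a sparse `cell key -> per-class counts` map.
#'
#' @param model A `grid_model`.
#' @param path File path.
#' @return `write_grid_model()` returns `path` invisibly;
#'   `read_grid_model()` returns the restored `grid_model`.
#' @export
write_grid_model <- function(model, path) {
  obj <- list(
    type = "grid_model",
    geometry = list(cell_edge = model$geometry$cell_edge,
                    axis_max = model$geometry$axis_max),
    class_levels = model$class_levels,
    class_totals = as.list(model$class_totals),
    outside = as.list(model$outside),
    keys = model$keys,
    counts = model$counts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_model
#' @export
read_grid_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "grid_model")) {
    stop("not a grid model file", call. = FALSE)
  }
  geometry <- grid_geometry(obj$geometry$cell_edge, obj$geometry$axis_max)
  counts <- matrix(as.numeric(obj$counts), ncol = 3,
                   dimnames = list(NULL, obj$class_levels))
  structure(
    list(geometry = geometry, class_levels = obj$class_levels,
         keys = as.numeric(obj$keys), counts = counts,
         class_totals = unlist(obj$class_totals)[obj$class_levels],
         outside = unlist(obj$outside)[obj$class_levels]),
    class = "grid_model")
}
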