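#' Load one participant's ROI time series from a TSV file
#'
#' Expects a header row of region labels and an all-numeric body with one row
#' per time point (no index column). Parsing is strict: ragged rows,
#' non-numeric cells and duplicate labels are reported with the offending
#' line; constant (zero-variance) regions load with a warning naming them.
#'
#' @param path TSV file path.
#' @param id participant id; defaults to the file name without extension.
#' @param tr repetition time in seconds (metadata only).
#' @return object of class `roi_timeseries` with fields `id`, `x`
#'   (time x regions matrix), `region_labels`, `tr`.
#' @export
load_roi_timeseries <- function(path, id = NULL, tr = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("file has no data rows: ", path)
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(labels)) {
    stop("duplicate region labels in header (line 1): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  p <- length(labels)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  n <- length(body)
  x <- matrix(NA_real_, n, p, dimnames = list(NULL, labels))
  for (r in seq_len(n)) {
    row <- body[[r]]
    if (length(row) != p) {
      stop("ragged row at line ", r + 1, ": expected ", p, " fields, found ",
           length(row))
    }
    vals <- suppressWarnings(as.numeric(row))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      stop("non-numeric cell at line ", r + 1, ", column ", bad,
           " (", labels[bad], "): '", row[bad], "'")
    }
    x[r, ] <- vals
  }
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("constant (zero-variance) regions: ",
            paste(labels[sds == 0], collapse = ", "))
  }
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(id = id, x = x, region_labels = labels, tr = tr),
            class = "roi_timeseries")
}

#' Sliding-window parameters
#'
#' @param window_length window length in TRs (default 10, i.e. 30 s at
#'   TR = 3 s).
#' @param step window step in TRs (default 1).
#' @return object of class `window_params`.
#' @export
window_params <- function(window_length = 10, step = 1) {
  stopifnot(step >= 1, window_length >= step)
  structure(list(window_length = as.integer(window_length),
                 step = as.integer(step)),
            class = "window_params")
}

#' Sliding-window functional connectivity
#'
#' Computes the Pearson correlation matrix of every rectangular window
#' `[i*step, i*step + window_length)` (0-based, half-open) of one
#' participant's time series, yielding `floor((T - window_length)/step) + 1`
#' symmetric matrices stored as edge vectors. A region with zero variance
#' inside a window gets 0-valued correlations for that window and the event
#' is recorded in per-window flags (no NaN propagates downstream).
#'
#' @param ts a `roi_timeseries` (or plain time x regions matrix).
#' @param params a [window_params()].
#' @param id participant id when `ts` is a plain matrix.
#' @param tr repetition time in seconds when `ts` is a plain matrix.
#' @return object of class `windowed_fc` with fields `id`, `edges`
#'   (windows x edges matrix), `n_regions`, `region_labels`, `starts`
#'   (0-based), `window_length`, `step`, `tr`, `flags` (per-window list of
#'   zero-variance regions).
#' @export
sliding_window_fc <- function(ts, params = window_params(), id = "participant",
                              tr = 3) {
  if (inherits(ts, "roi_timeseries")) {
    x <- ts$x
    id <- ts$id
    tr <- ts$tr
    labels <- ts$region_labels
  } else {
    x <- as.matrix(ts)
    labels <- colnames(x)
    if (is.null(labels)) labels <- sprintf("R%03d", seq_len(ncol(x)))
  }
  if (any(!is.finite(x))) stop("time series contains non-finite values")
  p <- ncol(x)
  tt <- nrow(x)
  wl <- params$window_length
  st <- params$step
  if (p < 2) stop("need at least 2 regions")
  if (tt < wl) stop("time series shorter than the window length")

  n_win <- (tt - wl) %/% st + 1L
  starts <- (seq_len(n_win) - 1L) * st
  n_edges <- p * (p - 1) / 2
  edges <- matrix(NA_real_, n_win, n_edges)
  flags <- vector("list", n_win)

  for (w in seq_len(n_win)) {
    seg <- x[(starts[w] + 1):(starts[w] + wl), , drop = FALSE]
    sds <- apply(seg, 2, sd)
    const <- which(sds == 0)
    if (length(const) == 0) {
      cm <- cor(seg)
    } else {
      cm <- matrix(0, p, p)
      ok <- setdiff(seq_len(p), const)
      if (length(ok) >= 2) cm[ok, ok] <- cor(seg[, ok, drop = FALSE])
      diag(cm) <- 1
      flags[[w]] <- labels[const]
    }
    edges[w, ] <- vectorize_upper(cm)
  }

  structure(list(id = id, edges = edges, n_regions = p,
                 region_labels = labels, starts = starts,
                 window_length = wl, step = st, tr = tr, flags = flags),
            class = "windowed_fc")
}

#' Number of windows in a `windowed_fc`
#' @param wfc a `windowed_fc`.
#' @return integer window count.
#' @export
n_windows <- function(wfc) nrow(wfc$edges)

#' Retrieve one window's full correlation matrix
#' @param wfc a `windowed_fc`.
#' @param i window index (1-based).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
window_matrix <- function(wfc, i) {
  m <- devectorize_upper(wfc$edges[i, ], wfc$n_regions)
  dimnames(m) <- list(wfc$region_labels, wfc$region_labels)
  m
}

#' Windowed FC for every participant file in a cohort directory
#'
#' @param dir cohort directory containing `<id>.tsv` files.
#' @param manifest data frame with at least an `id` column.
#' @param params a [window_params()].
#' @return list of `windowed_fc`, in manifest order.
#' @export
cohort_windows <- function(dir, manifest, params = window_params()) {
  lapply(seq_len(nrow(manifest)), function(i) {
    ts <- load_roi_timeseries(file.path(dir, paste0(manifest$id[i], ".tsv")),
                              id = manifest$id[i])
    sliding_window_fc(ts, params)
  })
}
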