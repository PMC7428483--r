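#' ROI time-series container
#'
#' A volumes-by-nodes numeric matrix with acquisition metadata. This is the
#' central currency of the pipeline: each column is the representative signal
#' of one node (brain region of interest), each row one fMRI volume.
#'
#' @param data Numeric matrix, volumes x nodes, no missing values, at least
#'   2 rows.
#' @param tr_seconds Repetition time between volumes, seconds (default 3).
#' @param node_ids Optional character vector of node labels (defaults to
#'   existing column names or `node001`, ...).
#' @return An object of class `roi_timeseries` (a matrix with attributes).
#' @export
roi_timeseries <- function(data, tr_seconds = 3, node_ids = NULL) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("time series contains missing values")
  if (nrow(data) < 2) stop("at least 2 volumes required")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be positive")
  if (is.null(node_ids)) {
    node_ids <- colnames(data)
    if (is.null(node_ids)) node_ids <- sprintf("node%03d", seq_len(ncol(data)))
  }
  if (length(node_ids) != ncol(data)) stop("node_ids length must match column count")
  colnames(data) <- node_ids
  structure(data, tr_seconds = tr_seconds, class = c("roi_timeseries", "matrix", "array"))
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d volumes x %d nodes, TR = %g s\n",
              nrow(x), ncol(x), attr(x, "tr_seconds")))
  invisible(x)
}

#' Drop initial (non-equilibrium) volumes
#'
#' Removes the first `k` time points, the standard guard against
#' magnetization non-equilibrium at the start of a scan sequence.
#'
#' @param ts A [roi_timeseries()] or a 4-D array (x, y, z, t).
#' @param k Number of leading volumes to drop (default 5); must be smaller
#'   than the number of volumes.
#' @return The same type with `k` fewer time points.
#' @export
drop_initial_volumes <- function(ts, k = 5L) {
  k <- as.integer(k)
  if (k < 0) stop("k must be non-negative")
  if (inherits(ts, "roi_timeseries")) {
    if (k >= nrow(ts)) stop(sprintf("cannot drop %d of %d volumes", k, nrow(ts)))
    if (k == 0L) return(ts)
    roi_timeseries(unclass(ts)[-seq_len(k), , drop = FALSE],
                   tr_seconds = attr(ts, "tr_seconds"))
  } else if (is.array(ts) && length(dim(ts)) == 4L) {
    nt <- dim(ts)[4]
    if (k >= nt) stop(sprintf("cannot drop %d of %d volumes", k, nt))
    if (k == 0L) return(ts)
    out <- ts[, , , -seq_len(k), drop = FALSE]
    attributes(out) <- utils::modifyList(attributes(ts), list(dim = dim(out)))
    out
  } else stop("ts must be a roi_timeseries or a 4-D array")
}

#' Zero-phase high-pass filter
#'
#' Removes slow drifts below `cutoff_hz` from each node's signal with a
#' second-order Butterworth filter applied forward and backward
#' ([signal::filtfilt()]), so the output is zero-phase. Each column is
#' mean-centered as a side effect of DC removal.
#'
#' @param ts A [roi_timeseries()].
#' @param cutoff_hz High-pass cutoff in Hz (default 0.01); must be below the
#'   Nyquist frequency `1 / (2 * TR)`.
#' @param order Butterworth order (default 2).
#' @return A filtered [roi_timeseries()].
#' @export
highpass_filter <- function(ts, cutoff_hz = 0.01, order = 2L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  tr <- attr(ts, "tr_seconds")
  nyquist <- 1 / (2 * tr)
  if (cutoff_hz <= 0 || cutoff_hz >= nyquist)
    stop(sprintf("cutoff %g Hz must lie in (0, Nyquist = %g Hz)", cutoff_hz, nyquist))
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "high")
  m <- unclass(ts)
  T_ <- nrow(m)
  # odd-reflection padding at both ends suppresses filtfilt edge transients;
  # pad length covers roughly three cutoff periods
  P <- min(T_ - 1L, 3L * ceiling(1 / (cutoff_hz * tr)))
  out <- apply(m, 2, function(col) {
    x <- col - mean(col)
    pre <- 2 * x[1] - x[(P + 1):2]
    post <- 2 * x[T_] - x[(T_ - 1):(T_ - P)]
    y <- signal::filtfilt(bf, c(pre, x, post))[(P + 1):(P + T_)]
    y - mean(y)   # DC sits in the stopband; make its removal exact
  })
  roi_timeseries(out, tr_seconds = tr, node_ids = colnames(ts))
}

#' Theoretical amplitude gain of the high-pass filter
#'
#' Magnitude response of the forward-backward Butterworth high-pass at a
#' given frequency (the squared single-pass magnitude, since the filter is
#' applied twice). Useful for validating attenuation of drift components.
#'
#' @param freq_hz Frequency at which to evaluate the gain.
#' @inheritParams highpass_filter
#' @param tr_seconds Sampling interval, seconds.
#' @return Amplitude gain in \[0, 1\].
#' @export
highpass_gain <- function(freq_hz, cutoff_hz = 0.01, tr_seconds = 3, order = 2L) {
  nyquist <- 1 / (2 * tr_seconds)
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "high")
  w <- 2 * pi * freq_hz * tr_seconds
  ew <- exp(-1i * w * (seq_along(bf$b) - 1))
  h <- sum(bf$b * ew) / sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  Mod(h)^2
}

#' Parcellation table
#'
#' Maps each node to an MNI-space coordinate and a functional network label
#' (for example `DMN`, `FPN`, `other`).
#'
#' @param node_id Unique node identifiers.
#' @param x,y,z MNI coordinates in mm.
#' @param network Non-empty network label per node.
#' @return A data frame of class `parcellation`.
#' @export
parcellation <- function(node_id, x, y, z, network) {
  node_id <- as.character(node_id)
  network <- as.character(network)
  if (anyDuplicated(node_id)) stop("node ids must be unique")
  if (any(!nzchar(network)) || anyNA(network)) stop("network labels must be non-empty")
  structure(data.frame(node_id = node_id, x = x, y = y, z = z,
                       network = network, stringsAsFactors = FALSE),
            class = c("parcellation", "data.frame"))
}

#' Read / write a parcellation TSV
#'
#' Columns: `node_id`, `x`, `y`, `z`, `network`.
#'
#' @param path File path.
#' @return [read_parcellation()]: a `parcellation`.
#' @export
read_parcellation <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  parcellation(d$node_id, d$x, d$y, d$z, d$network)
}

#' @rdname read_parcellation
#' @param parc A `parcellation`.
#' @export
write_parcellation <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Extract spherical-ROI mean time series from a 4-D volume
#'
#' For each parcellation node, averages the signal of all voxels whose
#' centers lie strictly within `radius_mm` of the node's MNI coordinate
#' (default 5 mm radius, i.e. a 10 mm diameter sphere). Voxels may belong to
#' several ROIs; an ROI that captures no voxel is an error naming the node.
#'
#' @param vol 4-D numeric array (x, y, z, t), assumed already in MNI space.
#' @param affine 4x4 matrix mapping 1-based voxel indices (homogeneous) to
#'   MNI mm. Defaults to 3 mm isotropic voxels with the volume centered on
#'   the origin.
#' @param parc A [parcellation()].
#' @param radius_mm Sphere radius in mm (default 5).
#' @param tr_seconds TR of the acquisition, seconds.
#' @return A [roi_timeseries()] with one column per parcellation node.
#' @export
extract_roi_timeseries <- function(vol, parc, affine = NULL, radius_mm = 5,
                                   tr_seconds = 3) {
  stopifnot(is.array(vol), length(dim(vol)) == 4L, inherits(parc, "parcellation"))
  dm <- dim(vol)
  if (is.null(affine)) {
    affine <- diag(c(3, 3, 3, 1))
    affine[1:3, 4] <- -3 * (dm[1:3] + 1) / 2   # center volume on the origin
  }
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  # voxel-center coordinates in mm for the full grid
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]), j = seq_len(dm[2]),
                               k = seq_len(dm[3])))
  mm <- t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  nt <- dm[4]
  flat <- matrix(vol, nrow = prod(dm[1:3]), ncol = nt)
  out <- matrix(NA_real_, nrow = nt, ncol = nrow(parc))
  for (n in seq_len(nrow(parc))) {
    ctr <- c(parc$x[n], parc$y[n], parc$z[n])
    d2 <- (mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2 + (mm[, 3] - ctr[3])^2
    sel <- which(d2 < radius_mm^2)
    if (length(sel) == 0)
      stop(sprintf("ROI '%s' captures no voxels within %g mm", parc$node_id[n], radius_mm))
    out[, n] <- if (length(sel) == 1L) flat[sel, ] else colMeans(flat[sel, , drop = FALSE])
  }
  roi_timeseries(out, tr_seconds = tr_seconds, node_ids = parc$node_id)
}

#' Read a 4-D NIfTI volume
#'
#' Thin wrapper over [RNifti::readNifti()] returning the intensity array and
#' the affine in the 1-based voxel-index convention used by
#' [extract_roi_timeseries()].
#'
#' @param path NIfTI-1 file path.
#' @return List with `data` (4-D array) and `affine` (4x4 matrix mapping
#'   1-based voxel indices, homogeneous, to world mm).
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI files requires the RNifti package")
  img <- RNifti::readNifti(path)
  a <- structure(RNifti::xform(img), class = NULL)  # 0-based voxel -> mm
  shift <- diag(4)
  shift[1:3, 4] <- -1
  list(data = as.array(img), affine = a %*% shift)
}

#' Read / write ROI time-series TSV
#'
#' Tabular text format: comment header lines `# key: value` carrying
#' `tr_seconds` (and optionally `subject`, `condition`), then a header row of
#' node ids and one row per volume.
#'
#' @param path File path.
#' @return [read_roi_timeseries()]: a [roi_timeseries()]; `subject` and
#'   `condition`, if present in the header, are attached as attributes.
#' @export
read_roi_timeseries <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[trimws(key)]] <- val
  }
  body <- lines[!grepl("^#", lines)]
  d <- utils::read.table(text = body, header = TRUE, sep = "\t",
                         check.names = FALSE)
  tr <- if (!is.null(meta$tr_seconds)) as.numeric(meta$tr_seconds) else 3
  ts <- roi_timeseries(as.matrix(d), tr_seconds = tr, node_ids = colnames(d))
  if (!is.null(meta$subject)) attr(ts, "subject") <- meta$subject
  if (!is.null(meta$condition)) attr(ts, "condition") <- meta$condition
  ts
}

#' @rdname read_roi_timeseries
#' @param ts A [roi_timeseries()].
#' @param subject,condition Optional metadata written to the header.
#' @export
write_roi_timeseries <- function(ts, path, subject = NULL, condition = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds: %g", attr(ts, "tr_seconds")), con)
  if (!is.null(subject)) writeLines(sprintf("# subject: %s", subject), con)
  if (!is.null(condition)) writeLines(sprintf("# condition: %s", condition), con)
  df <- as.data.frame(unclass(ts))
  colnames(df) <- colnames(ts)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
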