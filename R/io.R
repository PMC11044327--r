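# Data model and readers/writers for EIT frame sequences, lung masks,
# ventilator logs and SBT phase annotations.

#' Construct an EIT frame sequence
#'
#' An `eit_sequence` is a time-ordered stack of reconstructed 2-D pixel
#' impedance maps (arbitrary units, AU) sampled at a fixed rate, the raw
#' signal every downstream stage consumes. Frames are stored as an
#' `n_frames x (nrow * ncol)` matrix in row-major pixel order (pixel
#' `(r, c)` sits in column `(r - 1) * ncol + c`). Frame `i` is acquired at
#' `t0 + (i - 1) / fs` seconds.
#'
#' Non-finite pixel values are never propagated silently: they are replaced
#' by temporal interpolation of the affected pixel and recorded in the
#' `nonfinite` attribute (a tibble with columns `frame`, `pixel`).
#'
#' @param frames Numeric matrix, one row per frame, row-major pixel order.
#' @param fs Sampling frequency in Hz (> 0).
#' @param nrow,ncol Frame grid dimensions; `nrow * ncol` must equal
#'   `ncol(frames)`.
#' @param t0 Start time of the recording in seconds.
#' @param channels Optional named list of auxiliary scalar channels (for
#'   example transcutaneous CO2), each a tibble with columns `t`, `value`.
#' @return An object of class `eit_sequence`.
#' @export
eit_sequence <- function(frames, fs, nrow, ncol, t0 = 0, channels = list()) {
  frames <- as.matrix(frames)
  if (!is.numeric(frames) || base::nrow(frames) < 1) {
    abort("`frames` must be a numeric matrix with at least one row.")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  if (nrow * ncol != base::ncol(frames)) {
    abort(sprintf(
      "Frame grid %d x %d does not match %d pixels per frame.",
      nrow, ncol, base::ncol(frames)
    ))
  }
  rep <- repair_nonfinite(frames)
  structure(
    list(
      frames = rep$frames, fs = fs, t0 = t0,
      nrow = as.integer(nrow), ncol = as.integer(ncol),
      channels = channels
    ),
    nonfinite = rep$flagged,
    class = "eit_sequence"
  )
}

#' @export
print.eit_sequence <- function(x, ...) {
  cat(sprintf(
    "<eit_sequence> %d frames of %d x %d pixels @ %.4g Hz (%.1f s, t0 = %.3g s)\n",
    n_frames(x), x$nrow, x$ncol, x$fs, n_frames(x) / x$fs, x$t0
  ))
  if (length(x$channels)) {
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq An `eit_sequence`.
#' @export
n_frames <- function(seq) base::nrow(seq$frames)

#' Frame acquisition times
#' @param seq An `eit_sequence`.
#' @return Numeric vector of times in seconds, one per frame.
#' @export
frame_times <- function(seq) seq$t0 + (seq_len(n_frames(seq)) - 1) / seq$fs

#' Map timestamps to frame indices
#'
#' Nearest-frame mapping with ties broken toward the earlier frame, so
#' increasing timestamps always map to non-decreasing indices.
#'
#' @param seq An `eit_sequence`.
#' @param t Numeric vector of times in seconds.
#' @return Integer frame indices (1-based), clamped to the recording.
#' @export
time_to_frame <- function(seq, t) {
  i0 <- ceiling((t - seq$t0) * seq$fs - 0.5)
  as.integer(pmin(pmax(i0, 0), n_frames(seq) - 1L)) + 1L
}

#' Extract one frame as a matrix
#' @param seq An `eit_sequence`.
#' @param i Frame index.
#' @return A `nrow x ncol` matrix (row 1 = ventral edge by convention).
#' @export
frame_matrix <- function(seq, i) {
  matrix(seq$frames[i, ], seq$nrow, seq$ncol, byrow = TRUE)
}

# Replace non-finite pixels by temporal interpolation of that pixel.
repair_nonfinite <- function(frames) {
  bad <- which(!is.finite(frames), arr.ind = TRUE)
  if (base::nrow(bad) == 0) {
    return(list(frames = frames, flagged = tibble(frame = integer(), pixel = integer())))
  }
  for (p in unique(bad[, "col"])) {
    col <- frames[, p]
    ok <- is.finite(col)
    if (!any(ok)) {
      abort(sprintf("Pixel %d is non-finite in every frame.", p))
    }
    if (sum(ok) == 1) {
      col[!ok] <- col[ok]
    } else {
      col[!ok] <- approx(which(ok), col[ok], xout = which(!ok), rule = 2)$y
    }
    frames[, p] <- col
  }
  list(
    frames = frames,
    flagged = tibble(frame = as.integer(bad[, "row"]), pixel = as.integer(bad[, "col"]))
  )
}

#' Construct a lung mask
#'
#' Binary pixel map defining the lung contour; all image indices (GI, CoV,
#' silent spaces, regional fractions) are computed over mask pixels only.
#'
#' @param mask Logical or 0/1 matrix with the same grid as the frames.
#' @return An object of class `lung_mask` with fields `mask` (logical
#'   matrix) and `n_lung_pixels`.
#' @export
lung_mask <- function(mask) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) {
    abort("`mask` must contain only 0/1 values.")
  }
  mask <- mask == 1
  if (!any(mask)) {
    abort("Mask contains no lung pixels.")
  }
  structure(
    list(mask = mask, n_lung_pixels = sum(mask)),
    class = "lung_mask"
  )
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf(
    "<lung_mask> %d x %d grid, %d lung pixels\n",
    base::nrow(x$mask), base::ncol(x$mask), x$n_lung_pixels
  ))
  invisible(x)
}

# Row-major column indices of lung pixels within the frame matrix.
mask_pixel_index <- function(mask) {
  which(as.vector(t(mask$mask)))
}

check_mask_matches <- function(seq, mask) {
  if (base::nrow(mask$mask) != seq$nrow || base::ncol(mask$mask) != seq$ncol) {
    abort(sprintf(
      "Mask grid %d x %d does not match frame grid %d x %d.",
      base::nrow(mask$mask), base::ncol(mask$mask), seq$nrow, seq$ncol
    ))
  }
  invisible(TRUE)
}

#' Construct SBT phase annotations
#'
#' Timestamps (seconds, same clock as the recording) of the pre-SBT
#' baseline start, the SBT start and end, and the end of the post-SBT
#' observation window, plus the trial outcome.
#'
#' @param t_pre_start,t_sbt_start,t_sbt_end,t_post_end Strictly increasing
#'   times in seconds.
#' @param outcome One of `"success"`, `"failure"`, `"unknown"`.
#' @return An object of class `sbt_annotation`.
#' @export
sbt_annotation <- function(t_pre_start, t_sbt_start, t_sbt_end, t_post_end,
                           outcome = c("unknown", "success", "failure")) {
  outcome <- match.arg(outcome)
  ts <- c(t_pre_start, t_sbt_start, t_sbt_end, t_post_end)
  if (any(!is.finite(ts)) || any(diff(ts) <= 0)) {
    abort("Annotation timestamps must be finite and strictly increasing.")
  }
  structure(
    list(
      t_pre_start = t_pre_start, t_sbt_start = t_sbt_start,
      t_sbt_end = t_sbt_end, t_post_end = t_post_end, outcome = outcome
    ),
    class = "sbt_annotation"
  )
}

#' @export
print.sbt_annotation <- function(x, ...) {
  cat(sprintf(
    "<sbt_annotation> pre [%.1f, %.1f) s | SBT [%.1f, %.1f) s (%.1f min) | post to %.1f s | outcome: %s\n",
    x$t_pre_start, x$t_sbt_start, x$t_sbt_start, x$t_sbt_end,
    (x$t_sbt_end - x$t_sbt_start) / 60, x$t_post_end, x$outcome
  ))
  invisible(x)
}

#' Construct a ventilator log
#'
#' @param data Data frame with columns `t_s` (strictly increasing seconds)
#'   and `vt_ml` (tidal volume, ml, non-negative), optionally `rr_bpm` and
#'   `peep_cmh2o`.
#' @return A tibble with class `vent_log`.
#' @export
vent_log <- function(data) {
  data <- as_tibble(data)
  if (!all(c("t_s", "vt_ml") %in% names(data))) {
    abort("Ventilator log needs columns `t_s` and `vt_ml`.")
  }
  if (any(diff(data$t_s) <= 0)) {
    abort("Ventilator timestamps must be strictly increasing.")
  }
  if (any(data$vt_ml < 0, na.rm = TRUE)) {
    abort("Ventilator tidal volumes must be non-negative.")
  }
  class(data) <- c("vent_log", class(data))
  data
}

# ---- frame-csv dialect -----------------------------------------------------

parse_frame_csv_headers <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("#\\s*([A-Za-z0-9_]+)\\s*=\\s*([-+0-9.eE]+)", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- as.numeric(m[3])
  }
  kv
}

parse_frame_csv_data <- function(lines, path) {
  data_lines <- lines[!grepl("^\\s*#", lines)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0) abort(sprintf("No data rows in '%s'.", path))
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  len <- lengths(parts)
  if (length(unique(len)) > 1) {
    bad <- which(len != len[1])[1]
    abort(sprintf(
      "Ragged frame rows in '%s': data row %d has %d values, expected %d.",
      path, bad, len[bad], len[1]
    ))
  }
  matrix(as.numeric(unlist(parts)), length(parts), len[1], byrow = TRUE)
}

#' Read an EIT frame sequence
#'
#' Two dialects are supported. `"frame-csv"` is a plain-text format with
#' header lines `# fs=<float>`, `# rows=<int>`, `# cols=<int>`,
#' `# t0=<float>` followed by one comma-separated data row per frame in
#' row-major pixel order. `"container"` is the single-file session
#' container written by [write_eit_container()]; only the frame sequence is
#' returned (use [read_eit_container()] for the full session).
#'
#' @param path Path to the file.
#' @param dialect `"frame-csv"` or `"container"`.
#' @return An `eit_sequence`.
#' @export
read_eit_sequence <- function(path, dialect = c("frame-csv", "container")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  if (dialect == "container") {
    return(read_eit_container(path)$seq)
  }
  lines <- readLines(path)
  kv <- parse_frame_csv_headers(lines)
  if (is.null(kv$fs)) abort(sprintf("Missing `# fs=` header in '%s'.", path))
  if (!is.finite(kv$fs) || kv$fs <= 0) {
    abort(sprintf("Invalid sampling frequency fs=%g in '%s'.", kv$fs, path))
  }
  frames <- parse_frame_csv_data(lines, path)
  nr <- kv$rows %||% base::ncol(frames)
  nc <- kv$cols %||% 1
  eit_sequence(frames, fs = kv$fs, nrow = nr, ncol = nc, t0 = kv$t0 %||% 0)
}

#' Write an EIT frame sequence in the frame-csv dialect
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the frames bit-identically.
#'
#' @param seq An `eit_sequence`.
#' @param path Output path.
#' @export
write_eit_sequence <- function(seq, path) {
  hdr <- c(
    sprintf("# fs=%.17g", seq$fs),
    sprintf("# rows=%d", seq$nrow),
    sprintf("# cols=%d", seq$ncol),
    sprintf("# t0=%.17g", seq$t0)
  )
  rows <- apply(seq$frames, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a lung mask
#'
#' Frame-csv layout without the `fs` header: headers `# rows=`, `# cols=`
#' and either a single row-major data row or `rows` data rows of `cols`
#' values each, all values 0 or 1.
#'
#' @param path Path to the mask file.
#' @return A `lung_mask`.
#' @export
read_lung_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  lines <- readLines(path)
  kv <- parse_frame_csv_headers(lines)
  dat <- parse_frame_csv_data(lines, path)
  nr <- kv$rows
  nc <- kv$cols
  if (base::nrow(dat) == 1) {
    nr <- nr %||% 1
    nc <- nc %||% base::ncol(dat)
    if (nr * nc != base::ncol(dat)) {
      abort(sprintf(
        "Mask in '%s' has %d values, expected %d x %d.", path, base::ncol(dat), nr, nc
      ))
    }
    m <- matrix(dat[1, ], nr, nc, byrow = TRUE)
  } else {
    if (!is.null(nr) && base::nrow(dat) != nr) {
      abort(sprintf("Mask in '%s' has %d rows, header says %d.", path, base::nrow(dat), nr))
    }
    m <- dat
  }
  lung_mask(m)
}

#' Write a lung mask in the frame-csv layout
#' @param mask A `lung_mask`.
#' @param path Output path.
#' @export
write_lung_mask <- function(mask, path) {
  hdr <- c(
    sprintf("# rows=%d", base::nrow(mask$mask)),
    sprintf("# cols=%d", base::ncol(mask$mask))
  )
  row <- paste(as.integer(as.vector(t(mask$mask))), collapse = ",")
  writeLines(c(hdr, row), path)
  invisible(path)
}

#' Read a ventilator log CSV
#'
#' Expects named columns `t_s`, `vt_ml` and optionally `rr_bpm`,
#' `peep_cmh2o`.
#'
#' @param path Path to the CSV file.
#' @return A `vent_log` tibble.
#' @export
read_vent_log <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  vent_log(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write a ventilator log CSV
#' @param vent A `vent_log` tibble.
#' @param path Output path.
#' @export
write_vent_log <- function(vent, path) {
  readr::write_csv(as_tibble(unclass_tbl(vent)), path)
  invisible(path)
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("vent_log"))
  x
}

#' Read/write SBT annotations (YAML)
#'
#' @param path Path to a YAML file with keys `t_pre_start`, `t_sbt_start`,
#'   `t_sbt_end`, `t_post_end`, `outcome`.
#' @return An `sbt_annotation`.
#' @export
read_sbt_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  y <- yaml::read_yaml(path)
  sbt_annotation(
    y$t_pre_start, y$t_sbt_start, y$t_sbt_end, y$t_post_end,
    outcome = y$outcome %||% "unknown"
  )
}

#' @rdname read_sbt_annotation
#' @param ann An `sbt_annotation`.
#' @export
write_sbt_annotation <- function(ann, path) {
  yaml::write_yaml(unclass(ann), path)
  invisible(path)
}

# ---- container dialect -----------------------------------------------------

#' Read/write a single-file session container
#'
#' The container is one hierarchical binary file (an RDS-serialized named
#' list) holding the groups `frames`, `fs`, `t0`, `mask`, `vent` (with
#' `t`, `vt`), `annotation`, plus optional `channels` and `ground_truth`.
#'
#' @param path Path to the container file.
#' @param seq An `eit_sequence`.
#' @param mask Optional `lung_mask`.
#' @param vent Optional `vent_log`.
#' @param annotation Optional `sbt_annotation`.
#' @param ground_truth Optional ground-truth object from
#'   [generate_scenario()].
#' @return `read_eit_container()` returns a list with elements `seq`,
#'   `mask`, `vent`, `annotation`, `ground_truth` (missing parts are
#'   `NULL`).
#' @export
write_eit_container <- function(path, seq, mask = NULL, vent = NULL,
                                annotation = NULL, ground_truth = NULL) {
  obj <- list(
    frames = seq$frames, fs = seq$fs, t0 = seq$t0,
    rows = seq$nrow, cols = seq$ncol, channels = seq$channels,
    mask = if (!is.null(mask)) mask$mask,
    vent = if (!is.null(vent)) {
      c(list(t = vent$t_s, vt = vent$vt_ml),
        as.list(vent[setdiff(names(vent), c("t_s", "vt_ml"))]))
    },
    annotation = if (!is.null(annotation)) unclass(annotation),
    ground_truth = ground_truth
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_eit_container
#' @export
read_eit_container <- function(path) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  obj <- readRDS(path)
  seq <- eit_sequence(obj$frames,
    fs = obj$fs, nrow = obj$rows, ncol = obj$cols,
    t0 = obj$t0 %||% 0, channels = obj$channels %||% list()
  )
  vent <- NULL
  if (!is.null(obj$vent)) {
    extra <- obj$vent[setdiff(names(obj$vent), c("t", "vt"))]
    vent <- vent_log(as_tibble(c(list(t_s = obj$vent$t, vt_ml = obj$vent$vt), extra)))
  }
  ann <- NULL
  if (!is.null(obj$annotation)) {
    a <- obj$annotation
    ann <- sbt_annotation(a$t_pre_start, a$t_sbt_start, a$t_sbt_end, a$t_post_end,
      outcome = a$outcome %||% "unknown"
    )
  }
  list(
    seq = seq,
    mask = if (!is.null(obj$mask)) lung_mask(obj$mask),
    vent = vent,
    annotation = ann,
    ground_truth = obj$ground_truth
  )
}

# ---- alignment -------------------------------------------------------------

#' Align EIT frames, ventilator log and annotations on the frame clock
#'
#' Expresses every channel on the EIT frame clock: ventilator samples and
#' annotation timestamps are mapped to frame indices (nearest frame, ties
#' toward the earlier frame). Ventilator samples outside the recording are
#' dropped.
#'
#' @param seq An `eit_sequence`.
#' @param vent A `vent_log` (optional).
#' @param ann An `sbt_annotation`.
#' @return A list of class `eit_aligned` with elements `seq`, `vent` (with
#'   added `frame` column), `ann`, and `ann_frames` (named integer vector).
#' @export
align_channels <- function(seq, vent = NULL, ann = NULL) {
  t_start <- seq$t0
  # frame i covers [t_i, t_i + 1/fs): the span ends one period after the
  # last frame time
  t_end <- seq$t0 + n_frames(seq) / seq$fs
  ann_frames <- NULL
  if (!is.null(ann)) {
    if (ann$t_post_end <= t_start || ann$t_pre_start >= t_end) {
      abort("Annotation window does not overlap the EIT recording.")
    }
    ts <- c(
      t_pre_start = ann$t_pre_start, t_sbt_start = ann$t_sbt_start,
      t_sbt_end = ann$t_sbt_end, t_post_end = ann$t_post_end
    )
    tol <- 0.5 / seq$fs
    if (any(ts < t_start - tol) || any(ts > t_end + tol)) {
      abort("Annotation timestamp outside the EIT recording.")
    }
    ann_frames <- setNames(time_to_frame(seq, ts), names(ts))
  }
  if (!is.null(vent)) {
    keep <- vent$t_s >= t_start - 0.5 / seq$fs & vent$t_s <= t_end + 0.5 / seq$fs
    vent <- vent[keep, , drop = FALSE]
    vent$frame <- time_to_frame(seq, vent$t_s)
  }
  structure(
    list(seq = seq, vent = vent, ann = ann, ann_frames = ann_frames),
    class = "eit_aligned"
  )
}
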