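#' Read a skeleton recording
#'
#' Two on-disk dialects are supported.
#'
#' **CSV**: header `timestamp,<joint>_x,<joint>_y,<joint>_z,<joint>_state`
#' repeated for each of the 25 joints of [kinect_joints()]; one row per frame;
#' positions in metres, UTF-8, `.` decimal separator. Camera axes map as
#' x = mediolateral, y = superior-inferior, z = anterior-posterior (depth).
#' Metadata travels in
#' `#`-prefixed key:value comment lines before the header
#' (`rate_hz`, `height_cm`, `mass_kg`, `subject`, `condition`, `repeat`).
#'
#' **JSON**: a top-level object
#' `{meta: {rate_hz, height_cm, mass_kg, subject, condition, repeat},
#'   frames: [{t, joints: {name: [ml, si, ap, state]}}]}`.
#'
#' @param path File path (or connection for `dialect = "csv"`).
#' @param dialect `"csv"` or `"json"`.
#' @return A [skeleton_sequence()].
#' @seealso [write_skeleton()]
#' @export
read_skeleton <- function(path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") read_skeleton_csv(path) else read_skeleton_json(path)
}

#' Write a skeleton recording
#'
#' Deterministic and lossless at 6 decimal places (metres); a written file
#' re-read with [read_skeleton()] reproduces the sequence at that precision.
#'
#' @param seq A valid [skeleton_sequence()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(seq, path, dialect = c("csv", "json")) {
  dialect <- match.arg(dialect)
  if (!inherits(seq, "skeleton_sequence"))
    stop("seq must be a skeleton_sequence")
  if (dialect == "csv") write_skeleton_csv(seq, path)
  else write_skeleton_json(seq, path)
  invisible(path)
}

skeleton_csv_header <- function() {
  cols <- lapply(kinect_joints(), function(j)
    paste0(j, "_", c("x", "y", "z", "state")))
  c("timestamp", unlist(cols))
}

fmt6 <- function(x) {
  out <- sprintf("%.6f", x)
  out[is.na(x)] <- "NA"
  out
}

meta_header_lines <- function(seq) {
  m <- seq$meta
  vals <- c(rate_hz = format(seq$rate_hz), height_cm = format(m$height_cm),
            mass_kg = format(m$mass_kg), subject = as.character(m$subject),
            condition = as.character(m$condition),
            repeat_ = format(m$repeat_idx))
  names(vals)[names(vals) == "repeat_"] <- "repeat"
  sprintf("# %s: %s", names(vals), vals)
}

parse_meta_lines <- function(lines) {
  m <- list(rate_hz = 30, height_cm = NA_real_, mass_kg = NA_real_,
            subject = NA_character_, condition = NA_character_,
            repeat_idx = NA_integer_)
  keys <- sub("^# *([^:]+):.*$", "\\1", lines)
  vals <- trimws(sub("^# *[^:]+:", "", lines))
  for (i in seq_along(keys)) {
    v <- vals[i]
    switch(keys[i],
           rate_hz = { m$rate_hz <- as.numeric(v) },
           height_cm = { m$height_cm <- suppressWarnings(as.numeric(v)) },
           mass_kg = { m$mass_kg <- suppressWarnings(as.numeric(v)) },
           subject = { m$subject <- v },
           condition = { m$condition <- v },
           "repeat" = { m$repeat_idx <- suppressWarnings(as.integer(v)) })
  }
  m
}

write_skeleton_csv <- function(seq, path) {
  joints <- kinect_joints()
  n <- n_frames(seq)
  blocks <- vector("list", length(joints))
  for (k in seq_along(joints)) {
    p <- seq$pos[, k, , drop = TRUE]
    if (n == 1L) p <- matrix(p, nrow = 1L)
    blocks[[k]] <- cbind(fmt6(p[, 1]), fmt6(p[, 2]), fmt6(p[, 3]),
                         seq$state[, k])
  }
  body <- do.call(cbind, c(list(fmt6(seq$t)), blocks))
  lines <- c(meta_header_lines(seq),
             paste(skeleton_csv_header(), collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  writeLines(lines, path)
}

read_skeleton_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_ln <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[meta_ln])
  lines <- lines[!meta_ln]
  if (length(lines) < 1L) stop("empty skeleton CSV: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  expected <- skeleton_csv_header()
  if (length(header) != length(expected) || any(header != expected)) {
    bad <- header[!(header %in% expected)]
    if (length(bad))
      stop("unknown column(s) in skeleton CSV header: ",
           paste(utils::head(bad, 3L), collapse = ", "))
    stop("skeleton CSV header does not match the 25-joint dialect")
  }
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nfield <- length(expected)
  badrow <- which(vapply(rows, length, 1L) != nfield)
  if (length(badrow))
    stop(sprintf("malformed skeleton CSV row at line %d of %s",
                 badrow[1] + 1L + sum(meta_ln), path))
  mat <- do.call(rbind, rows)
  n <- nrow(mat)
  t <- as.numeric(mat[, 1])
  pos <- array(NA_real_, dim = c(n, 25L, 3L))
  state <- matrix("tracked", n, 25L)
  for (k in 1:25) {
    off <- 1L + (k - 1L) * 4L
    pos[, k, 1] <- suppressWarnings(as.numeric(mat[, off + 1L]))
    pos[, k, 2] <- suppressWarnings(as.numeric(mat[, off + 2L]))
    pos[, k, 3] <- suppressWarnings(as.numeric(mat[, off + 3L]))
    state[, k] <- mat[, off + 4L]
  }
  skeleton_sequence(t, pos, state, rate_hz = meta$rate_hz,
                    height_cm = meta$height_cm, mass_kg = meta$mass_kg,
                    subject = meta$subject, condition = meta$condition,
                    repeat_idx = meta$repeat_idx)
}

write_skeleton_json <- function(seq, path) {
  joints <- kinect_joints()
  frames <- lapply(seq_len(n_frames(seq)), function(i) {
    jl <- lapply(seq_along(joints), function(k) {
      p <- round(seq$pos[i, k, ], 6)
      c(as.list(p), seq$state[i, k])
    })
    names(jl) <- joints
    list(t = round(seq$t[i], 6), joints = jl)
  })
  m <- seq$meta
  obj <- list(meta = list(rate_hz = seq$rate_hz, height_cm = m$height_cm,
                          mass_kg = m$mass_kg, subject = m$subject,
                          condition = m$condition, "repeat" = m$repeat_idx),
              frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
}

read_skeleton_json <- function(path) {
  obj <- jsonlite::read_json(path)
  meta <- obj$meta
  frames <- obj$frames
  if (is.null(frames) || !length(frames)) stop("no frames in skeleton JSON")
  n <- length(frames)
  joints <- kinect_joints()
  t <- vapply(frames, function(f) as.numeric(f$t), 1.0)
  pos <- array(NA_real_, dim = c(n, 25L, 3L))
  state <- matrix("tracked", n, 25L)
  for (i in seq_len(n)) {
    jl <- frames[[i]]$joints
    unknown <- setdiff(names(jl), joints)
    if (length(unknown))
      stop("unknown joint name in skeleton JSON: ", unknown[1])
    for (k in seq_along(joints)) {
      rec <- jl[[joints[k]]]
      if (is.null(rec))
        stop("frame ", i, " is missing joint ", joints[k])
      pos[i, k, ] <- vapply(rec[1:3], function(v)
        if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v)), 1.0)
      state[i, k] <- as.character(rec[[length(rec)]])
    }
  }
  nm <- function(x, d) if (is.null(x)) d else x
  skeleton_sequence(t, pos, state,
                    rate_hz = nm(meta$rate_hz, 30),
                    height_cm = nm(meta$height_cm, NA_real_),
                    mass_kg = nm(meta$mass_kg, NA_real_),
                    subject = nm(meta$subject, NA_character_),
                    condition = nm(meta$condition, NA_character_),
                    repeat_idx = as.integer(nm(meta$`repeat`, NA_integer_)))
}

#' Read / write a centre-of-force trace
#'
#' CSV dialect: header `t,ml_mm,ap_mm`, one row per 10-ms sample; the
#' subject's height travels in a `# height_cm: <value>` comment line (written
#' by [write_cof()]) or is supplied via `height_cm`, which takes precedence.
#'
#' @param path File path.
#' @param height_cm Subject height in cm; required if the file carries none.
#' @param rate_hz Sampling rate in Hz (default 100).
#' @return A [cof_trace()].
#' @export
read_cof <- function(path, height_cm = NULL, rate_hz = 100) {
  lines <- readLines(path, warn = FALSE)
  meta_ln <- grepl("^#", lines)
  file_h <- NA_real_
  hm <- grep("^# *height_cm:", lines, value = TRUE)
  if (length(hm)) file_h <- as.numeric(trimws(sub("^# *height_cm:", "", hm[1])))
  rm_ <- grep("^# *rate_hz:", lines, value = TRUE)
  if (length(rm_)) rate_hz <- as.numeric(trimws(sub("^# *rate_hz:", "", rm_[1])))
  df <- utils::read.csv(text = lines[!meta_ln])
  if (!all(c("t", "ml_mm", "ap_mm") %in% names(df)))
    stop("CoF CSV must have header t,ml_mm,ap_mm")
  h <- if (!is.null(height_cm)) height_cm else file_h
  cof_trace(df$ml_mm, df$ap_mm, rate_hz = rate_hz, height_cm = h, t = df$t)
}

#' @rdname read_cof
#' @param trace A [cof_trace()].
#' @export
write_cof <- function(trace, path) {
  if (!inherits(trace, "cof_trace")) stop("trace must be a cof_trace")
  lines <- c(sprintf("# height_cm: %s", format(attr(trace, "height_cm"))),
             sprintf("# rate_hz: %s", format(attr(trace, "rate_hz"))),
             "t,ml_mm,ap_mm",
             sprintf("%.6f,%.6f,%.6f", trace$t, trace$ml_mm, trace$ap_mm))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a CoM path
#'
#' On-disk form of the pipeline output: CSV with header `t,ml_mm,ap_mm` plus
#' `#`-comment metadata lines (`method`, `rate_hz`, `subject`, `condition`,
#' `repeat`).
#'
#' @param path File path.
#' @return A [com_path_new()] object.
#' @export
read_com_path <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_ln <- grepl("^#", lines)
  get1 <- function(key, default = NA_character_) {
    m <- grep(sprintf("^# *%s:", key), lines, value = TRUE)
    if (length(m)) trimws(sub(sprintf("^# *%s:", key), "", m[1])) else default
  }
  df <- utils::read.csv(text = lines[!meta_ln])
  method <- get1("method", "three_joint")
  rate <- as.numeric(get1("rate_hz", "30"))
  meta <- list(subject = get1("subject"), condition = get1("condition"),
               repeat_idx = suppressWarnings(as.integer(get1("repeat"))))
  com_path_new(df$t, df$ml_mm, df$ap_mm, rate_hz = rate, method = method,
               meta = meta)
}

#' @rdname read_com_path
#' @param path_obj A `com_path`.
#' @export
write_com_path <- function(path_obj, path) {
  if (!inherits(path_obj, "com_path")) stop("path_obj must be a com_path")
  meta <- attr(path_obj, "meta")
  g <- function(x) if (is.null(x)) NA else x
  lines <- c(sprintf("# method: %s", attr(path_obj, "method")),
             sprintf("# rate_hz: %s", format(attr(path_obj, "rate_hz"))),
             sprintf("# subject: %s", g(meta$subject)),
             sprintf("# condition: %s", g(meta$condition)),
             sprintf("# repeat: %s", format(g(meta$repeat_idx))),
             "t,ml_mm,ap_mm",
             sprintf("%.6f,%.6f,%.6f", path_obj$t, path_obj$ml_mm,
                     path_obj$ap_mm))
  writeLines(lines, path)
  invisible(path)
}
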