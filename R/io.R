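#' Read COCO-keypoints JSON
#'
#' Parses the standard COCO keypoints dialect (images / annotations /
#' categories arrays, keypoints as flat `[x1, y1, v1, x2, y2, v2, ...]`
#' triplets) into [kp_frame()] records. A triplet with visibility 0
#' marks an absent keypoint; its coordinates are carried but ignored by
#' all downstream geometry.
#'
#' @param path Path to a COCO-format JSON file.
#' @param schema A [calf_face_schema()]; annotation keypoint counts must
#'   match its length.
#' @return A list with one element per annotation, each a list with
#'   `image_id` and `frame` (a `kp_frame`).
#' @export
read_coco_keypoints <- function(path, schema = calf_face_schema()) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("failed to parse COCO JSON '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  if (is.null(doc$annotations) || is.null(doc$images)) {
    stop("COCO file '", path, "' lacks images/annotations arrays", call. = FALSE)
  }
  img_size <- list()
  for (im in doc$images) {
    img_size[[as.character(im$id)]] <- c(im$width, im$height)
  }
  n_kp <- length(schema$names)
  out <- vector("list", length(doc$annotations))
  for (i in seq_along(doc$annotations)) {
    ann <- doc$annotations[[i]]
    kp <- unlist(ann$keypoints)
    if (length(kp) != 3L * n_kp) {
      stop(
        "annotation ", i, " in '", path, "': expected ", n_kp,
        " keypoints (", 3L * n_kp, " values), found ", length(kp) / 3,
        call. = FALSE
      )
    }
    m <- matrix(kp, ncol = 3L, byrow = TRUE)
    pts <- m[, 1:2, drop = FALSE]
    rownames(pts) <- schema$names
    vis <- as.integer(m[, 3])
    names(vis) <- schema$names
    sz <- img_size[[as.character(ann$image_id)]]
    if (is.null(sz)) sz <- c(NA_real_, NA_real_)
    fidx <- if (!is.null(ann$frame_index)) ann$frame_index else i - 1L
    out[[i]] <- list(
      image_id = ann$image_id,
      frame = kp_frame(
        frame_index = fidx, points = pts, visibility = vis,
        image_size = sz,
        bbox = if (!is.null(ann$bbox)) unlist(ann$bbox) else NULL,
        schema = schema
      )
    )
  }
  out
}

#' Write frames as COCO-keypoints JSON
#'
#' Inverse of [read_coco_keypoints()]; coordinates are written at full
#' double precision so read/write round trips are lossless well beyond
#' 6 decimal places.
#'
#' @param frames List of [kp_frame()] objects.
#' @param path Output file path.
#' @param animal_id Category/supercategory name recorded in the file.
#' @param digits Decimal digits written for numeric values; `NA` (the
#'   default) keeps full double precision. Three digits keep coordinates
#'   to a thousandth of a pixel while shrinking the file.
#' @export
write_coco_keypoints <- function(frames, path, animal_id = "calf", digits = NA) {
  if (inherits(frames, "kp_frame")) frames <- list(frames)
  schema <- frames[[1]]$schema
  images <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    list(
      id = i, width = f$image_size[1], height = f$image_size[2],
      file_name = sprintf("frame_%06d.png", f$frame_index)
    )
  })
  annotations <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    kp <- as.vector(t(cbind(f$points, f$visibility)))
    ann <- list(
      id = i, image_id = i, category_id = 1L,
      keypoints = kp, num_keypoints = sum(f$visibility > 0L),
      frame_index = f$frame_index
    )
    if (!is.null(f$bbox)) ann$bbox <- f$bbox
    ann
  })
  doc <- list(
    images = images,
    annotations = annotations,
    categories = list(list(
      id = 1L, name = animal_id, supercategory = "animal",
      keypoints = schema$names,
      skeleton = schema$skeleton
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = digits, null = "null")
  invisible(path)
}

#' Read one frame from YOLO pose text
#'
#' The YOLO pose dialect stores one detection per line:
#' `class cx cy w h  x1 y1 [c1]  x2 y2 [c2] ...`, all normalized to
#' `[0, 1]`. Coordinates are denormalized to pixels by the image size so
#' downstream geometry never sees normalized units. Per-keypoint
#' confidence at or above `conf_threshold` maps to visible (2), below it
#' to absent (0); the 2-value-per-keypoint variant (no confidence) maps
#' every keypoint to visible.
#'
#' @param path Path to a YOLO pose text file.
#' @param image_size `(width, height)` in pixels.
#' @param schema A [calf_face_schema()].
#' @param conf_threshold Visibility threshold on keypoint confidence,
#'   default 0.5.
#' @param frame_index Frame index to assign, default 0.
#' @return A [kp_frame()].
#' @export
read_yolo_pose <- function(path, image_size, schema = calf_face_schema(),
                           conf_threshold = 0.5, frame_index = 0L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no detection lines in '", path, "'", call. = FALSE)
  n_kp <- length(schema$names)
  parse_line <- function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  toks <- lapply(lines, parse_line)
  if (length(toks) > 1L) {
    # one calf per file is the expected case; keep the most confident line
    conf <- vapply(toks, function(v) {
      if (length(v) == 5L + 3L * n_kp) mean(v[5L + seq_len(n_kp) * 3L]) else 1
    }, numeric(1))
    warning(
      length(toks), " detections in '", path,
      "'; keeping the highest-confidence line",
      call. = FALSE
    )
    toks <- toks[which.max(conf)]
  }
  v <- toks[[1]]
  with_conf <- length(v) == 5L + 3L * n_kp
  if (!with_conf && length(v) != 5L + 2L * n_kp) {
    stop(
      "YOLO pose line in '", path, "': expected ", 5L + 3L * n_kp, " (or ",
      5L + 2L * n_kp, ") tokens for ", n_kp, " keypoints, found ", length(v),
      call. = FALSE
    )
  }
  w <- image_size[1]
  h <- image_size[2]
  body <- v[-(1:5)]
  step <- if (with_conf) 3L else 2L
  idx <- (seq_len(n_kp) - 1L) * step
  pts <- cbind(x = body[idx + 1L] * w, y = body[idx + 2L] * h)
  rownames(pts) <- schema$names
  vis <- if (with_conf) {
    ifelse(body[idx + 3L] >= conf_threshold, 2L, 0L)
  } else {
    rep(2L, n_kp)
  }
  names(vis) <- schema$names
  bbox <- c(
    (v[2] - v[4] / 2) * w, (v[3] - v[5] / 2) * h,
    v[4] * w, v[5] * h
  )
  kp_frame(
    frame_index = frame_index, points = pts, visibility = vis,
    image_size = image_size, bbox = bbox, schema = schema
  )
}

#' Write one frame as YOLO pose text
#'
#' Normalizes pixel coordinates by the image size and writes the
#' `class cx cy w h x y conf ...` layout with 6 decimal places, the
#' precision conventional for the format (round trips are exact to well
#' under half a pixel on a 640 px image).
#'
#' @param frame A [kp_frame()].
#' @param path Output file path.
#' @param class_id Integer object class, default 0.
#' @export
write_yolo_pose <- function(frame, path, class_id = 0L) {
  w <- frame$image_size[1]
  h <- frame$image_size[2]
  bbox <- frame$bbox
  if (is.null(bbox)) {
    vis <- frame$visibility > 0L
    xs <- frame$points[vis, 1]
    ys <- frame$points[vis, 2]
    bbox <- c(min(xs), min(ys), max(xs) - min(xs), max(ys) - min(ys))
  }
  cx <- (bbox[1] + bbox[3] / 2) / w
  cy <- (bbox[2] + bbox[4] / 2) / h
  kp <- as.vector(t(cbind(
    frame$points[, 1] / w, frame$points[, 2] / h,
    ifelse(frame$visibility > 0L, 1, 0)
  )))
  line <- paste(
    c(class_id, sprintf("%.6f", c(cx, cy, bbox[3] / w, bbox[4] / h, kp))),
    collapse = " "
  )
  writeLines(line, path)
  invisible(path)
}

#' Write a phenotype table to CSV
#'
#' One row per animal/session; units are encoded in the column names
#' (`_cm`, `_s`, `_count`). UTF-8, '.' decimal separator.
#'
#' @param records A data.frame of phenotype records (possibly empty).
#' @param path Output CSV path.
#' @export
write_phenotype_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phenotype table written by [write_phenotype_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_phenotype_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
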