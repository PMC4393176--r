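# On-disk formats: JSON contour cines, CSV displacement tables, and the
# study report bundle. All plain text; coordinates in mm; angles CCW
# from +x. Displacement CSVs use 1-based segment_id and 0-based
# frame_index, matching instrument-export convention.

#' Write a contour cine stack to JSON
#'
#' Canonical on-disk form of a short-axis contour cine:
#' `{slice_spacing_mm, frame_times, slices: [[{endo: [[x,y],...],
#' epi: [[x,y],...]?}, ...], ...]}` with slices ordered apex to base.
#'
#' @param stack a `cine_stack`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_cine_stack()]
#' @export
write_cine_stack <- function(stack, path) {
  stop_if(!inherits(stack, "cine_stack"), "stack must be a cine_stack")
  doc <- list(
    slice_spacing_mm = stack$slice_spacing,
    frame_times = stack$frame_times,
    slices = lapply(stack$slices, function(sl) {
      lapply(sl, function(f) {
        out <- list(endo = unname(f$endo))
        if (!is.null(f$epi)) out$epi <- unname(f$epi)
        out
      })
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and validate a contour cine stack
#'
#' Reads the JSON format written by [write_cine_stack()] and enforces
#' the structural contract: every contour has at least 8 vertices and
#' is a simple (non-self-intersecting) polygon; all slices share one
#' frame count; frame times are strictly increasing in \[0, 1).
#' Vertex order is normalized to counterclockwise (the area is
#' unaffected). Violations raise an error naming the slice and frame.
#'
#' @param path path to a cine-stack JSON file.
#' @return a validated `cine_stack`.
#' @export
read_cine_stack <- function(path) {
  stop_if(!file.exists(path), "no such file: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stop_if(is.null(doc$slice_spacing_mm) || is.null(doc$frame_times) ||
            is.null(doc$slices), "not a cine-stack document: %s", path)
  ft <- as.numeric(doc$frame_times)
  stop_if(any(diff(ft) <= 0) || ft[1] < 0 || ft[length(ft)] >= 1,
          "frame_times must be strictly increasing within [0, 1)")
  counts <- vapply(doc$slices, length, integer(1))
  if (length(unique(counts)) > 1) {
    stop(sprintf(
      "inconsistent frame counts across slices (%s): slices %s differ from the majority",
      paste(counts, collapse = ", "),
      paste(which(counts != as.integer(names(sort(table(counts),
                                                  decreasing = TRUE))[1])),
            collapse = ", ")), call. = FALSE)
  }
  stop_if(counts[1] != length(ft),
          "frame count (%d) does not match frame_times length (%d)",
          counts[1], length(ft))
  slices <- lapply(seq_along(doc$slices), function(j) {
    lapply(seq_len(counts[j]), function(k) {
      f <- doc$slices[[j]][[k]]
      endo <- validate_contour(f$endo, j, k, "endocardial")
      epi <- if (!is.null(f$epi)) validate_contour(f$epi, j, k, "epicardial")
      list(endo = endo, epi = epi)
    })
  })
  structure(list(slices = slices,
                 slice_spacing = as.numeric(doc$slice_spacing_mm),
                 frame_times = ft),
            class = "cine_stack")
}

validate_contour <- function(v, slice, frame, which) {
  if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
  v <- tryCatch(as_polygon(v), error = function(e) {
    stop(sprintf("slice %d frame %d (%s): %s",
                 slice, frame, which, conditionMessage(e)), call. = FALSE)
  })
  stop_if(nrow(v) < 8,
          "slice %d frame %d (%s): contour has %d vertices, need >= 8",
          slice, frame, which, nrow(v))
  stop_if(!polygon_is_simple(v),
          "slice %d frame %d (%s): contour is self-intersecting",
          slice, frame, which)
  ensure_ccw(v)
}

#' Write a displacement field as a CSV displacement table
#'
#' Long-format export with columns `segment_id` (1-based),
#' `frame_index` (0-based), `frame_time` and `displacement_mm`
#' (inward positive), one row per (segment, frame).
#'
#' @param field a [displacement_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_displacement_table <- function(field, path) {
  stop_if(!inherits(field, "displacement_field"),
          "field must be a displacement_field")
  n_f <- ncol(field$d)
  tab <- data.frame(
    segment_id = rep(seq_len(field$n_segments), times = n_f),
    frame_index = rep(seq_len(n_f) - 1L, each = field$n_segments),
    frame_time = rep(field$frame_times, each = field$n_segments),
    displacement_mm = as.vector(field$d))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV displacement table into a displacement field
#'
#' Expects columns `segment_id` (1..M), `frame_index` (0..N) and
#' `displacement_mm` (or `displacement_um`, converted to mm), with an
#' optional `frame_time` column. The (segment, frame) grid must be
#' complete with no duplicates; holes are an error naming the missing
#' cell. The reference frame is taken as the frame whose column is
#' identically zero (frame 0 in the standard export).
#'
#' @param path path to the CSV file.
#' @return a [displacement_field()] of shape M x (N+1).
#' @export
read_displacement_table <- function(path) {
  stop_if(!file.exists(path), "no such file: %s", path)
  tab <- utils::read.csv(path)
  stop_if(!all(c("segment_id", "frame_index") %in% names(tab)),
          "displacement table needs segment_id and frame_index columns")
  if ("displacement_mm" %in% names(tab)) {
    disp <- tab$displacement_mm
  } else if ("displacement_um" %in% names(tab)) {
    disp <- tab$displacement_um / 1000
  } else {
    stop("displacement table needs a displacement_mm or displacement_um column",
         call. = FALSE)
  }
  stop_if(!is.numeric(disp) || anyNA(disp),
          "non-numeric or missing displacement values")
  stop_if(!is.numeric(tab$segment_id) || !is.numeric(tab$frame_index),
          "segment_id and frame_index must be numeric")
  segs <- sort(unique(tab$segment_id))
  frames <- sort(unique(tab$frame_index))
  M <- length(segs); N <- length(frames)
  stop_if(!identical(as.integer(segs), seq_len(M)),
          "segment_id must cover 1..M without gaps")
  stop_if(!identical(as.integer(frames), seq_len(N) - 1L),
          "frame_index must cover 0..N without gaps")
  key <- paste(tab$segment_id, tab$frame_index)
  dup <- duplicated(key)
  stop_if(any(dup), "duplicate rows for (segment %s, frame %s)",
          tab$segment_id[dup][1], tab$frame_index[dup][1])
  if (nrow(tab) != M * N) {
    full <- outer(segs, frames, paste)
    miss <- which(matrix(!(full %in% key), M, N), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete grid: missing (segment %d, frame %d)",
                 segs[miss[1]], frames[miss[2]]), call. = FALSE)
  }
  d <- matrix(NA_real_, M, N)
  d[cbind(tab$segment_id, tab$frame_index + 1L)] <- disp
  ft <- if ("frame_time" %in% names(tab)) {
    ft_tab <- unique(tab[order(tab$frame_index), c("frame_index", "frame_time")])
    as.numeric(ft_tab$frame_time)
  } else {
    (frames) / N
  }
  ref <- which(colSums(abs(d)) == 0)
  ref <- if (length(ref)) ref[1] else 1L
  stop_if(any(d[, ref] != 0),
          "no all-zero reference frame found in the table")
  displacement_field(d, frame_times = ft, reference_frame = ref)
}

#' Write a study report bundle
#'
#' Serializes a [run_study()] result: the long per-animal metric table
#' as CSV, group summaries (mean +/- SEM per timepoint) as CSV, the
#' statistics tables and the run manifest as JSON. Field ordering is
#' deterministic, so identical studies produce byte-identical reports.
#'
#' @param study a `study_report` from [run_study()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(study, dir) {
  stop_if(!inherits(study, "study_report"), "study must be a study_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stop_if(!dir.exists(dir), "cannot create output directory %s", dir)
  write_num_csv <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    utils::write.csv(df, file.path(dir, file), row.names = FALSE,
                     quote = FALSE)
  }
  write_num_csv(study$metrics, "per_animal_metrics.csv")
  write_num_csv(study$summaries, "group_summaries.csv")
  jsonlite::write_json(study$stats, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(dir)
}
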