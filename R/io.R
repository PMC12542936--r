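# Plain-text interchange formats: delimited current traces with a
# `# sample_rate` header, JSON dishes, and whitespace-delimited frame
# stacks (one matrix per frame).

#' Read and write amperometric traces
#'
#' Traces are 2-3 column delimited text (`time_s`, `current_pA`, optional
#' `position_um`) preceded by a `# sample_rate: <Hz>` comment header.
#'
#' @param trace an [nt_trace()].
#' @param path file path.
#' @return `read_trace()` returns an `nt_trace`; `write_trace()` its path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "nt_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate: %g", trace$sample_rate), con)
  if (nrow(trace$annotations) > 0)
    writeLines(sprintf("# annotation: %.12g %s", trace$annotations$time,
                       trace$annotations$label), con)
  df <- data.frame(time_s = trace_time(trace), current_pA = trace$current)
  if (!is.null(trace$position)) df$position_um <- trace$position
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  sr <- sub(".*sample_rate:\\s*", "", grep("sample_rate", hdr, value = TRUE))
  sr <- if (length(sr)) as.numeric(sr[1]) else 1000
  ann_lines <- grep("annotation:", hdr, value = TRUE)
  ann <- if (length(ann_lines)) {
    parts <- strsplit(sub(".*annotation:\\s*", "", ann_lines), "\\s+")
    data.frame(time = as.numeric(vapply(parts, `[`, "", 1)),
               label = vapply(parts, `[`, "", 2))
  } else NULL
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  nt_trace(df$current_pA, sr,
           position = if ("position_um" %in% names(df)) df$position_um,
           annotations = ann)
}

#' Read and write virtual dishes as JSON
#'
#' @param dish an [nt_dish()].
#' @param path file path.
#' @return `read_dish()` returns an `nt_dish`; `write_dish()` its path,
#'   invisibly.
#' @export
write_dish <- function(dish, path) {
  stopifnot(inherits(dish, "nt_dish"))
  jsonlite::write_json(unclass(dish), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_dish
#' @export
read_dish <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$fov <- as.numeric(x$fov)
  x$cells <- lapply(seq_len(nrow_or_len(x$cells)), function(i) {
    cl <- if (is.data.frame(x$cells)) lapply(x$cells, `[[`, i)
          else x$cells[[i]]
    for (f in c("contour", "nucleus_contour"))
      cl[[f]] <- matrix(unlist(cl[[f]]), ncol = 2,
                        byrow = !is.matrix(cl[[f]]),
                        dimnames = list(NULL, c("x", "y")))
    for (f in c("center", "nucleus_center")) cl[[f]] <- as.numeric(cl[[f]])
    cl
  })
  class(x) <- "nt_dish"
  x
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' Read and write image stacks as plain text
#'
#' One whitespace-delimited intensity matrix per frame, frames separated
#' by `# frame <k>` lines, with `# frame_rate` / `# pixel_size` headers.
#' (Text stands in for multi-page TIFF: the container contract is the
#' in-memory [nt_stack()].)
#'
#' @param stack an [nt_stack()].
#' @param path file path.
#' @return `read_stack()` returns an `nt_stack`; `write_stack()` its path,
#'   invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "nt_stack"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate: %g", stack$frame_rate),
               sprintf("# pixel_size: %g", stack$pixel_size)), con)
  for (f in seq_len(n_frames(stack))) {
    writeLines(sprintf("# frame %d", f), con)
    utils::write.table(stack$frames[, , f], con, sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  lines <- readLines(path)
  fr <- as.numeric(sub(".*frame_rate:\\s*", "",
                       grep("frame_rate", lines, value = TRUE)[1]))
  ps <- as.numeric(sub(".*pixel_size:\\s*", "",
                       grep("pixel_size", lines, value = TRUE)[1]))
  marks <- grep("^# frame [0-9]+$", lines)
  frames <- lapply(seq_along(marks), function(i) {
    from <- marks[i] + 1
    to <- if (i < length(marks)) marks[i + 1] - 1 else length(lines)
    as.matrix(utils::read.table(text = lines[from:to]))
  })
  frames <- lapply(frames, function(m) {
    dimnames(m) <- NULL
    m
  })
  nt_stack(frames, frame_rate = fr, pixel_size = ps)
}
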