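# Canonical on-disk dialect: UTF-8 tab-separated text, '#' comment headers,
# 0-based node indices stated in every header.

#' Write / read a label map as tab-separated text
#'
#' Two columns: `node` (0-based index) and `label`.
#'
#' @param labels Character label map.
#' @param path File path.
#' @return `read_label_map` returns the character label map;
#'   `write_label_map` returns `path` invisibly.
#' @export
write_label_map <- function(labels, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# netmapr label_map", "# node indices are 0-based",
               "node\tlabel"), con)
  writeLines(paste(seq_along(labels) - 1L, labels, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0 || lines[body[1]] != "node\tlabel")
    stop("malformed label_map header at line ",
         if (length(body)) body[1] else 1, " of ", path)
  rows <- strsplit(lines[body[-1]], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != 2)
  if (length(bad) > 0)
    stop("malformed label_map row at line ", body[-1][bad[1]], " of ", path)
  node <- as.integer(vapply(rows, `[[`, "", 1L))
  labels <- vapply(rows, `[[`, "", 2L)
  labels[order(node)]
}

#' Write / read a symmetric matrix as tab-separated text
#'
#' A `# nodes:` comment records the node ids; the body is the full numeric
#' matrix.
#'
#' @param m An `fc_matrix` or numeric matrix.
#' @param path File path.
#' @return `read_fc_matrix` returns an `fc_matrix`; `write_fc_matrix`
#'   returns `path` invisibly.
#' @export
write_fc_matrix <- function(m, path) {
  ids <- attr(m, "node_ids")
  if (is.null(ids)) ids <- seq_len(nrow(m)) - 1L
  level <- attr(m, "level")
  if (is.null(level)) level <- "vertex"
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# netmapr fc_matrix",
               paste0("# level: ", level),
               paste0("# nodes: ", paste(ids, collapse = "\t"))), con)
  utils::write.table(format(unclass(m), digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# netmapr fc_matrix")
    stop("malformed fc_matrix header at line 1 of ", path)
  hdr <- lines[startsWith(lines, "#")]
  level_line <- hdr[startsWith(hdr, "# level: ")]
  nodes_line <- hdr[startsWith(hdr, "# nodes: ")]
  if (length(level_line) != 1 || length(nodes_line) != 1)
    stop("malformed fc_matrix header (missing level/nodes) in ", path)
  level <- sub("# level: ", "", level_line)
  ids <- strsplit(sub("# nodes: ", "", nodes_line), "\t", fixed = TRUE)[[1]]
  body <- lines[!startsWith(lines, "#")]
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\t",
                                              fixed = TRUE)[[1]]))
    if (anyNA(v))
      stop("malformed fc_matrix row at line ",
           which(lines == body[i])[1], " of ", path)
    v
  })
  m <- do.call(rbind, vals)
  fc_matrix(m, node_ids = ids, level = level)
}

#' Write / read a surface mesh as tab-separated text
#'
#' OBJ-like dialect: `v x y z` vertex rows and `f i j k` face rows with
#' 0-based vertex indices.
#'
#' @param mesh A `surface_mesh`.
#' @param path File path.
#' @return `read_surface_mesh` returns a `surface_mesh`;
#'   `write_surface_mesh` returns `path` invisibly.
#' @export
write_surface_mesh <- function(mesh, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# netmapr surface_mesh",
               "# v x y z rows then f i j k rows; indices 0-based"), con)
  writeLines(paste("v",
                   format(mesh$vertices[, 1], digits = 17),
                   format(mesh$vertices[, 2], digits = 17),
                   format(mesh$vertices[, 3], digits = 17), sep = "\t"), con)
  writeLines(paste("f", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_surface_mesh
#' @export
read_surface_mesh <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0 || lines[1] != "# netmapr surface_mesh")
    stop("malformed surface_mesh header at line 1 of ", path)
  body_idx <- which(!startsWith(lines, "#"))
  rows <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  kinds <- vapply(rows, `[[`, "", 1L)
  bad <- which(!(kinds %in% c("v", "f")) | lengths(rows) != 4)
  if (length(bad) > 0)
    stop("malformed surface_mesh row at line ", body_idx[bad[1]],
         " of ", path)
  v <- do.call(rbind, lapply(rows[kinds == "v"], function(r)
    as.numeric(r[2:4])))
  f <- do.call(rbind, lapply(rows[kinds == "f"], function(r)
    as.integer(r[2:4]) + 1L))
  structure(list(vertices = v, faces = f, n_vertices = nrow(v)),
            class = "surface_mesh")
}

#' Write / read a demographics table as tab-separated text
#'
#' @param table Data.frame of per-subject demographics.
#' @param path File path.
#' @return `read_demographics` returns a data.frame; `write_demographics`
#'   returns `path` invisibly.
#' @export
write_demographics <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_demographics
#' @export
read_demographics <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Build a run manifest
#'
#' Records the configuration snapshot, the seeds in play, the package
#' version and a timestamp, so that a report can state exactly how it was
#' produced; deterministic stages rerun from an identical manifest
#' reproduce identical outputs.
#'
#' @param config Configuration list.
#' @param seeds Named list/vector of seeds used.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, seeds) {
  structure(
    list(config = config, seeds = seeds,
         package_version = as.character(utils::packageVersion("netmapr")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}
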