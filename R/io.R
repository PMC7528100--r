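#' Read a skull network from a binary adjacency-matrix CSV
#'
#' The expected dialect is a square 0/1 matrix: first row and first column
#' hold identical bone-name headers, cells are strictly `0` or `1`, the
#' diagonal is zero and the matrix is symmetric.
#'
#' @param path path to the CSV file.
#' @param specimen_id specimen label; defaults to the file name without
#'   extension.
#' @param provenance free-text provenance note.
#' @return A [skull_network()].
#' @export
read_adjacency <- function(path,
                           specimen_id = tools::file_path_sans_ext(basename(path)),
                           provenance = path) {
  x <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  rn <- trimws(x[[1L]])
  m <- as.matrix(x[, -1L, drop = FALSE])
  colnames(m) <- trimws(colnames(m))
  rownames(m) <- rn
  if (nrow(m) != ncol(m))
    abort_skullnet("adjacency matrix is not square", "skullnet_format")
  if (!identical(rownames(m), colnames(m)))
    abort_skullnet("row and column bone-name headers differ",
                   "skullnet_format")
  vals <- trimws(as.vector(m))
  if (!all(vals %in% c("0", "1")))
    abort_skullnet("adjacency cells must be 0 or 1", "skullnet_format")
  a <- matrix(as.integer(vals), nrow = nrow(m), dimnames = dimnames(m))
  if (any(diag(a) != 0L))
    abort_skullnet("adjacency diagonal must be zero (no self-articulations)",
                   "skullnet_format")
  if (!identical(a, t(a)))
    abort_skullnet("adjacency matrix is not symmetric", "skullnet_format")
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    abort_skullnet("adjacency matrix has no articulations", "skullnet_empty")
  edges <- cbind(rownames(a)[idx[, 1L]], colnames(a)[idx[, 2L]])
  skull_network(edges, specimen_id = specimen_id, provenance = provenance)
}

#' Write a skull network as a binary adjacency-matrix CSV
#'
#' Writes the canonical form (bones in sorted order, unquoted headers,
#' `\n` line endings), so that `write_adjacency(read_adjacency(f))` is
#' byte-identical to a canonical `f`.
#'
#' @param net a `skull_network` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(net, path) {
  validate_skull_network(net)
  b <- net$bones
  if (any(grepl("[,\"\n]", b)))
    abort_skullnet("bone names must not contain commas, quotes or newlines",
                   "skullnet_format")
  a <- adjacency_matrix(net)
  lines <- c(paste(c("", b), collapse = ","),
             vapply(seq_along(b), function(i)
               paste(c(b[i], a[i, ]), collapse = ","), character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Binary adjacency matrix of a skull network
#'
#' @param net a `skull_network` object.
#' @return A symmetric 0/1 integer matrix with bone-name dimnames, bones
#'   in canonical (sorted) order.
#' @export
adjacency_matrix <- function(net) {
  b <- net$bones
  a <- matrix(0L, length(b), length(b), dimnames = list(b, b))
  e <- net$articulations
  a[cbind(e[, 1L], e[, 2L])] <- 1L
  a[cbind(e[, 2L], e[, 1L])] <- 1L
  a
}

#' Read / write a skull network as an edge-list TSV
#'
#' Two tab-separated columns, one articulation per line; lines starting
#' with `#` are comments.
#'
#' @param path path to the TSV file.
#' @param specimen_id specimen label; defaults to the file name.
#' @param provenance free-text provenance note.
#' @return `read_edge_list()` returns a [skull_network()];
#'   `write_edge_list()` returns `path` invisibly.
#' @export
read_edge_list <- function(path,
                           specimen_id = tools::file_path_sans_ext(basename(path)),
                           provenance = path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    abort_skullnet("edge list is empty", "skullnet_empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    abort_skullnet("each edge-list line must have exactly two tab-separated bone names",
                   "skullnet_format")
  edges <- do.call(rbind, parts)
  skull_network(edges, specimen_id = specimen_id, provenance = provenance)
}

#' @rdname read_edge_list
#' @param net a `skull_network` object.
#' @export
write_edge_list <- function(net, path) {
  validate_skull_network(net)
  e <- net$articulations
  writeLines(paste(e[, 1L], e[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Export a skull network to GraphML
#'
#' Writes a GraphML file with the specimen id as a graph attribute and,
#' optionally, a `module` vertex attribute for use in external viewers.
#'
#' @param net a `skull_network` object.
#' @param path output path.
#' @param partition optional named vector (bone -> module label), e.g.
#'   the `partition` field of a [detect_modules()] result.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, partition = NULL) {
  g <- as_igraph(net)
  g <- igraph::set_graph_attr(g, "specimen_id", net$specimen_id)
  if (!is.null(partition)) {
    if (!all(net$bones %in% names(partition)))
      abort_skullnet("partition must cover every bone", "skullnet_bad_input")
    g <- igraph::set_vertex_attr(g, "module",
                                 value = as.character(partition[net$bones]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# Allowed levels for the categorical metadata fields.
metadata_levels <- list(
  stage = c("adult", "juvenile"),
  diet = c("carnivorous", "omnivorous", "herbivorous"),
  flight = c("early flight", "soaring", "flapping", "gliding",
             "flightless", "n/a")
)

#' Read and validate a specimen metadata table
#'
#' The table must contain a unique, non-missing `specimen_id` column.
#' When present, `stage`, `diet` and `flight` are checked against their
#' allowed levels (adult/juvenile; carnivorous/omnivorous/herbivorous;
#' early flight/soaring/flapping/gliding/flightless/n-a). Any further
#' columns (clade flags, extant status, ...) are kept as-is.
#'
#' @param path path to a CSV file.
#' @return A validated data frame.
#' @export
read_metadata <- function(path) {
  validate_metadata(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_metadata
#' @param metadata a data frame to validate in place of a file.
#' @export
validate_metadata <- function(metadata) {
  if (!is.data.frame(metadata) || !"specimen_id" %in% names(metadata))
    abort_skullnet("metadata must be a data frame with a specimen_id column",
                   "skullnet_metadata")
  ids <- metadata$specimen_id
  if (anyNA(ids) || anyDuplicated(ids))
    abort_skullnet("specimen_id must be unique and non-missing",
                   "skullnet_metadata")
  for (col in names(metadata_levels)) {
    if (col %in% names(metadata)) {
      vals <- metadata[[col]]
      bad <- !is.na(vals) & !vals %in% metadata_levels[[col]]
      if (any(bad))
        abort_skullnet(
          sprintf("invalid %s level(s): %s", col,
                  paste(unique(vals[bad]), collapse = ", ")),
          "skullnet_metadata")
    }
  }
  metadata
}
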