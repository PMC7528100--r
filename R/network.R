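#' Build a skull network from a list of articulations
#'
#' A skull network is an undirected, simple, connected graph whose nodes are
#' bones and whose links are pair-wise articulations. Bones that are fused
#' without trace of a suture are modelled as a single node (see
#' [fuse_bones()]). The constructor canonicalizes the input: bone names are
#' whitespace-trimmed (case-sensitive), duplicate articulations are
#' collapsed, each pair is stored in lexicographic order, and the bone list
#' is the sorted union of all names appearing in `edges`.
#'
#' @param edges articulations, as a two-column matrix or data frame of bone
#'   names, or a list of length-2 character vectors.
#' @param specimen_id label for the specimen this skull belongs to.
#' @param provenance free-text note on the source of the data.
#'
#' @return An object of class `skull_network` with fields `specimen_id`,
#'   `bones` (sorted unique bone names), `articulations` (two-column
#'   character matrix, canonical order) and `provenance`.
#'
#' @details Self-articulations are rejected (`skullnet_self_loop` error).
#'   A disconnected bone set is rejected (`skullnet_disconnected` error)
#'   because a skull is a single structure and the mean path length is
#'   undefined otherwise; the error message lists the components.
#'
#' @examples
#' net <- skull_network(rbind(c("frontal", "parietal"),
#'                            c("parietal", "nasal")), "toy")
#' net
#' @export
skull_network <- function(edges, specimen_id = "specimen", provenance = "") {
  e <- normalize_edges(edges)
  if (nrow(e) == 0L)
    abort_skullnet("`edges` must contain at least one articulation",
                   "skullnet_empty")
  loops <- e[, 1L] == e[, 2L]
  if (any(loops))
    abort_skullnet(
      sprintf("self-articulation not allowed: %s",
              paste(unique(e[loops, 1L]), collapse = ", ")),
      "skullnet_self_loop")
  swap <- e[, 1L] > e[, 2L]
  e[swap, ] <- e[swap, 2:1]
  e <- unique(e)
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  bones <- sort(unique(as.vector(e)))
  net <- structure(
    list(specimen_id = as.character(specimen_id)[1L],
         bones = bones,
         articulations = e,
         provenance = as.character(provenance)[1L]),
    class = "skull_network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    parts <- split(names(comp$membership), comp$membership)
    abort_skullnet(
      sprintf("skull network is disconnected; components: %s",
              paste(vapply(parts, function(p) paste(p, collapse = "+"),
                           character(1L)), collapse = " | ")),
      "skullnet_disconnected")
  }
  validate_skull_network(net)
}

# Coerce edge input to a trimmed two-column character matrix.
normalize_edges <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, function(p) as.character(p)))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L)
    abort_skullnet("`edges` must have exactly two columns (bone pairs)",
                   "skullnet_bad_input")
  e <- matrix(trimws(as.character(edges)), ncol = 2L)
  if (any(!nzchar(e)) || anyNA(e))
    abort_skullnet("bone names must be non-empty strings",
                   "skullnet_bad_input")
  dimnames(e) <- NULL
  e
}

#' Validate skull-network invariants
#'
#' Checks the structural invariants of a [skull_network()]: at least two
#' bones and one articulation, no self-articulations, unique canonical
#' pairs, and all articulation endpoints present in the bone list.
#' Connectivity is established at construction time.
#'
#' @param net a `skull_network` object.
#' @return `net`, invisibly usable, if valid; otherwise an error.
#' @export
validate_skull_network <- function(net) {
  if (!inherits(net, "skull_network"))
    abort_skullnet("not a skull_network object", "skullnet_bad_input")
  e <- net$articulations
  if (length(net$bones) < 2L || nrow(e) < 1L)
    abort_skullnet("a skull network needs at least 2 bones and 1 articulation",
                   "skullnet_too_small")
  if (any(e[, 1L] == e[, 2L]))
    abort_skullnet("self-articulation present", "skullnet_self_loop")
  if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\r")))
    abort_skullnet("duplicate articulations present", "skullnet_bad_input")
  if (!all(as.vector(e) %in% net$bones))
    abort_skullnet("articulation references unknown bone",
                   "skullnet_bad_input")
  net
}

#' Convert a skull network to an igraph graph
#'
#' @param net a `skull_network` object.
#' @return An [igraph::igraph] graph with vertices in the canonical bone
#'   order and vertex attribute `name` set to the bone names.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "skull_network"))
  igraph::graph_from_data_frame(
    as.data.frame(net$articulations, stringsAsFactors = FALSE),
    directed = FALSE, vertices = net$bones)
}

#' Number of bones / articulations
#'
#' @param net a `skull_network` object.
#' @return Integer count of nodes (`n_bones`) or links (`n_articulations`).
#' @export
n_bones <- function(net) length(net$bones)

#' @rdname n_bones
#' @export
n_articulations <- function(net) nrow(net$articulations)

#' @export
print.skull_network <- function(x, ...) {
  cat(sprintf("<skull_network '%s'>  %d bones, %d articulations\n",
              x$specimen_id, n_bones(x), n_articulations(x)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Neighbour set of one bone.
bone_neighbors <- function(net, bone) {
  e <- net$articulations
  sort(unique(c(e[e[, 2L] == bone, 1L], e[e[, 1L] == bone, 2L])))
}

#' Fuse two bones into a single node
#'
#' Bone fusion (e.g. the closure of a suture during ontogeny or evolution,
#' as in Williston's law) is modelled as node contraction: the two bones
#' are replaced by a single node whose neighbourhood is the union of their
#' neighbourhoods. The result remains simple and connected; the bone count
#' drops by exactly one, and the articulation count drops by one for the
#' fused pair's own articulation (if present) plus one per shared
#' neighbour (duplicate links collapse).
#'
#' @param net a `skull_network` object.
#' @param a,b names of the two bones to fuse (must differ and be present).
#' @param fused_name name of the new node; defaults to `"a+b"`. Must not
#'   collide with any remaining bone.
#' @return A new `skull_network` with `n_bones(net) - 1` bones.
#' @examples
#' sq <- skull_network(rbind(c("L.frontal", "R.frontal"),
#'                           c("R.frontal", "parietal"),
#'                           c("parietal", "nasal"),
#'                           c("nasal", "L.frontal")))
#' fused <- fuse_bones(sq, "L.frontal", "R.frontal", "frontal")
#' n_bones(fused)          # 3
#' n_articulations(fused)  # 3
#' @export
fuse_bones <- function(net, a, b, fused_name = paste(a, b, sep = "+")) {
  validate_skull_network(net)
  a <- trimws(a); b <- trimws(b); fused_name <- trimws(fused_name)
  if (identical(a, b))
    abort_skullnet("cannot fuse a bone with itself", "skullnet_bad_input")
  missing <- setdiff(c(a, b), net$bones)
  if (length(missing))
    abort_skullnet(sprintf("unknown bone(s): %s",
                           paste(missing, collapse = ", ")),
                   "skullnet_unknown_bone")
  if (fused_name %in% setdiff(net$bones, c(a, b)))
    abort_skullnet(sprintf("fused name '%s' collides with an existing bone",
                           fused_name), "skullnet_name_collision")
  if (n_bones(net) <= 2L)
    abort_skullnet("cannot fuse: result would have fewer than 2 bones",
                   "skullnet_too_small")
  e <- net$articulations
  e[e == a | e == b] <- fused_name
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  skull_network(e, specimen_id = net$specimen_id,
                provenance = net$provenance)
}
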