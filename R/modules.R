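#' Local spinglass module around one bone
#'
#' Runs a single-community spinglass search (simulated-annealing Potts
#' model) anchored at `focal_bone` and returns the community containing
#' it. With `method = "global"` a whole-graph spinglass partition is
#' computed instead and the focal bone's cell returned. For very small
#' skulls (N <= 5) annealing is unreliable, so the cell of the exhaustive
#' maximum-modularity partition is returned.
#'
#' @param net a [skull_network()].
#' @param focal_bone name of the anchor bone; always contained in the
#'   returned set.
#' @param seed RNG seed; a failed run is retried with an incremented seed
#'   (bounded, logged via `message()`).
#' @param spins,gamma spinglass hyperparameters (number of spin states and
#'   resolution).
#' @param method `"anchored"` (single-community variant, default) or
#'   `"global"` (whole-graph partition).
#' @param max_retries bound on retries after a failed spinglass run.
#' @return Character vector of bone names.
#' @export
local_module <- function(net, focal_bone, seed = 1L, spins = 25L,
                         gamma = 1, method = c("anchored", "global"),
                         max_retries = 5L) {
  method <- match.arg(method)
  validate_skull_network(net)
  if (!focal_bone %in% net$bones)
    abort_skullnet(sprintf("unknown bone '%s'", focal_bone),
                   "skullnet_unknown_bone")
  g <- as_igraph(net)
  if (n_bones(net) <= 5L) {
    memb <- exhaustive_partition(g)
    return(sort(net$bones[memb == memb[match(focal_bone, net$bones)]]))
  }
  for (attempt in 0:max_retries) {
    set.seed(seed + attempt)
    res <- tryCatch({
      if (method == "anchored") {
        out <- igraph::cluster_spinglass(g, vertex = focal_bone,
                                         spins = spins, gamma = gamma)
        net$bones[out$community]
      } else {
        out <- igraph::cluster_spinglass(g, spins = spins, gamma = gamma)
        memb <- igraph::membership(out)
        names(memb)[memb == memb[[focal_bone]]]
      }
    }, error = function(e) e)
    if (!inherits(res, "error")) return(sort(unique(c(focal_bone, res))))
    message(sprintf("spinglass failed at '%s' (seed %d): %s; retrying",
                    focal_bone, seed + attempt, conditionMessage(res)))
  }
  abort_skullnet(sprintf("spinglass did not converge at '%s' after %d retries",
                         focal_bone, max_retries), "skullnet_detection")
}

# Exhaustive maximum-modularity partition for tiny graphs: enumerates all
# set partitions via restricted growth strings (Bell(5) = 52) and keeps
# the one with highest Newman modularity; ties broken toward fewer
# modules, then first in enumeration order (deterministic).
exhaustive_partition <- function(g) {
  n <- igraph::vcount(g)
  best <- rep(1L, n)
  best_q <- igraph::modularity(g, best)
  rgs <- function(prefix, mx) {
    if (length(prefix) == n) return(list(prefix))
    out <- list()
    for (v in seq_len(mx + 1L))
      out <- c(out, rgs(c(prefix, v), max(mx, v)))
    out
  }
  for (memb in rgs(1L, 1L)) {
    q <- igraph::modularity(g, memb)
    improves <- q > best_q + 1e-12 ||
      (abs(q - best_q) <= 1e-12 && max(memb) < max(best))
    if (improves) { best <- memb; best_q <- q }
  }
  best
}

#' Hypergeometric intersection test for two candidate modules
#'
#' Upper-tail probability of observing at least the given overlap when
#' `|a|` and `|b|` bones are drawn without replacement from `n_total`
#' bones. A small value means the two candidate modules share more bones
#' than expected by chance, i.e. they are redundant descriptions of the
#' same anatomical region.
#'
#' @param module_a,module_b character vectors of bone names (subsets of
#'   the `n_total` bones).
#' @param n_total total number of bones in the network.
#' @return The probability `P(X >= |a intersect b|)`.
#' @examples
#' intersection_pvalue(letters[1:5], letters[1:5], 20)  # 1 / choose(20, 5)
#' @export
intersection_pvalue <- function(module_a, module_b, n_total) {
  a <- unique(module_a); b <- unique(module_b)
  if (length(a) > n_total || length(b) > n_total)
    abort_skullnet("module larger than the network", "skullnet_bad_input")
  ov <- length(intersect(a, b))
  if (ov > min(length(a), length(b)))
    abort_skullnet("overlap exceeds the smaller module", "skullnet_bad_input")
  stats::phyper(ov - 1L, length(a), n_total - length(a), length(b),
                lower.tail = FALSE)
}

#' Detect anatomical-network modules (node-based informed strategy)
#'
#' Starts a [local_module()] spinglass search at every bone, removes
#' duplicate candidate sets, and then iteratively merges pairs of
#' candidates whose intersection is statistically significant under the
#' hypergeometric test (Bonferroni-adjusted over the current candidate
#' pairs) — significant overlap marks two candidates as redundant
#' descriptions of one module. Merging repeats to a fixed point. The
#' surviving modules may overlap; a disjoint partition for the
#' parcellation index is derived with [disjointify()]. A single-module
#' outcome is valid (small, highly fused skulls).
#'
#' For N <= 5 the exhaustive maximum-modularity partition is used
#' directly instead of annealing.
#'
#' @param net a [skull_network()].
#' @param seed master seed; per-bone seeds are `seed +` bone index.
#' @param alpha significance level for the Bonferroni-adjusted merge test.
#' @param spins,gamma,method passed to [local_module()].
#' @return An object of class `module_set`: list with `modules` (list of
#'   bone-name sets, possibly overlapping), `partition` (named bone ->
#'   module-label vector), `n_modules`, `merge_log` (data frame of merge
#'   decisions with raw and adjusted p-values), and `params`.
#' @examples
#' net <- skull_network(t(combn(c("a", "b", "c", "d", "e"), 2)))
#' detect_modules(net, seed = 7)$n_modules  # complete graph: one module
#' @export
detect_modules <- function(net, seed = 42L, alpha = 0.05, spins = 25L,
                           gamma = 1, method = "anchored") {
  validate_skull_network(net)
  n <- n_bones(net)
  params <- list(seed = seed, alpha = alpha, spins = spins, gamma = gamma,
                 method = method)
  if (n <= 5L) {
    memb <- exhaustive_partition(as_igraph(net))
    modules <- unname(lapply(split(net$bones, memb), sort))
    return(new_module_set(modules, net, merge_log = NULL, params = params))
  }
  candidates <- lapply(seq_len(n), function(i)
    local_module(net, net$bones[i], seed = seed + i, spins = spins,
                 gamma = gamma, method = method))
  candidates <- unique(candidates)
  merge_log <- list()
  repeat {
    k <- length(candidates)
    if (k < 2L) break
    pairs <- utils::combn(k, 2L)
    praw <- apply(pairs, 2L, function(ij)
      intersection_pvalue(candidates[[ij[1L]]], candidates[[ij[2L]]], n))
    padj <- pmin(1, praw * ncol(pairs))
    best <- which.min(padj)
    if (padj[best] >= alpha) break
    i <- pairs[1L, best]; j <- pairs[2L, best]
    merge_log[[length(merge_log) + 1L]] <- data.frame(
      size_a = length(candidates[[i]]), size_b = length(candidates[[j]]),
      overlap = length(intersect(candidates[[i]], candidates[[j]])),
      p_raw = praw[best], p_adj = padj[best])
    merged <- sort(union(candidates[[i]], candidates[[j]]))
    candidates <- c(candidates[-c(i, j)], list(merged))
    candidates <- unique(candidates)
  }
  # Coverage guard: any bone missed by every candidate joins the module
  # holding most of its articulations (cannot happen with the anchored
  # search, which always contains its focal bone).
  uncovered <- setdiff(net$bones, unique(unlist(candidates)))
  for (bone in uncovered) {
    votes <- vapply(candidates, function(m)
      length(intersect(bone_neighbors(net, bone), m)), integer(1L))
    pick <- which.max(votes)
    candidates[[pick]] <- sort(c(candidates[[pick]], bone))
  }
  log_df <- if (length(merge_log)) do.call(rbind, merge_log) else NULL
  new_module_set(candidates, net, merge_log = log_df, params = params)
}

new_module_set <- function(modules, net, merge_log, params) {
  modules <- modules[order(vapply(modules, function(m) m[1L], character(1L)))]
  part <- disjointify(modules, net)
  structure(list(
    specimen_id = net$specimen_id,
    modules = modules,
    n_modules = length(modules),
    partition = part,
    merge_log = merge_log,
    params = params), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set '%s'>  %d module(s), %d partition cell(s)\n",
              x$specimen_id, x$n_modules,
              length(unique(x$partition))))
  sizes <- vapply(x$modules, length, integer(1L))
  cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Derive a disjoint partition from (possibly overlapping) modules
#'
#' Each bone is assigned to the module containing the largest fraction of
#' its articulations; ties go to the larger module, then to the
#' lexicographically first module label — a deterministic rule, so
#' repeated runs agree. Modules left empty are dropped. Only modules that
#' contain the bone are considered (every bone is covered by
#' construction).
#'
#' @param modules a `module_set` or a list of bone-name sets covering all
#'   bones.
#' @param net the [skull_network()] the modules belong to.
#' @return Named character vector bone -> module label (`M01`, `M02`, ...
#'   in module order; labels of dropped empty modules are skipped).
#' @export
disjointify <- function(modules, net) {
  if (inherits(modules, "module_set")) modules <- modules$modules
  validate_skull_network(net)
  if (!all(net$bones %in% unique(unlist(modules))))
    abort_skullnet("modules must cover every bone", "skullnet_bad_input")
  labels <- sprintf("M%02d", seq_along(modules))
  sizes <- vapply(modules, length, integer(1L))
  part <- vapply(net$bones, function(bone) {
    cand <- which(vapply(modules, function(m) bone %in% m, logical(1L)))
    if (length(cand) == 1L) return(labels[cand])
    nb <- bone_neighbors(net, bone)
    frac <- vapply(cand, function(i)
      length(intersect(nb, setdiff(modules[[i]], bone))) / length(nb),
      numeric(1L))
    ord <- order(-frac, -sizes[cand], labels[cand])
    labels[cand[ord[1L]]]
  }, character(1L))
  names(part) <- net$bones
  part
}

#' Long-format module tables for a cohort
#'
#' @param module_sets named list of [detect_modules()] results (names are
#'   specimen ids, or taken from the objects).
#' @return A list of two data frames: `partition` (specimen_id, bone,
#'   module) and `overlap` (specimen_id, module, bone; one row per module
#'   membership, so overlapping bones appear more than once).
#' @export
module_tables <- function(module_sets) {
  part <- do.call(rbind, lapply(module_sets, function(ms)
    data.frame(specimen_id = ms$specimen_id,
               bone = names(ms$partition),
               module = unname(ms$partition),
               stringsAsFactors = FALSE)))
  over <- do.call(rbind, lapply(module_sets, function(ms)
    do.call(rbind, lapply(seq_along(ms$modules), function(i)
      data.frame(specimen_id = ms$specimen_id,
                 module = sprintf("M%02d", i),
                 bone = ms$modules[[i]],
                 stringsAsFactors = FALSE)))))
  rownames(part) <- rownames(over) <- NULL
  list(partition = part, overlap = over)
}
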