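#' Topological variables of a skull network
#'
#' The eight whole-skull variables used throughout the package are the
#' number of bones (N), the number of articulations (K), the density of
#' connections (D), the mean clustering coefficient (C), the mean path
#' length (L), the heterogeneity of connections (H), the assortativity of
#' connections (A) and the parcellation (P). D, C and L are proxies for
#' morphological complexity and integration; H and A for anisomerism
#' (diversification of bones); P for the degree of modularity.
#'
#' @param net a [skull_network()].
#' @return `net_density()`: `2K / (N(N-1))`, in (0, 1].
#' @name topology-metrics
NULL

#' @rdname topology-metrics
#' @export
net_density <- function(net) {
  validate_skull_network(net)
  n <- n_bones(net)
  2 * n_articulations(net) / (n * (n - 1))
}

#' @rdname topology-metrics
#' @param isolates how nodes of degree < 2 enter the mean clustering
#'   coefficient: `"zero"` (default) counts them as 0, `"exclude"` drops
#'   them from the average.
#' @return `net_clustering()`: mean local clustering coefficient in
#'   \[0, 1\] (fraction of realised triangles among each bone's
#'   neighbours, averaged over bones).
#' @export
net_clustering <- function(net, isolates = c("zero", "exclude")) {
  isolates <- match.arg(isolates)
  g <- as_igraph(net)
  loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (isolates == "zero") loc[is.nan(loc)] <- 0
  mean(loc, na.rm = TRUE)
}

#' @rdname topology-metrics
#' @return `net_path_length()`: mean shortest-path length over all
#'   unordered bone pairs, in \[1, N - 1\]. Defined because skull
#'   networks are connected by construction.
#' @export
net_path_length <- function(net) {
  igraph::mean_distance(as_igraph(net), directed = FALSE)
}

#' @rdname topology-metrics
#' @param formula heterogeneity formula: `"cv"` (default) is the
#'   coefficient of variation of the degree sequence (population standard
#'   deviation divided by mean degree); `"variance"` is the population
#'   variance of degrees. Both are 0 exactly when all bones have the same
#'   number of articulations (a regular network).
#' @return `net_heterogeneity()`: non-negative, unitless.
#' @export
net_heterogeneity <- function(net, formula = c("cv", "variance")) {
  formula <- match.arg(formula)
  deg <- igraph::degree(as_igraph(net))
  m <- mean(deg)
  v <- mean((deg - m)^2)
  switch(formula, cv = sqrt(v) / m, variance = v)
}

#' @rdname topology-metrics
#' @return `net_assortativity()`: Newman degree assortativity (Pearson
#'   correlation of end-point degrees over articulations), in \[-1, 1\].
#'   For degree-regular networks the correlation is undefined
#'   (zero variance) and `NA` is returned as an explicit flag, not an
#'   error; see [compute_profile()] for how it is imputed downstream.
#' @export
net_assortativity <- function(net) {
  r <- suppressWarnings(
    igraph::assortativity_degree(as_igraph(net), directed = FALSE))
  if (!is.finite(r)) NA_real_ else r
}

#' Parcellation index of a module partition
#'
#' `P = 1 - sum((n_i / N)^2)` over module sizes `n_i`: 0 when the skull
#' forms a single integrated module, `1 - 1/S` for S equally sized
#' modules, approaching 1 as the number of even modules grows.
#'
#' @param partition either a [detect_modules()] result or a vector of
#'   module labels, one per bone (each bone assigned to exactly one
#'   module).
#' @return Parcellation index in \[0, 1).
#' @export
parcellation <- function(partition) {
  if (inherits(partition, "module_set")) partition <- partition$partition
  if (anyNA(partition))
    abort_skullnet("every bone must be assigned to exactly one module",
                   "skullnet_bad_partition")
  sizes <- table(as.character(partition))
  n <- sum(sizes)
  1 - sum((as.numeric(sizes) / n)^2)
}

#' Compute the eight-variable topology profile of one skull
#'
#' Parcellation requires a disjoint module partition; if `modules` is not
#' supplied, [detect_modules()] is run with the given `seed`. The raw
#' profile keeps an undefined assortativity as `NA` (flagged in the
#' `"assortativity_undefined"` attribute); [profiles_table()] imputes it
#' for multivariate analyses.
#'
#' @param net a [skull_network()].
#' @param modules a [detect_modules()] result, a bone -> module vector, or
#'   `NULL` to detect modules here.
#' @param seed seed for module detection when `modules` is `NULL`.
#' @param clustering_isolates,h_formula passed to [net_clustering()] and
#'   [net_heterogeneity()].
#' @return A one-row data frame of class `topology_profile` with columns
#'   `specimen_id, N, K, D, C, L, H, A, P`.
#' @examples
#' net <- skull_network(t(combn(c("a", "b", "c", "d"), 2)), "complete4")
#' compute_profile(net, seed = 1)
#' @export
compute_profile <- function(net, modules = NULL, seed = 1L,
                            clustering_isolates = "zero",
                            h_formula = "cv") {
  validate_skull_network(net)
  if (is.null(modules)) modules <- detect_modules(net, seed = seed)
  a <- net_assortativity(net)
  prof <- data.frame(
    specimen_id = net$specimen_id,
    N = n_bones(net),
    K = n_articulations(net),
    D = net_density(net),
    C = net_clustering(net, isolates = clustering_isolates),
    L = net_path_length(net),
    H = net_heterogeneity(net, formula = h_formula),
    A = if (is.na(a)) NA_real_ else a,
    P = parcellation(modules),
    stringsAsFactors = FALSE)
  attr(prof, "assortativity_undefined") <- is.na(a)
  class(prof) <- c("topology_profile", class(prof))
  prof
}

#' Topology profiles for a cohort of skulls
#'
#' Runs [compute_profile()] for every network, detecting modules per
#' specimen with seeds derived from `seed` (seed + specimen index).
#' Undefined assortativity values are imputed as 0 with a warning when
#' `impute_assortativity` is `TRUE` (the default), since the downstream
#' PCA cannot carry missing values.
#'
#' @param networks a list of [skull_network()] objects.
#' @param module_sets optional list of [detect_modules()] results (same
#'   length/order as `networks`); detected here when `NULL`.
#' @param seed master seed for per-specimen module detection.
#' @param impute_assortativity replace flagged-undefined A by 0?
#' @param ... passed on to [compute_profile()].
#' @return A data frame with one row per specimen and columns
#'   `specimen_id, N, K, D, C, L, H, A, P`.
#' @export
profiles_table <- function(networks, module_sets = NULL, seed = 1L,
                           impute_assortativity = TRUE, ...) {
  stopifnot(is.list(networks), length(networks) >= 1L)
  rows <- lapply(seq_along(networks), function(i) {
    mods <- if (is.null(module_sets)) NULL else module_sets[[i]]
    compute_profile(networks[[i]], modules = mods, seed = seed + i, ...)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame))
  if (impute_assortativity && anyNA(out$A)) {
    warning(sprintf(
      "assortativity undefined (regular network) for: %s; imputed as 0",
      paste(out$specimen_id[is.na(out$A)], collapse = ", ")))
    out$A[is.na(out$A)] <- 0
  }
  rownames(out) <- NULL
  out
}
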