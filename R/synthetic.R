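#' Generate a bilaterally symmetric template skull network
#'
#' Builds one half of the skull as a random connected, spatially local
#' sparse graph (a spanning tree over index-ordered bones plus extra
#' short-range edges, mimicking sutural adjacency between neighbouring
#' bones), mirrors it, and joins the halves through a chain of unpaired
#' midline bones, each articulating with the same bones on both sides.
#' The result is connected, sparse, and bilaterally symmetric under the
#' left/right relabeling map.
#'
#' Paired bones are named `L.bXX` / `R.bXX`; midline bones `mXX`. The
#' `"regions"` attribute carries a planted module structure (anterior /
#' middle / posterior thirds of each half, shared across sides, plus a
#' midline region) used by [simulate_fusion_trajectory()] to bias
#' fusions within modules.
#'
#' @param n_half number of bones per side (>= 3).
#' @param n_midline number of unpaired midline bones (>= 1; an empty
#'   midline would disconnect the halves).
#' @param p_extra probability of each admissible extra short-range edge
#'   within a half.
#' @param reach maximum index distance for short-range edges.
#' @param seed RNG seed; a fixed seed reproduces the network exactly.
#' @param specimen_id specimen label.
#' @return A [skull_network()] with `N = 2 * n_half + n_midline` bones
#'   and attribute `"regions"` (named bone -> region vector).
#' @export
make_template_skull <- function(n_half = 10L, n_midline = 4L,
                                p_extra = 0.25, reach = 3L, seed = 1L,
                                specimen_id = "template") {
  if (n_half < 3L)
    abort_skullnet("n_half must be at least 3", "skullnet_bad_input")
  if (n_midline < 1L)
    abort_skullnet("midline must be non-empty (halves would disconnect)",
                   "skullnet_bad_input")
  set.seed(seed)
  half <- matrix(integer(0), 0L, 2L)
  for (i in 2:n_half) {
    j <- if (i == 2L) 1L else
      resample(seq(max(1L, i - reach), i - 1L), 1L)
    half <- rbind(half, c(j, i))
  }
  for (i in 1:(n_half - 1L)) {
    for (j in (i + 1L):min(n_half, i + reach)) {
      already <- any(half[, 1L] == i & half[, 2L] == j)
      if (!already && stats::runif(1) < p_extra)
        half <- rbind(half, c(i, j))
    }
  }
  bname <- function(side, i) sprintf("%s.b%02d", side, i)
  edges <- rbind(
    cbind(bname("L", half[, 1L]), bname("L", half[, 2L])),
    cbind(bname("R", half[, 1L]), bname("R", half[, 2L])))
  mline <- sprintf("m%02d", seq_len(n_midline))
  if (n_midline > 1L)
    edges <- rbind(edges, cbind(mline[-n_midline], mline[-1L]))
  # Anchor midline bones along the half, spread front to back, with the
  # same attachments on both sides (bilateral symmetry).
  anchor_at <- round(seq(1L, n_half, length.out = n_midline))
  for (k in seq_len(n_midline)) {
    extra <- sample(0:1, 1L)
    att <- unique(c(anchor_at[k],
                    if (extra) sample(n_half, 1L)))
    edges <- rbind(edges,
                   cbind(mline[k], bname("L", att)),
                   cbind(mline[k], bname("R", att)))
  }
  net <- skull_network(edges, specimen_id = specimen_id,
                       provenance = sprintf("synthetic template (seed %d)", seed))
  third <- cut(seq_len(n_half), breaks = 3L,
               labels = c("anterior", "middle", "posterior"))
  regions <- c(
    stats::setNames(as.character(third), bname("L", seq_len(n_half))),
    stats::setNames(as.character(third), bname("R", seq_len(n_half))),
    stats::setNames(rep("midline", n_midline), mline))
  attr(net, "regions") <- regions[net$bones]
  net
}

# sample() treats a length-1 numeric x as 1:x; this does not.
resample <- function(x, ...) x[sample.int(length(x), ...)]

# Mirror of a (possibly compound, "+"-joined) bone name; NA when the
# bone has no clean mirror (midline or cross-side fused).
mirror_name <- function(x) {
  parts <- strsplit(x, "+", fixed = TRUE)[[1L]]
  if (all(startsWith(parts, "L."))) {
    paste(sub("^L\\.", "R.", parts), collapse = "+")
  } else if (all(startsWith(parts, "R."))) {
    paste(sub("^R\\.", "L.", parts), collapse = "+")
  } else NA_character_
}

#' Simulate a bone-fusion trajectory
#'
#' Starting from a template skull, repeatedly fuses articulated bone
#' pairs (Williston's law: skulls lose bones through fusion). Candidate
#' pairs are sampled among current articulations, with same-module pairs
#' up-weighted by `bias` (bones within a module are more likely to fuse).
#' When a fused pair has an intact mirrored counterpart, the mirror pair
#' is co-fused with probability `mirror_prob` (paired bones typically
#' fuse bilaterally); each co-fusion counts as its own fusion event, so
#' the final bone count is exactly `N0 - n_events`.
#'
#' @param template a [skull_network()], typically [make_template_skull()].
#' @param n_fusions number of (non-mirror) fusion draws; must be at most
#'   `N - 3` so the result keeps >= 2 bones even after a trailing
#'   co-fusion.
#' @param bias multiplicative weight for same-module candidate pairs
#'   (1 = unbiased).
#' @param mirror_prob probability of co-fusing the mirrored pair.
#' @param modules named bone -> module vector used for the bias; defaults
#'   to the template's `"regions"` attribute. `NULL` disables the bias.
#' @param seed RNG seed.
#' @return A list of `skull_network`s, one per fusion event (each derived
#'   from the previous by a single [fuse_bones()] call), with attributes
#'   `n_events`, `n_cofusions` and `within_module_fraction`.
#' @export
simulate_fusion_trajectory <- function(template, n_fusions, bias = 1,
                                       mirror_prob = 0.9,
                                       modules = attr(template, "regions"),
                                       seed = 1L) {
  validate_skull_network(template)
  n0 <- n_bones(template)
  if (n_fusions < 1L || n_fusions > n0 - 3L)
    abort_skullnet("n_fusions must be between 1 and N - 3",
                   "skullnet_bad_input")
  set.seed(seed)
  net <- template
  mod <- modules
  traj <- list()
  n_events <- 0L
  n_cofusions <- 0L
  n_within <- 0L
  do_fuse <- function(net, a, b) {
    fused <- paste(a, b, sep = "+")
    out <- fuse_bones(net, a, b, fused)
    if (!is.null(mod)) {
      mod[fused] <<- unname(mod[a])
      mod <<- mod[setdiff(names(mod), c(a, b))]
    }
    out
  }
  while (n_events < n_fusions) {
    e <- net$articulations
    same <- if (is.null(mod)) rep(FALSE, nrow(e)) else
      unname(mod[e[, 1L]] == mod[e[, 2L]])
    w <- ifelse(same, bias, 1)
    pick <- sample.int(nrow(e), 1L, prob = w)
    a <- e[pick, 1L]; b <- e[pick, 2L]
    if (isTRUE(same[pick])) n_within <- n_within + 1L
    net <- do_fuse(net, a, b)
    n_events <- n_events + 1L
    traj[[length(traj) + 1L]] <- net
    ma <- mirror_name(a); mb <- mirror_name(b)
    can_mirror <- !is.na(ma) && !is.na(mb) && ma != mb &&
      all(c(ma, mb) %in% net$bones) &&
      any(net$articulations[, 1L] == pmin(ma, mb) &
            net$articulations[, 2L] == pmax(ma, mb)) &&
      n_bones(net) > 3L
    if (can_mirror && stats::runif(1) < mirror_prob) {
      net <- do_fuse(net, ma, mb)
      n_events <- n_events + 1L
      n_cofusions <- n_cofusions + 1L
      traj[[length(traj) + 1L]] <- net
    }
  }
  attr(traj, "n_events") <- n_events
  attr(traj, "n_cofusions") <- n_cofusions
  attr(traj, "within_module_fraction") <-
    if (n_events - n_cofusions > 0) n_within / (n_events - n_cofusions)
    else NA_real_
  traj
}

#' Planted-partition (stochastic block) network with ground truth
#'
#' Samples a standard stochastic block model: within-block edges with
#' probability `p_in`, between-block edges with probability `p_out`.
#' Connectivity is forced by adding a minimal number of bridging edges
#' between components (count reported in `n_bridges`). Used as ground
#' truth for module-recovery tests.
#'
#' @param sizes integer vector of block sizes (sum >= 6).
#' @param p_in,p_out within/between-block edge probabilities; `p_in`
#'   must exceed `p_out` so the truth labels are meaningful.
#' @param seed RNG seed.
#' @param specimen_id specimen label.
#' @return A list with `network` (a [skull_network()]), `truth` (named
#'   bone -> block factor) and `n_bridges`.
#' @export
planted_partition_network <- function(sizes, p_in, p_out, seed = 1L,
                                      specimen_id = "planted") {
  if (sum(sizes) < 6L)
    abort_skullnet("need at least 6 nodes in total", "skullnet_bad_input")
  if (!(p_in > p_out))
    abort_skullnet("p_in must exceed p_out for truth-labeled use",
                   "skullnet_bad_input")
  if (p_in > 1 || p_out < 0)
    abort_skullnet("probabilities must be in [0, 1]", "skullnet_bad_input")
  set.seed(seed)
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  names(block) <- sprintf("b%02d", seq_len(n))
  pairs <- utils::combn(n, 2L)
  p <- ifelse(block[pairs[1L, ]] == block[pairs[2L, ]], p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < p
  edges <- cbind(names(block)[pairs[1L, keep]],
                 names(block)[pairs[2L, keep]])
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE, vertices = names(block))
  comp <- igraph::components(g)
  n_bridges <- 0L
  while (comp$no > 1L) {
    members <- split(names(comp$membership), comp$membership)
    a <- sample(members[[1L]], 1L)
    b <- sample(members[[2L]], 1L)
    edges <- rbind(edges, c(a, b))
    n_bridges <- n_bridges + 1L
    g <- igraph::add_edges(g, c(a, b))
    comp <- igraph::components(g)
  }
  net <- skull_network(edges, specimen_id = specimen_id,
                       provenance = sprintf(
                         "planted partition (p_in=%g, p_out=%g, seed=%d)",
                         p_in, p_out, seed))
  list(network = net,
       truth = factor(block[net$bones]),
       n_bridges = n_bridges)
}

#' Default synthetic cohort groups
#'
#' Two groups emulating the ontogenetic/evolutionary contrast in
#' archosaur skulls: a "basal" group of large, little-fused skulls
#' (template-sized, like non-avian dinosaurs and juveniles at 32-44
#' bones) and a "derived" group of heavily fused skulls (like adult
#' crown birds, where extensive postnatal fusion leaves far fewer
#' bones). Group sizes add to 25, the size of a typical comparative
#' cohort.
#'
#' @return A list of group specifications for [make_cohort()]: each has
#'   `label`, `n` (specimen count), `fusions` (min/max fusion events) and
#'   `meta` (metadata column values).
#' @export
default_cohort_groups <- function() {
  list(
    list(label = "basal", n = 13L, fusions = c(0L, 4L),
         meta = list(stage = "adult", neornithes = FALSE, extant = FALSE)),
    list(label = "derived", n = 12L, fusions = c(16L, 24L),
         meta = list(stage = "adult", neornithes = TRUE, extant = TRUE)))
}

#' Generate a synthetic cohort of skull networks with metadata
#'
#' Each specimen gets its own template (same size parameters, fresh
#' seed) and a fusion trajectory whose length is drawn uniformly from the
#' group's `fusions` range; the final network of the trajectory is the
#' specimen's skull. Null cohorts (identical fusion ranges in every
#' group) are supported for type-I error calibration. Regeneration from
#' the same master seed is bit-identical.
#'
#' @param groups list of group specifications, see
#'   [default_cohort_groups()].
#' @param n_half,n_midline,p_extra,reach template parameters, see
#'   [make_template_skull()].
#' @param bias,mirror_prob fusion parameters, see
#'   [simulate_fusion_trajectory()].
#' @param seed master seed; every specimen's seeds derive from it.
#' @return A list with `networks` (named list of [skull_network()]s) and
#'   `metadata` (data frame with `specimen_id`, `taxon`, `group` and the
#'   group `meta` columns).
#' @export
make_cohort <- function(groups = default_cohort_groups(),
                        n_half = 19L, n_midline = 6L, p_extra = 0.25,
                        reach = 3L, bias = 4, mirror_prob = 0.9,
                        seed = 1L) {
  networks <- list()
  meta_rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    stopifnot(!is.null(grp$label), !is.null(grp$n), !is.null(grp$fusions))
    if (grp$n < 2L)
      abort_skullnet("each group needs at least 2 specimens (PERMANOVA)",
                     "skullnet_bad_input")
    for (s in seq_len(grp$n)) {
      sid <- sprintf("%s_%02d", grp$label, s)
      sseed <- seed * 10000L + gi * 1000L + s
      set.seed(sseed)
      nf <- resample(grp$fusions[1L]:grp$fusions[2L], 1L)
      tpl <- make_template_skull(n_half = n_half, n_midline = n_midline,
                                 p_extra = p_extra, reach = reach,
                                 seed = sseed + 1L, specimen_id = sid)
      net <- if (nf > 0L) {
        traj <- simulate_fusion_trajectory(tpl, nf, bias = bias,
                                           mirror_prob = mirror_prob,
                                           seed = sseed + 2L)
        traj[[length(traj)]]
      } else tpl
      networks[[sid]] <- net
      row <- data.frame(specimen_id = sid, taxon = sid,
                        group = grp$label, stringsAsFactors = FALSE)
      for (m in names(grp$meta)) row[[m]] <- grp$meta[[m]]
      meta_rows[[sid]] <- row
    }
  }
  metadata <- do.call(rbind, meta_rows)
  rownames(metadata) <- NULL
  list(networks = networks, metadata = validate_metadata(metadata))
}

#' Write / read a cohort as a directory of adjacency CSVs
#'
#' One canonical adjacency CSV per specimen plus `metadata.csv`; an
#' optional `cohort_spec.json` records the generator call.
#'
#' @param cohort a list with `networks` and `metadata` as returned by
#'   [make_cohort()].
#' @param dir target directory (created if needed).
#' @param spec optional list written as `cohort_spec.json`.
#' @return `dir` (write) or a cohort list (read), invisibly for write.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$networks))
    write_adjacency(cohort$networks[[sid]],
                    file.path(dir, paste0(sid, ".csv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  if (!is.null(spec))
    jsonlite::write_json(spec, file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path))
    abort_skullnet("cohort directory needs a metadata.csv", "skullnet_format")
  metadata <- read_metadata(meta_path)
  networks <- lapply(metadata$specimen_id, function(sid) {
    p <- file.path(dir, paste0(sid, ".csv"))
    if (!file.exists(p))
      abort_skullnet(sprintf("missing adjacency file for specimen '%s'", sid),
                     "skullnet_format")
    read_adjacency(p, specimen_id = sid)
  })
  names(networks) <- metadata$specimen_id
  list(networks = networks, metadata = metadata)
}
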