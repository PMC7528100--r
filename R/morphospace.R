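#' Principal component analysis of topology profiles
#'
#' Column-wise centers and unit-variance scales the eight topological
#' variables (sample standard deviation, n - 1 denominator) and performs
#' a singular value decomposition. The variance fraction of PC i is
#' `sigma_i^2 / sum(sigma^2)`. A deterministic sign convention is applied:
#' within each PC, the loading of largest magnitude is made positive, so
#' scores are reproducible across linear-algebra backends and specimen
#' orderings.
#'
#' @param profiles a data frame as returned by [profiles_table()] (a
#'   `specimen_id` column plus numeric variables), or a plain numeric
#'   matrix with specimen rownames.
#' @return An object of class `morphospace`: list with `scores`
#'   (specimens x PCs), `loadings` (variables x PCs), `variance_fraction`
#'   (non-increasing, sums to 1), `center`, `scale` and `sdev`. The number
#'   of PCs is `min(n_specimens - 1, n_variables)`.
#' @export
pca_profiles <- function(profiles) {
  x <- as_profile_matrix(profiles)
  if (nrow(x) < 3L)
    abort_skullnet("PCA needs at least 3 specimens", "skullnet_bad_input")
  if (anyNA(x))
    abort_skullnet("profiles contain missing values; impute assortativity first",
                   "skullnet_bad_input")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds < 1e-12))
    abort_skullnet(sprintf("zero-variance column(s): %s — scaling undefined",
                           paste(colnames(x)[sds < 1e-12], collapse = ", ")),
                   "skullnet_zero_variance")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(nrow(x) - 1L, ncol(x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(
    scores = scores,
    loadings = loadings,
    variance_fraction = p$sdev[seq_len(k)]^2 / sum(p$sdev^2),
    center = p$center,
    scale = p$scale,
    sdev = p$sdev[seq_len(k)]), class = "morphospace")
}

as_profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.data.frame(profiles))
  num <- vapply(profiles, is.numeric, logical(1L))
  x <- as.matrix(profiles[, num, drop = FALSE])
  if ("specimen_id" %in% names(profiles))
    rownames(x) <- profiles$specimen_id
  x
}

#' @export
print.morphospace <- function(x, ...) {
  vf <- round(100 * x$variance_fraction, 1)
  cat(sprintf("<morphospace>  %d specimens, %d PCs\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA on morphospace coordinates
#'
#' Permutational multivariate analysis of variance (one factor) from a
#' Euclidean distance matrix, after Anderson: with squared distances
#' `d2`, `SS_total = sum_{i<j}(d2_ij) / n`, `SS_within =
#' sum_g sum_{i<j in g}(d2_ij) / n_g`, `SS_between = SS_total -
#' SS_within`, and `pseudo-F = (SS_between / (a - 1)) / (SS_within /
#' (n - a))`. Significance comes from unrestricted permutations of the
#' group labels: `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`. With
#' `permutations = "exact"`, all distinct label arrangements are
#' enumerated and `p` is the exact fraction with `F >= F_obs` (the
#' observed arrangement included).
#'
#' @param x specimen coordinates (matrix, e.g. the `scores` of
#'   [pca_profiles()]) or a [stats::dist] object.
#' @param labels group label per specimen; at least 2 groups, each of
#'   size >= 2.
#' @param n_perm number of label permutations (ignored in exact mode).
#' @param seed RNG seed for the permutations; `F` itself is
#'   seed-independent.
#' @param permutations `"sampled"` (default) or `"exact"` enumeration.
#' @param exact_limit refuse exact enumeration beyond this many distinct
#'   arrangements.
#' @return An object of class `permanova`: list with `F`, `df_between`
#'   (a - 1), `df_within` (n - a), `R2`, `p`, `n_perm`, `seed`, `method`.
#' @export
permanova <- function(x, labels, n_perm = 10000L, seed = NULL,
                      permutations = c("sampled", "exact"),
                      exact_limit = 1e5) {
  permutations <- match.arg(permutations)
  d2 <- if (inherits(x, "dist")) as.matrix(x)^2 else
    as.matrix(stats::dist(x))^2
  f <- factor(labels)
  n <- length(f)
  if (n != nrow(d2))
    abort_skullnet("labels length must match the number of specimens",
                   "skullnet_bad_input")
  if (nlevels(f) < 2L)
    abort_skullnet("PERMANOVA needs at least 2 groups", "skullnet_bad_input")
  if (any(table(f) < 2L))
    abort_skullnet("every group must have at least 2 members",
                   "skullnet_bad_input")
  a <- nlevels(f)
  ss_total <- sum(d2) / (2 * n)
  if (ss_total < 1e-12)
    abort_skullnet("constant distances: pseudo-F undefined",
                   "skullnet_degenerate")
  ss_within <- function(fl) {
    ssw <- 0
    for (lev in levels(fl)) {
      idx <- which(fl == lev)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ssw
  }
  fstat <- function(fl) {
    ssw <- ss_within(fl)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ssw_obs <- ss_within(f)
  f_obs <- fstat(f)
  if (permutations == "exact") {
    arr <- multiset_permutations(as.integer(f))
    if (ncol(arr) > exact_limit)
      abort_skullnet("too many arrangements for exact enumeration",
                     "skullnet_bad_input")
    f_all <- apply(arr, 2L, function(v) fstat(factor(v)))
    p <- mean(f_all >= f_obs - 1e-10)
    n_used <- ncol(arr)
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- 0L
    for (i in seq_len(n_perm))
      if (fstat(sample(f)) >= f_obs - 1e-10) count <- count + 1L
    p <- (count + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(
    F = f_obs, df_between = a - 1L, df_within = n - a,
    R2 = (ss_total - ssw_obs) / ss_total,
    p = p, n_perm = n_used, seed = seed, method = permutations),
    class = "permanova")
}

# All distinct arrangements of a label multiset, one per column.
multiset_permutations <- function(labels) {
  rec <- function(remaining) {
    if (length(remaining) == 1L) return(matrix(remaining, 1L))
    out <- list()
    for (v in sort(unique(remaining))) {
      i <- match(v, remaining)
      sub <- rec(remaining[-i])
      out[[length(out) + 1L]] <- rbind(v, sub)
    }
    do.call(cbind, out)
  }
  rec(sort(labels))
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA  F(%d,%d) = %.4f, R2 = %.4f, p = %.5g (%s, %d perms)\n",
              x$df_between, x$df_within, x$F, x$R2, x$p, x$method, x$n_perm))
  invisible(x)
}

# Built-in subsample rules. `no-birds` drops all modern birds
# (neornithes); `no-adult-birds` drops only their adults. Both need the
# metadata columns they mention.
subsample_index <- function(metadata, rule) {
  if (is.function(rule)) return(rule(metadata))
  switch(rule,
    "all" = rep(TRUE, nrow(metadata)),
    "no-birds" = {
      need_col(metadata, "neornithes", rule)
      !isTRUE_vec(metadata$neornithes)
    },
    "no-adult-birds" = {
      need_col(metadata, c("neornithes", "stage"), rule)
      !(isTRUE_vec(metadata$neornithes) & metadata$stage == "adult")
    },
    abort_skullnet(sprintf("unknown subsample rule '%s'", rule),
                   "skullnet_bad_input"))
}

need_col <- function(metadata, cols, rule) {
  miss <- setdiff(cols, names(metadata))
  if (length(miss))
    abort_skullnet(sprintf("subsample '%s' needs metadata column(s): %s",
                           rule, paste(miss, collapse = ", ")),
                   "skullnet_metadata")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Run PCA + PERMANOVA over grouping schemes and subsamples
#'
#' For each subsample the PCA is recomputed (variance fractions change
#' with the cohort) and each grouping scheme is tested with [permanova()]
#' on the PC scores. Euclidean distance on the full set of PC scores
#' equals the distance on the scaled variables themselves; `n_pcs`
#' optionally restricts the test to the first PCs.
#'
#' @param profiles a [profiles_table()] data frame (no missing values).
#' @param metadata a [validate_metadata()] data frame with one row per
#'   specimen; grouping schemes are metadata column names.
#' @param schemes character vector of metadata columns to test.
#' @param subsamples character vector of built-in rules (`"all"`,
#'   `"no-birds"`, `"no-adult-birds"`) and/or a named list of predicate
#'   functions over the metadata.
#' @param n_perm,seed passed to [permanova()]; the seed is offset per
#'   scheme/subsample so tests are independent but reproducible.
#' @param n_pcs number of leading PCs to test (`NULL` = all).
#' @return A data frame with one row per scheme x subsample: `subsample,
#'   scheme, n, n_groups, F, df_between, df_within, R2, p, n_perm, seed`.
#'   Schemes whose levels collapse after subsampling (fewer than 2 groups
#'   or a group of size < 2) are skipped with a `message()`.
#' @export
run_grouping_suite <- function(profiles, metadata, schemes,
                               subsamples = "all", n_perm = 999L,
                               seed = 1L, n_pcs = NULL) {
  metadata <- validate_metadata(metadata)
  if (!all(profiles$specimen_id %in% metadata$specimen_id))
    abort_skullnet("every profiled specimen needs a metadata row",
                   "skullnet_metadata")
  metadata <- metadata[match(profiles$specimen_id, metadata$specimen_id), ]
  if (is.character(subsamples)) {
    subsamples <- stats::setNames(as.list(subsamples), subsamples)
  }
  rows <- list()
  off <- 0L
  for (sub_name in names(subsamples)) {
    keep <- subsample_index(metadata, subsamples[[sub_name]])
    prof_s <- profiles[keep, , drop = FALSE]
    meta_s <- metadata[keep, , drop = FALSE]
    if (nrow(prof_s) < 3L) {
      message(sprintf("subsample '%s': fewer than 3 specimens; skipped",
                      sub_name))
      next
    }
    ms <- pca_profiles(prof_s)
    scores <- ms$scores
    if (!is.null(n_pcs))
      scores <- scores[, seq_len(min(n_pcs, ncol(scores))), drop = FALSE]
    for (scheme in schemes) {
      off <- off + 1L
      if (!scheme %in% names(meta_s)) {
        message(sprintf("scheme '%s' missing from metadata; skipped", scheme))
        next
      }
      lab <- meta_s[[scheme]]
      ok <- !is.na(lab)
      tab <- table(lab[ok])
      if (length(tab) < 2L || any(tab < 2L) || sum(ok) < 4L) {
        message(sprintf(
          "scheme '%s' (subsample '%s'): empty or singleton level; skipped",
          scheme, sub_name))
        next
      }
      pm <- permanova(scores[ok, , drop = FALSE], lab[ok],
                      n_perm = n_perm, seed = seed + off)
      rows[[length(rows) + 1L]] <- data.frame(
        subsample = sub_name, scheme = scheme, n = sum(ok),
        n_groups = length(tab), F = pm$F,
        df_between = pm$df_between, df_within = pm$df_within,
        R2 = pm$R2, p = pm$p, n_perm = pm$n_perm, seed = seed + off,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subsample = character(), scheme = character(),
               n = integer(), n_groups = integer(), F = numeric(),
               df_between = integer(), df_within = integer(),
               R2 = numeric(), p = numeric(), n_perm = integer(),
               seed = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
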