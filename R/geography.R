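# Latitude classification, range-overlap sympatry scoring, tree slicing for
# large clades, and sympatry downsampling.

#' Classify a breeding latitude band as tropical, temperate or both
#'
#' The tropics are the closed band between `-boundary` and `+boundary`
#' degrees latitude. A breeding range strictly inside the band is
#' `"tropical"`; a range that does not touch the band is `"temperate"`; any
#' other range (including one touching the boundary exactly) is `"both"`.
#'
#' @param lat_min,lat_max Breeding range latitudinal limits in degrees,
#'   `-90 <= lat_min <= lat_max <= 90`. Vectorized.
#' @param boundary Tropics boundary in degrees (default 23.437, the Tropic
#'   of Cancer/Capricorn).
#' @return Character vector in `{"tropical","temperate","both"}`.
#' @export
#' @examples
#' classify_latitude(-10, 5)    # "tropical"
#' classify_latitude(30, 45)    # "temperate"
#' classify_latitude(-30, 10)   # "both"
classify_latitude <- function(lat_min, lat_max, boundary = 23.437) {
  if (any(lat_min > lat_max)) stop_("lat_min must not exceed lat_max")
  if (any(lat_min < -90 | lat_max > 90)) stop_("latitudes must lie in [-90, 90]")
  ifelse(lat_min > -boundary & lat_max < boundary, "tropical",
         ifelse(lat_max < -boundary | lat_min > boundary, "temperate", "both"))
}

#' Szymkiewicz-Simpson range-overlap coefficient
#'
#' `overlap / min(area1, area2)`: 1 when the smaller range is nested inside
#' the larger, 0 for disjoint ranges. Symmetric in the two areas and
#' invariant to rescaling all areas by a common factor.
#'
#' @param overlap_area Overlap area (same units as the ranges).
#' @param area1,area2 Range areas, both `> 0`.
#' @return Coefficient in `[0, 1]`. Vectorized.
#' @export
szymkiewicz_simpson <- function(overlap_area, area1, area2) {
  if (any(area1 <= 0 | area2 <= 0)) stop_("range areas must be positive")
  m <- pmin(area1, area2)
  if (any(overlap_area < 0 | overlap_area > m * (1 + 1e-12))) {
    stop_("overlap area cannot exceed the smaller range area")
  }
  overlap_area / m
}

#' Score a pair as sympatric
#'
#' @param coefficient Szymkiewicz-Simpson coefficient(s).
#' @param threshold Overlap proportion at or above which a pair counts as
#'   sympatric (default 0.20).
#' @return Logical vector.
#' @export
is_sympatric <- function(coefficient, threshold = 0.20) {
  coefficient >= threshold
}

#' Clade-level index of tropicality
#'
#' Proportion of species with exclusively tropical breeding ranges.
#'
#' @param states Character vector of tip regimes (any states; only
#'   `"tropical"` counts).
#' @return Proportion in `[0, 1]`.
#' @export
tropicality_index <- function(states) {
  if (!length(states)) stop_("need at least one tip")
  mean(states == "tropical")
}

#' Slice a large tree into subclades below a size threshold
#'
#' Slides a cut line from the root toward the tips in small time steps
#' until every clade crossing the line has fewer than `max_tips` tips, then
#' returns those clades (each monophyletic in the input) with at least
#' `min_tips` tips. A tree already below `max_tips` is returned unchanged,
#' which makes slicing idempotent.
#'
#' @param tree Validated ultrametric `phylo`.
#' @param max_tips Clades must end up strictly below this size (default 200).
#' @param step Cut-line increment in Myr (default 0.1).
#' @param min_tips Minimum subclade size to keep (default 10).
#' @return List of `phylo` subtrees.
#' @export
slice_tree <- function(tree, max_tips = 200, step = 0.1, min_tips = 10) {
  ntip <- length(tree$tip.label)
  if (ntip < max_tips) return(list(tree))
  d <- node_depths(tree)
  T <- tree_height(tree)
  nsub <- vapply(seq_len(ntip + tree$Nnode), function(v)
    if (v <= ntip) 1L else length(ape::extract.clade(tree, v)$tip.label),
    integer(1))
  t <- 0
  repeat {
    t <- t + step
    if (t >= T) {
      cross <- seq_len(ntip)
      break
    }
    cross <- tree$edge[d[tree$edge[, 1]] <= t & d[tree$edge[, 2]] > t, 2]
    if (all(nsub[cross] < max_tips)) break
  }
  keep <- cross[nsub[cross] >= min_tips]
  lapply(keep, function(v) ape::extract.clade(tree, v))
}

#' Downsample continental sympatry
#'
#' Continental-scale occupancy overstates true sympatry; this operation
#' thins it to a target retained fraction per regime. In the default
#' lineage-level reading, for each area and regime a fraction `p` of the
#' tips occupying that area (rounded down) is retained in the area's
#' interacting set; dropped tips lose that area along their terminal
#' branch, and a tip dropped from all of its areas is moved to a private
#' singleton area (so it still occupies one area, but is sympatric with no
#' other lineage). Internal branches are untouched. With `unit = "pair"`
#' the operation instead thins edges of a tip sympatry matrix: each
#' within-regime sympatric pair is kept with probability `p` of its regime
#' (mixed pairs use the mean of the two rates).
#'
#' @param biogeo A [biogeo_history()] (for `unit = "lineage"`) or a
#'   symmetric 0/1 tip sympatry matrix with tip labels as dimnames (for
#'   `unit = "pair"`).
#' @param regimes Named character vector of tip regimes
#'   (`"tropical"`/`"temperate"`), or a [regime_history()].
#' @param p_tropical,p_temperate Retained fraction per regime, in `(0, 1]`.
#' @param seed Optional integer seed; identical seeds reproduce the
#'   downsampling exactly.
#' @param unit `"lineage"` (default) or `"pair"`.
#' @return Same class as `biogeo`: a modified history (possibly with extra
#'   private areas) or a thinned sympatry matrix.
#' @export
downsample_sympatry <- function(biogeo, regimes, p_tropical, p_temperate,
                                seed = NULL, unit = c("lineage", "pair")) {
  unit <- match.arg(unit)
  if (p_tropical <= 0 || p_temperate <= 0 || p_tropical > 1 || p_temperate > 1) {
    stop_("retained fractions must lie in (0, 1]")
  }
  if (inherits(regimes, "regime_history")) regimes <- tip_states(regimes)
  p_of <- c(tropical = p_tropical, temperate = p_temperate)
  set_seed_if(seed)

  if (unit == "pair") {
    A <- biogeo
    if (!is.matrix(A)) stop_("unit='pair' expects a tip sympatry matrix")
    tips <- rownames(A)
    reg <- regimes[tips]
    for (i in seq_len(nrow(A) - 1L)) {
      for (j in (i + 1L):nrow(A)) {
        if (A[i, j] > 0) {
          p <- mean(p_of[c(reg[i], reg[j])])
          if (stats::runif(1) > p) A[i, j] <- A[j, i] <- 0
        }
      }
    }
    return(A)
  }

  if (!inherits(biogeo, "biogeo_history")) stop_("expected a biogeo_history")
  tree <- biogeo$tree
  ntip <- length(tree$tip.label)
  e2n <- edge_to_node(tree)
  occ_raw <- vapply(seq_len(ntip), function(i) {
    segs <- biogeo$maps[[e2n[i]]]
    as.numeric(strsplit(names(segs)[length(segs)], "")[[1]] == "1")
  }, numeric(biogeo$K))
  occ_tip <- if (biogeo$K == 1L) matrix(occ_raw, ncol = 1) else t(occ_raw)
  drop_bit <- matrix(FALSE, ntip, biogeo$K)
  for (k in seq_len(biogeo$K)) {
    for (g in c("tropical", "temperate")) {
      members <- which(occ_tip[, k] > 0 & regimes[tree$tip.label] == g)
      if (!length(members)) next
      n_keep <- floor(p_of[[g]] * length(members))
      keep <- if (n_keep > 0) sample(members, n_keep) else integer(0)
      drop_bit[setdiff(members, keep), k] <- TRUE
    }
  }
  orphan <- which(vapply(seq_len(ntip), function(i)
    all(occ_tip[i, ] == 0 | drop_bit[i, ]), logical(1)))
  K_new <- biogeo$K + length(orphan)
  private <- stats::setNames(seq_along(orphan) + biogeo$K, orphan)
  maps <- biogeo$maps
  for (e in seq_along(maps)) {
    v <- tree$edge[e, 2]
    pad <- paste(rep("0", length(orphan)), collapse = "")
    segs <- maps[[e]]
    nm <- paste0(names(segs), pad)
    if (v <= ntip) {
      nm <- vapply(nm, function(pat) {
        bits <- strsplit(pat, "")[[1]]
        orig <- bits
        bits[seq_len(biogeo$K)][drop_bit[v, ]] <- "0"
        if (v %in% orphan) bits[private[[as.character(v)]]] <- "1"
        # a segment emptied by dropping (ancestral areas differing from the
        # tip-end set) keeps its original occupancy
        if (!any(bits == "1")) bits <- orig
        paste(bits, collapse = "")
      }, character(1))
    }
    maps[[e]] <- merge_adjacent(stats::setNames(unname(segs), nm))
  }
  areas <- c(biogeo$areas, if (length(orphan))
    paste0("private_", tree$tip.label[orphan]))
  biogeo_history(tree, maps, areas = areas)
}
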