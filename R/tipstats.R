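#' Normalized terminal branch lengths
#'
#' Each extant terminal branch length is divided by the mean of *all* branch
#' lengths (internal and terminal) of the extant restriction of the same
#' tree, giving a per-tree relative measure of tip length that is invariant
#' to the overall time scale.  Higher extinction fractions shorten terminal
#' branches relative to the rest of the tree, which this statistic is
#' designed to expose.
#'
#' @param tree a chronotree (a complete tree is pruned to its extant tips
#'   first unless `on_extant = FALSE`).
#' @param on_extant compute on the extant (pruned) restriction, which is what
#'   an empiricist observes (default), or on the tree as supplied.
#' @return a data.frame with columns `tip_label`, `tip_length`,
#'   `norm_tip_length`; the normalising mean branch length is attached as
#'   attribute `"mean_branch_length"`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:2,D:2):2);")
#' normalized_tip_lengths(as_chronotree(tr))
#' @export
normalized_tip_lengths <- function(tree, on_extant = TRUE) {
  if (ape::Ntip(tree) < 2) stop("tree must have >= 2 tips")
  obs <- if (on_extant && length(extinct_tips(tree)) > 0) prune_extinct(tree) else tree
  mbl <- mean(obs$edge.length)
  if (!is.finite(mbl) || mbl <= 0) stop("all branch lengths are zero")
  tip_edge <- match(seq_len(ape::Ntip(obs)), obs$edge[, 2])
  tl <- obs$edge.length[tip_edge]
  out <- data.frame(
    tip_label = obs$tip.label,
    tip_length = tl,
    norm_tip_length = tl / mbl,
    stringsAsFactors = FALSE
  )
  attr(out, "mean_branch_length") <- mbl
  out
}

#' Tip-length table for an ensemble of trees
#'
#' Convenience wrapper applying [normalized_tip_lengths()] across trees,
#' returning the long table used for extinction-rate comparisons.
#'
#' @param trees a list of chronotrees.
#' @param epsilon optional extinction fraction(s) to annotate (recycled).
#' @return long data.frame with columns `tree_id`, `epsilon`, `tip_label`,
#'   `tip_length`, `norm_tip_length`.
#' @export
tip_length_table <- function(trees, epsilon = NA_real_) {
  epsilon <- rep_len(epsilon, length(trees))
  out <- lapply(seq_along(trees), function(i) {
    df <- normalized_tip_lengths(trees[[i]])
    cbind(tree_id = i, epsilon = epsilon[i], df)
  })
  do.call(rbind, out)
}

#' Lineages-through-time curve of the extant restriction
#'
#' Exact step function of the number of ancestral lineages of the extant
#' sample against age (time before present), from the root age down to 0.
#' The slope of log(lineage count) against forward time over the most recent
#' fraction of the tree height (default: the final decile) summarises the
#' "pull of the present": it grows with the extinction fraction.
#'
#' @param tree a chronotree; its extant restriction must be ultrametric.
#' @param decile width of the recent window, as a fraction of tree height,
#'   over which the slope is estimated.
#' @return a data.frame with columns `age` (decreasing) and `lineages`
#'   (count prevailing from that age until the next row), ending at
#'   `age = 0` with the extant tip count.  Attributes: `"height"` (root age)
#'   and `"recent_slope"` (see `ltt_recent_slope()`).
#' @export
ltt_curve <- function(tree, decile = 0.1) {
  obs <- if (length(extinct_tips(tree)) > 0) prune_extinct(tree) else tree
  if (!is_ultrametric_extant(obs)) stop("extant restriction is not ultrametric")
  ntip <- ape::Ntip(obs)
  ages <- node_ages(obs)
  node_a <- sort(ages[(ntip + 1L):(ntip + obs$Nnode)], decreasing = TRUE)
  curve <- data.frame(
    age = c(node_a, 0),
    lineages = c(seq_along(node_a) + 1L, ntip)
  )
  h <- node_a[1]
  attr(curve, "height") <- h
  attr(curve, "recent_slope") <- ltt_recent_slope(curve, decile)
  curve
}

#' @rdname ltt_curve
#' @param curve an LTT curve as returned by `ltt_curve()`.
#' @return `ltt_recent_slope()`: the least-squares slope of log lineage
#'   count against *relative* forward time (tree height normalised to 1)
#'   over the recent window.  Measuring on relative time makes the statistic
#'   a pure curve-shape quantity, comparable across trees of different
#'   heights (an absolute-time slope would be dominated by the tree height,
#'   which grows steeply with the extinction fraction).
#' @export
ltt_recent_slope <- function(curve, decile = 0.1) {
  stopifnot(decile > 0, decile <= 1)
  h <- max(curve$age)
  a0 <- decile * h # window: ages in [0, a0]
  u <- (h - curve$age) / h # relative forward time in [0, 1]
  keep <- curve$age <= a0 + 1e-12
  # prevailing count at the window boundary
  before <- which(!keep)
  uu <- c(if (length(before)) 1 - decile, u[keep])
  nn <- c(if (length(before)) curve$lineages[max(before)], curve$lineages[keep])
  if (length(unique(uu)) < 2) return(NA_real_)
  unname(coef(lm(log(nn) ~ uu))[2])
}
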