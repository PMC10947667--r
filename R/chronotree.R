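#' Time-calibrated trees with extinct tips (chronotrees)
#'
#' A *chronotree* is an [ape::read.tree()]-style `phylo` object whose branch
#' lengths are in time units and whose tips carry an alive/extinct status.
#' Extinct tips are flagged by the label suffix `"@extinct"`, so a chronotree
#' survives a round trip through plain newick unchanged.  Node ages are
#' measured backward from the present, which is anchored at the extant tips
#' (all extant tips have age 0); the tree restricted to its extant tips is
#' therefore ultrametric.
#'
#' @param phy a `phylo` object with branch lengths.
#' @return `as_chronotree()` returns `phy` with class
#'   `c("chronotree", "phylo")`.
#' @seealso [simulate_complete_tree()], [prune_extinct()]
#' @export
as_chronotree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a 'phylo' object")
  if (is.null(phy$edge.length)) stop("chronotrees need branch lengths")
  if (any(phy$edge.length < -1e-9)) stop("negative branch lengths")
  class(phy) <- unique(c("chronotree", class(phy)))
  phy
}

#' @rdname as_chronotree
#' @param tree a chronotree (or any `phylo` whose extinct tips use the
#'   `"@extinct"` label convention).
#' @return `tip_status()`: a character vector (`"extant"`/`"extinct"`) named
#'   by tip label; `extant_tips()` and `extinct_tips()`: character vectors of
#'   labels.
#' @export
tip_status <- function(tree) {
  ext <- grepl("@extinct$", tree$tip.label)
  setNames(ifelse(ext, "extinct", "extant"), tree$tip.label)
}

#' @rdname as_chronotree
#' @export
extant_tips <- function(tree) tree$tip.label[!grepl("@extinct$", tree$tip.label)]

#' @rdname as_chronotree
#' @export
extinct_tips <- function(tree) tree$tip.label[grepl("@extinct$", tree$tip.label)]

#' Node ages in the extant-tip frame
#'
#' Ages are time before present for every node (tips `1..Ntip` first, then
#' internal nodes), with the present defined by the extant tips: the deepest
#' extant tip sits at age 0.  Extinct tips get positive ages.
#'
#' @param tree a chronotree.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ext <- !grepl("@extinct$", tree$tip.label)
  if (!any(ext)) stop("tree has no extant tips; ages are anchored at the present")
  present <- max(depth[seq_along(tree$tip.label)][ext])
  ages <- present - depth
  # clamp numerically tiny negatives arising from summed edge lengths
  ages[ages < 0 & ages > -1e-8] <- 0
  ages
}

#' @rdname node_ages
#' @return `origin_age()`: the age of the origin of the stem lineage (root
#'   node age plus the root edge, if any).
#' @export
origin_age <- function(tree) {
  ages <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  ages[root] + if (is.null(tree$root.edge)) 0 else tree$root.edge
}

# parent[node] = parent node id (0 for the root); internal helper
parent_vec <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  pv <- integer(n)
  pv[tree$edge[, 2]] <- tree$edge[, 1]
  pv
}

#' Is the extant restriction of a tree ultrametric?
#'
#' @param tree a chronotree.
#' @param tol absolute age tolerance.
#' @return logical.
#' @export
is_ultrametric_extant <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  ext <- !grepl("@extinct$", tree$tip.label)
  d <- depth[seq_along(tree$tip.label)][ext]
  diff(range(d)) <= tol
}

#' Read and write chronotrees
#'
#' Plain newick with branch lengths; extinct tips are recognised by the
#' `"@extinct"` label suffix.  `write_chronotree()` can also emit a sidecar
#' TSV with per-tip `lineage_id`, `age`, `status`.
#'
#' @param tree a chronotree.
#' @param file path to a newick file.
#' @param sidecar optional path for the per-tip TSV.
#' @export
write_chronotree <- function(tree, file, sidecar = NULL) {
  ape::write.tree(tree, file = file)
  if (!is.null(sidecar)) {
    ages <- node_ages(tree)
    df <- data.frame(
      lineage_id = tree$tip.label,
      age = ages[seq_along(tree$tip.label)],
      status = unname(tip_status(tree)),
      stringsAsFactors = FALSE
    )
    write.table(df, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_chronotree
#' @export
read_chronotree <- function(file) {
  as_chronotree(ape::read.tree(file))
}

#' @export
print.chronotree <- function(x, ...) {
  ne <- length(extant_tips(x))
  nx <- length(extinct_tips(x))
  cat(sprintf(
    "Chronotree: %d tips (%d extant, %d extinct), origin age %.4g\n",
    ape::Ntip(x), ne, nx, origin_age(x)
  ))
  invisible(x)
}
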