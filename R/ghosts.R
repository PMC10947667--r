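#' Taxon sampling schemes
#'
#' Governs incomplete taxon sampling: a uniformly random subset of extant
#' taxa of size `round(keep_fraction * n)` (half-up, never below the minimum
#' implied by the constraints) is retained.  Draws violating the constraints
#' (a measurable recipient crown needs at least `min_recipient_kept` recipient
#' tips; an apparent donor needs at least `min_donor_side_kept` non-recipient
#' tips) are re-drawn, up to `retry_cap` times.
#'
#' @param keep_fraction fraction of extant taxa to retain, in (0, 1].
#' @param min_recipient_kept minimum recipient tips retained (>= 2; a crown
#'   must exist for a stem to be measured).
#' @param min_donor_side_kept minimum non-recipient tips retained (>= 1).
#' @param mode `"uniform"`: sample uniformly over all extant taxa (default);
#'   `"donor_side"`: keep all recipient taxa and subsample only the
#'   non-recipient (donor-side) taxa.
#' @param retry_cap maximum constraint-violating draws before erroring.
#' @return an object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(keep_fraction, min_recipient_kept = 2,
                            min_donor_side_kept = 1,
                            mode = c("uniform", "donor_side"),
                            retry_cap = 10000) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1,
            min_recipient_kept >= 2, min_donor_side_kept >= 1)
  structure(list(keep_fraction = keep_fraction,
                 min_recipient_kept = as.integer(min_recipient_kept),
                 min_donor_side_kept = as.integer(min_donor_side_kept),
                 mode = match.arg(mode),
                 retry_cap = retry_cap),
            class = "sampling_scheme")
}

round_half_up <- function(x) floor(x + 0.5)

# draw the retained labels (no pruning); shared by subsample_taxa() and the
# sweep's fast path so both consume the RNG stream identically
pick_retained_taxa <- function(labels, scheme, recipient_taxa = character()) {
  n <- length(labels)
  is_rec <- labels %in% recipient_taxa
  n_rec <- sum(is_rec)
  need_rec <- if (n_rec > 0) scheme$min_recipient_kept else 0L
  need_don <- scheme$min_donor_side_kept
  if (n_rec > 0 && n_rec < need_rec)
    stop("constraints unsatisfiable: only ", n_rec, " recipient taxa present")
  if (n - n_rec < need_don)
    stop("constraints unsatisfiable: only ", n - n_rec, " donor-side taxa present")
  if (scheme$mode == "donor_side") {
    k <- max(round_half_up(scheme$keep_fraction * (n - n_rec)), need_don)
    keep_d <- which(!is_rec)[sample.int(n - n_rec, k)]
    return(sort(labels[c(which(is_rec), keep_d)]))
  }
  k <- max(round_half_up(scheme$keep_fraction * n), need_rec + need_don, 1L)
  if (k > n) k <- n
  tries <- 0L
  repeat {
    idx <- sample.int(n, k)
    nr <- sum(is_rec[idx])
    if (nr >= need_rec && (k - nr) >= need_don) return(sort(labels[idx]))
    tries <- tries + 1L
    if (tries > scheme$retry_cap)
      stop("retry cap exceeded while drawing a constrained taxon subsample")
  }
}

#' Subsample extant taxa
#'
#' Retains a uniformly random subset of tips according to a
#' [sampling_scheme()] and returns the induced tree, with unifurcations
#' suppressed and branch lengths summed, so that all pairwise path lengths
#' among retained tips are preserved exactly.
#'
#' @param tree an extant-only chronotree.
#' @param scheme a [sampling_scheme()].
#' @param recipient_taxa labels of the recipient clade (for the minimum-kept
#'   constraints); may be empty when no recipient is designated.
#' @return the subsampled chronotree; the retained labels are attached as
#'   attribute `"retained"`.
#' @export
subsample_taxa <- function(tree, scheme, recipient_taxa = character()) {
  stopifnot(inherits(scheme, "sampling_scheme"))
  if (length(extinct_tips(tree)) > 0)
    stop("subsampling operates on extant-only trees; call prune_extinct() first")
  keep <- pick_retained_taxa(tree$tip.label, scheme, recipient_taxa)
  out <- if (length(keep) == ape::Ntip(tree)) {
    tree
  } else {
    as_chronotree(ape::keep.tip(tree, keep))
  }
  attr(out, "retained") <- keep
  out
}

#' Apparent donor of a transferred gene family
#'
#' In an observed (pruned and subsampled) gene tree, the apparent acquisition
#' point of the recipient clade is the node where it attaches to the rest of
#' the tree: the common ancestor it shares with its sister group.  Ghost
#' lineages can only push this attachment deeper, so the apparent divergence
#' age is always >= the true transfer age.
#'
#' @param tree an observed gene chronotree.
#' @param recipient_taxa labels of the recipient clade present in `tree`
#'   (>= 2 of them, and at least 1 non-recipient tip).
#' @return list with `sister_taxa` (labels), `divergence_age` (age of the
#'   recipient clade's attachment node) and `crown_age` (age of the recipient
#'   crown).
#' @export
inferred_donor <- function(tree, recipient_taxa) {
  recipient_taxa <- intersect(tree$tip.label, recipient_taxa)
  if (length(recipient_taxa) < 2)
    stop("need >= 2 recipient taxa in the observed tree")
  others <- setdiff(tree$tip.label, recipient_taxa)
  if (length(others) < 1) stop("need >= 1 non-recipient taxon")
  if (!ape::is.monophyletic(tree, recipient_taxa))
    stop("recipient taxa are not monophyletic in the observed tree (corrupted input?)")
  ages <- node_ages(tree)
  mrca <- ape::getMRCA(tree, recipient_taxa)
  parent <- tree$edge[match(mrca, tree$edge[, 2]), 1]
  if (is.na(parent))
    stop("recipient clade attaches at the root; no sister group observable")
  sister_all <- ape::extract.clade(tree, parent)$tip.label
  list(sister_taxa = setdiff(sister_all, recipient_taxa),
       divergence_age = ages[parent],
       crown_age = ages[mrca])
}
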