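#' Transfer events
#'
#' A horizontal transfer event is a donor lineage (identified by the node at
#' the lower, more recent end of the donating branch; the root node denotes
#' the origin-to-root stem branch) together with a transfer age `tau` (time
#' before present).  The donor branch must span `tau`.
#'
#' @param donor_lineage integer node id of the branch's child end.
#' @param tau transfer age, > 0.
#' @param recipient_id identifier for the recipient stem.
#' @return an object of class `transfer_event`.
#' @export
transfer_event <- function(donor_lineage, tau, recipient_id = "recipient") {
  stopifnot(length(donor_lineage) == 1, length(tau) == 1, tau > 0)
  structure(list(donor_lineage = as.integer(donor_lineage), tau = tau,
                 recipient_id = recipient_id),
            class = "transfer_event")
}

#' Branches alive at a given age
#'
#' @param tree a chronotree.
#' @param tau age (time before present).
#' @param ages optional precomputed [node_ages()] vector.
#' @return integer vector of node ids (child ends) of the branches spanning
#'   `tau`; the root node id denotes the origin stem when it spans `tau`.
#' @export
branches_spanning <- function(tree, tau, ages = node_ages(tree)) {
  root <- ape::Ntip(tree) + 1L
  child <- tree$edge[, 2]
  sp <- child[ages[tree$edge[, 1]] > tau & ages[child] < tau]
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  if (re > 0 && ages[root] < tau && tau < ages[root] + re) sp <- c(sp, root)
  sort(as.integer(sp))
}

#' Sample a donor lineage uniformly among branches alive at an age
#'
#' @param tree a chronotree (the species tree).
#' @param tau transfer age; must be younger than the origin.
#' @param exclude node ids never to choose (e.g. a designated recipient stem
#'   and its descendants).
#' @param ages optional precomputed [node_ages()] vector.
#' @return integer node id of the chosen branch (child end).
#' @export
sample_donor <- function(tree, tau, exclude = integer(), ages = node_ages(tree)) {
  if (tau >= origin_age(tree)) stop("tau is older than the origin of the tree")
  elig <- setdiff(branches_spanning(tree, tau, ages), exclude)
  if (length(elig) == 0) stop("no eligible branch spans tau = ", tau)
  elig[sample.int(length(elig), 1L)]
}

#' Simulate a recipient clade
#'
#' The recipient (the clade that acquires the transferred genes) is an
#' independent complete birth-death subtree, optionally rescaled so that its
#' crown age matches a prescribed value on the species-tree time scale.
#'
#' @param params a [bd_params()] object for the recipient clade.
#' @param crown_age optional target crown age; all branch lengths are scaled
#'   by `crown_age / (simulated crown age)`.
#' @param label_prefix tip label prefix (default `"r"`, keeping recipient
#'   labels disjoint from the species tree's `"t"` prefix).
#' @return a chronotree.
#' @export
simulate_recipient_clade <- function(params, crown_age = NULL, label_prefix = "r") {
  tr <- simulate_complete_tree(params, label_prefix = label_prefix)
  if (!is.null(crown_age)) {
    stopifnot(crown_age > 0)
    crown <- node_ages(tr)[ape::Ntip(tr) + 1L]
    f <- crown_age / crown
    tr$edge.length <- tr$edge.length * f
    if (!is.null(tr$root.edge)) tr$root.edge <- tr$root.edge * f
  }
  tr
}

#' Build the gene tree implied by a transfer event
#'
#' The gene tree of a transferred gene family is the species tree with a new
#' node of age `tau` inserted on the donor branch, from which the recipient
#' clade (crown age < `tau`) hangs; all other branch lengths are inherited
#' from the species tree.  The true acquisition stem length in the complete
#' (unpruned) gene tree is `tau` minus the recipient crown age.
#'
#' @param species a complete species chronotree.
#' @param recipient the recipient chronotree (see
#'   [simulate_recipient_clade()]); its tip labels must be disjoint from the
#'   species tree's.
#' @param event a [transfer_event()] whose donor branch spans `event$tau`.
#' @param period optional `c(P0, P1)` recipient stem interval (oldest,
#'   youngest) recorded with the scenario.
#' @return an object of class `gene_tree_scenario`: a list with elements
#'   `gene_tree` (chronotree), `recipient_taxa`, `event`, `true_stem`,
#'   `recipient_crown_age`, `period`.
#' @examples
#' sp <- as_chronotree(ape::read.tree(text = "((D1:2,D2:2):1,O:3);"))
#' rec <- as_chronotree(ape::read.tree(text = "(E1:0.5,E2:0.5);"))
#' sc <- build_gene_tree(sp, rec, transfer_event(1, tau = 1))
#' sc$true_stem # 0.5
#' @export
build_gene_tree <- function(species, recipient, event, period = NULL) {
  stopifnot(inherits(event, "transfer_event"))
  tau <- event$tau
  donor <- event$donor_lineage
  ages <- node_ages(species)
  root <- ape::Ntip(species) + 1L
  if (any(recipient$tip.label %in% species$tip.label))
    stop("recipient and species tip labels must be disjoint")
  crown <- node_ages(recipient)[ape::Ntip(recipient) + 1L]
  if (crown >= tau)
    stop("recipient crown age (", signif(crown, 6),
         ") must be strictly younger than tau (", signif(tau, 6), ")")
  if (!donor %in% branches_spanning(species, tau, ages))
    stop("donor branch does not span tau")

  y <- recipient
  y$root.edge <- tau - crown
  x <- species
  pos <- tau - ages[donor]
  gt <- ape::bind.tree(x, y, where = donor, position = pos)
  gt <- as_chronotree(gt)
  structure(
    list(gene_tree = gt,
         recipient_taxa = recipient$tip.label,
         event = event,
         true_stem = tau - crown,
         recipient_crown_age = crown,
         period = period),
    class = "gene_tree_scenario"
  )
}

#' @export
print.gene_tree_scenario <- function(x, ...) {
  cat(sprintf(
    "Gene-tree scenario: transfer at age %.4g onto node %d; %d recipient taxa; true stem %.4g\n",
    x$event$tau, x$event$donor_lineage, length(x$recipient_taxa), x$true_stem
  ))
  invisible(x)
}

#' Draw an ordered pair of transfer events into a shared recipient stem
#'
#' Two transfer ages are drawn uniformly within the recipient stem interval
#' (`period`), re-drawn if coincident, and ordered so the first event is the
#' earlier (older) one; a donor branch alive at each age is chosen uniformly
#' at random.
#'
#' @param species a complete species chronotree.
#' @param period `c(P0, P1)`: oldest and youngest admissible transfer age
#'   (the FECA-to-LECA analog).
#' @param exclude node ids excluded from donor sampling.
#' @param ages optional precomputed [node_ages()] vector.
#' @return list with `tau_early`, `tau_late`, `donor_early`, `donor_late`.
#' @export
draw_transfer_pair <- function(species, period, exclude = integer(),
                               ages = node_ages(species)) {
  stopifnot(length(period) == 2, period[1] > period[2])
  repeat {
    taus <- runif(2, min = period[2], max = period[1])
    if (taus[1] != taus[2]) break
  }
  taus <- sort(taus, decreasing = TRUE)
  list(tau_early = taus[1], tau_late = taus[2],
       donor_early = sample_donor(species, taus[1], exclude, ages),
       donor_late = sample_donor(species, taus[2], exclude, ages))
}
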