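#' Birth-death simulation parameters
#'
#' The process is parameterised by the speciation rate `lambda` (events per
#' lineage per time unit) and the extinction fraction `epsilon` = mu/lambda
#' (turnover), from which the extinction rate mu = `epsilon * lambda` is
#' derived.  Time is conventionally rescaled so that `lambda = 1`; an
#' absolute extinction rate can be selected instead via `mu`, which overrides
#' `epsilon`.
#'
#' @param lambda speciation rate, > 0.
#' @param epsilon extinction fraction mu/lambda, in `[0, 1)`.
#' @param n_extant_target number of extant tips at which the simulation halts
#'   (>= 2).
#' @param seed optional integer seed; if non-`NULL`, `set.seed(seed)` is
#'   called by [simulate_complete_tree()] before simulating.
#' @param mu optional absolute extinction rate; overrides `epsilon`.
#' @return an object of class `bd_params`.
#' @export
bd_params <- function(lambda = 1, epsilon = 0, n_extant_target = 100,
                      seed = NULL, mu = NULL) {
  if (!is.null(mu)) {
    if (mu < 0) stop("mu must be >= 0")
    epsilon <- mu / lambda
  }
  if (length(lambda) != 1 || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a single positive number")
  if (length(epsilon) != 1 || !is.finite(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("epsilon must be in [0, 1)")
  n_extant_target <- as.integer(n_extant_target)
  if (is.na(n_extant_target) || n_extant_target < 2)
    stop("n_extant_target must be an integer >= 2")
  structure(
    list(lambda = lambda, epsilon = epsilon, mu = epsilon * lambda,
         n_extant_target = n_extant_target, seed = seed),
    class = "bd_params"
  )
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("Birth-death parameters: lambda = %g, epsilon = %g (mu = %g), target %d extant tips\n",
              x$lambda, x$epsilon, x$mu, x$n_extant_target))
  invisible(x)
}

# Convert the lineage table returned by the C++ core (budding representation)
# into a chronotree.  Lineage ids are assigned in birth order, so for each
# parent its children appear in birth order; the internal (bifurcation) node
# created by the birth of lineage k >= 2 is numbered n + k - 1, which makes
# the earliest birth (lineage 2) the root node n + 1 as phylo requires.
lineage_table_to_tree <- function(tab, label_prefix = "t") {
  n <- tab$n_lineages
  if (n < 2) stop("degenerate simulation: fewer than 2 lineages")
  p <- tab$parent
  b <- tab$btime
  e <- ifelse(is.na(tab$dtime), tab$t_end, tab$dtime) # end time of each lineage

  kid <- 2:n
  par <- p[kid]
  ord <- order(par, kid) # kids sorted by parent, then birth order
  kid_o <- kid[ord]
  par_o <- par[ord]
  m <- length(kid_o)
  first <- c(TRUE, par_o[-1] != par_o[-m])
  last <- c(first[-1], TRUE)
  prev_kid <- c(NA_integer_, kid_o[-m])

  node_of <- function(k) n + k - 1L # internal node at the birth of lineage k

  # chain edges: the edge ending at node_of(k), running along the parent's
  # timeline from the previous event on that lineage (or the lineage's own
  # birth node).  The very first birth on lineage 1 is the root: no edge.
  from_chain <- ifelse(first, node_of(par_o), node_of(prev_kid))
  t_from <- ifelse(first, b[par_o], b[prev_kid])
  len_chain <- b[kid_o] - t_from
  drop_root <- first & par_o == 1L
  from_chain <- from_chain[!drop_root]
  to_chain <- node_of(kid_o)[!drop_root]
  len_chain <- len_chain[!drop_root]

  # tip edges: from the last event on each lineage (or its birth node, if
  # childless) to its tip.
  last_kid_of <- rep(NA_integer_, n)
  last_kid_of[par_o[last]] <- kid_o[last]
  has_kids <- !is.na(last_kid_of)
  from_tip <- ifelse(has_kids, node_of(last_kid_of), node_of(seq_len(n)))
  t_from_tip <- ifelse(has_kids, b[last_kid_of], b)
  len_tip <- e - t_from_tip

  edge <- cbind(c(from_chain, from_tip), c(to_chain, seq_len(n)))
  storage.mode(edge) <- "integer"
  extinct <- !is.na(tab$dtime)
  phy <- structure(
    list(edge = edge,
         edge.length = c(len_chain, len_tip),
         tip.label = paste0(label_prefix, seq_len(n),
                            ifelse(extinct, "@extinct", "")),
         Nnode = n - 1L,
         root.edge = b[2L]),
    class = "phylo", order = "cladewise"
  )
  phy <- ape::reorder.phylo(phy, "cladewise")
  as_chronotree(phy)
}

#' Simulate a complete birth-death species tree
#'
#' Event-by-event (Gillespie) simulation from a single stem lineage at the
#' origin, halted at the first instant the number of alive lineages reaches
#' `params$n_extant_target`.  Extinct lineages are retained as extinct tips
#' (label suffix `"@extinct"`); runs that go completely extinct before
#' reaching the target are discarded and re-drawn, up to `retry_cap`
#' attempts.  The number of discarded attempts is recorded in the
#' `"retries"` attribute of the result.
#'
#' @param params a [bd_params()] object.
#' @param label_prefix prefix for tip labels (tips are numbered in birth
#'   order).
#' @param retry_cap maximum number of fully-extinct runs discarded before
#'   giving up (a cap hit signals `epsilon` too close to 1 for the target
#'   size).
#' @param max_lineages safety cap on the total lineage count per attempt.
#' @return a chronotree with exactly `params$n_extant_target` extant tips.
#' @examples
#' tr <- simulate_complete_tree(bd_params(epsilon = 0.5, n_extant_target = 50, seed = 1))
#' tr
#' @export
simulate_complete_tree <- function(params, label_prefix = "t",
                                   retry_cap = 10000, max_lineages = 2e6) {
  stopifnot(inherits(params, "bd_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  retries <- 0L
  repeat {
    tab <- .bd_gillespie(params$lambda, params$mu, params$n_extant_target,
                         -1, as.integer(max_lineages))
    if (tab$n_alive == params$n_extant_target) break
    retries <- retries + 1L
    if (retries > retry_cap)
      stop("retry cap exceeded: all ", retry_cap,
           " attempts went extinct (epsilon too close to 1 for this target?)")
  }
  tree <- lineage_table_to_tree(tab, label_prefix)
  attr(tree, "retries") <- retries
  attr(tree, "bd_params") <- params
  tree
}

# time-stopped variant used for diagnostics and theory checks: returns the
# raw lineage table (possibly fully extinct) at absolute time t_max
simulate_bd_time <- function(lambda, epsilon, t_max, max_lineages = 2e6) {
  .bd_gillespie(lambda, epsilon * lambda, -1L, t_max, as.integer(max_lineages))
}

#' Prune extinct lineages
#'
#' Restricts a complete tree to its extant tips, suppressing unifurcations
#' (their branch lengths are summed), so that all pairwise path lengths among
#' extant tips are preserved exactly.  The result is ultrametric.
#'
#' @param tree a chronotree with at least 2 extant tips.
#' @return a chronotree containing only the extant tips.
#' @export
prune_extinct <- function(tree) {
  ext <- extinct_tips(tree)
  keep <- extant_tips(tree)
  if (length(keep) < 2) stop("fewer than 2 extant tips")
  if (length(ext) == 0) return(as_chronotree(tree))
  as_chronotree(ape::drop.tip(tree, ext, collapse.singles = TRUE))
}
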