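#' Relative-timing statistics for an observed gene tree
#'
#' The acquisition stem length `s` is the apparent divergence age of the
#' recipient clade (the age of the node where it attaches to its sister
#' group) minus the recipient crown age, both read from the observed gene
#' tree.  The branch-length ratio `r` divides `s` by the median branch
#' length (internal and terminal, excluding the stem itself) within the
#' observed recipient clade, giving a relative timing measure.  Under the
#' branch-length reading, a larger statistic means an earlier transfer.
#'
#' @param tree an observed gene chronotree (pruned/subsampled).
#' @param recipient_taxa labels of the recipient clade (>= 2 retained).
#' @param scenario_id optional identifier carried through.
#' @return an object of class `timing_call`: list with `scenario_id`, `s`,
#'   `r` (`NA` and flagged via `r_defined` when the recipient clade has no
#'   comparison branches), `divergence_age`, `crown_age`, `sister_taxa`.
#' @examples
#' gt <- ape::read.tree(text = "(((D1:1,(E1:0.5,E2:0.5):0.5):1,D2:2):1,O:3);")
#' timing_call(as_chronotree(gt), c("E1", "E2"))
#' @export
timing_call <- function(tree, recipient_taxa, scenario_id = NA) {
  inf <- inferred_donor(tree, recipient_taxa)
  s <- inf$divergence_age - inf$crown_age
  mrca <- ape::getMRCA(tree, intersect(tree$tip.label, recipient_taxa))
  clade <- ape::extract.clade(tree, mrca)
  bl <- clade$edge.length
  r_defined <- length(bl) >= 1
  r <- if (r_defined && median(bl) > 0) s / median(bl) else NA_real_
  structure(
    list(scenario_id = scenario_id, s = s, r = r,
         r_defined = r_defined && !is.na(r),
         divergence_age = inf$divergence_age, crown_age = inf$crown_age,
         sister_taxa = inf$sister_taxa),
    class = "timing_call"
  )
}

#' @export
print.timing_call <- function(x, ...) {
  cat(sprintf("Timing call: stem s = %.4g, ratio r = %.4g (divergence %.4g, crown %.4g)\n",
              x$s, x$r, x$divergence_age, x$crown_age))
  invisible(x)
}

#' Relative order of two timing calls
#'
#' Under the branch-length reading a larger statistic means an earlier
#' transfer.
#'
#' @param call_A,call_B [timing_call()] objects.
#' @param criterion order by raw stem length `"stem"` (default) or by the
#'   branch-length ratio `"ratio"`.
#' @return `"A_earlier"`, `"B_earlier"`, or `"tie"`.
#' @export
relative_order <- function(call_A, call_B, criterion = c("stem", "ratio")) {
  criterion <- match.arg(criterion)
  a <- if (criterion == "stem") call_A$s else call_A$r
  b <- if (criterion == "stem") call_B$s else call_B$r
  if (is.na(a) || is.na(b)) stop("criterion undefined for one of the calls")
  if (a > b) "A_earlier" else if (b > a) "B_earlier" else "tie"
}

#' Classify a called order against the true order
#'
#' A call is incorrect when it reverses the true transfer order; ties are
#' counted as incorrect under the (conservative) default policy.
#'
#' @param true_order `"A_earlier"` or `"B_earlier"` (from the true transfer
#'   ages).
#' @param called_order `"A_earlier"`, `"B_earlier"`, or `"tie"` (from
#'   [relative_order()]).
#' @param tie_policy how to score a tied call.
#' @return `"correct"` or `"incorrect"`.
#' @export
classify_shift <- function(true_order, called_order,
                           tie_policy = c("incorrect", "correct")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(true_order %in% c("A_earlier", "B_earlier"),
            called_order %in% c("A_earlier", "B_earlier", "tie"))
  if (called_order == "tie") {
    if (tie_policy == "incorrect") "incorrect" else "correct"
  } else if (called_order == true_order) "correct" else "incorrect"
}

#' Two-ghost scenarios and the analytic shift conditions
#'
#' A ghost scenario abstracts a pair of transfers into a recipient stem whose
#' true donors are ghosts: for each ghost `g`, `d[g]` is the age at which it
#' diverged from its closest sampled relative and `tau[g]` the age of its
#' transfer (`d[g] >= tau[g]`: a lineage must exist before it transfers).
#' `period = c(P0, P1)` is the recipient stem interval (oldest, youngest) --
#' the FECA-to-LECA analog.
#'
#' @param period numeric `c(P0, P1)` with `P0 > P1 >= 0`.
#' @param d divergence ages of the two ghosts from their sampled relatives.
#' @param tau transfer ages of the two ghosts.
#' @return an object of class `ghost_scenario`.
#' @export
ghost_scenario <- function(period, d, tau) {
  stopifnot(length(period) == 2, length(d) == 2, length(tau) == 2)
  if (!(period[1] > period[2]) || period[2] < 0)
    stop("period must satisfy P0 > P1 >= 0")
  if (any(d <= 0) || any(tau <= 0)) stop("ages must be positive")
  if (any(d < tau)) stop("invalid scenario: d[g] < tau[g] (a lineage must exist before it transfers)")
  structure(list(period = period, d = d, tau = tau), class = "ghost_scenario")
}

#' Can these ghosts induce a timing shift?
#'
#' Labelling the two ghosts by their transfer order (the *early* ghost
#' transferred at the older age), a shift -- the inferred order of the two
#' acquisitions reversing the true order -- is observable iff all of:
#' (a) both ghost divergences lie inside the recipient stem period;
#' (b) the ghost that transferred later diverged before (deeper than) the
#' ghost that transferred earlier; and (c) equivalently, the earlier-diverging
#' ghost transferred after the later-diverging one.  Conditions (b) and (c)
#' jointly say the divergence order is the reverse of the transfer order.
#'
#' @param sc a [ghost_scenario()].
#' @return logical; attribute `"failed"` lists the labels of failed
#'   conditions (`"a"`, `"bc"`) when `FALSE`.
#' @examples
#' shift_possible(ghost_scenario(c(1, 0), d = c(0.9, 0.5), tau = c(0.3, 0.4)))
#' @export
shift_possible <- function(sc) {
  stopifnot(inherits(sc, "ghost_scenario"))
  if (sc$tau[1] == sc$tau[2]) stop("transfer ages must be distinct")
  early <- which.max(sc$tau) # transferred first (older tau)
  late <- if (early == 1L) 2L else 1L
  failed <- character()
  in_period <- sc$d <= sc$period[1] & sc$d >= sc$period[2]
  if (!all(in_period)) failed <- c(failed, "a")
  # reversal: the late-transferring ghost diverged strictly deeper
  if (!(sc$d[late] > sc$d[early])) failed <- c(failed, "bc")
  structure(length(failed) == 0, failed = failed)
}
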