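# Independent oracles used across the test suite.  These deliberately avoid
# the package's own code paths.

# Brute-force pure-R event-by-event birth-death simulation (budding
# representation), halted at the first instant the alive count reaches
# n_target; returns NULL on total extinction.  Independent of the compiled
# simulation core.
r_gillespie <- function(lambda, mu, n_target) {
  parent <- 0L; btime <- 0; dtime <- NA_real_
  alive <- 1L
  t <- 0
  rate <- lambda + mu
  repeat {
    if (length(alive) == 0L) return(NULL)
    if (length(alive) == n_target) break
    t <- t + rexp(1L, rate * length(alive))
    k <- sample.int(length(alive), 1L)
    if (runif(1L) < lambda / rate) {
      parent <- c(parent, alive[k])
      btime <- c(btime, t)
      dtime <- c(dtime, NA_real_)
      alive <- c(alive, length(parent))
    } else {
      dtime[alive[k]] <- t
      alive <- alive[-k]
    }
  }
  list(parent = parent, btime = btime, dtime = dtime, t_end = t,
       n_lineages = length(parent))
}

# Explicit tiny-tree oracle for the two-ghost shift calculus.  For each
# ghost: sister S diverges from the ghost at age d; the recipient pair
# (E1,E2) with crown age cr attaches to the ghost branch at age tau; the
# ghost tip G is then dropped (it is the ghost) and the apparent stem is
# read off the observed tree.  A shift is observed iff the order of the two
# observed stems strictly reverses the true transfer order.
ghost_pair_tree <- function(d, tau, cr) {
  txt <- sprintf("(S:%g,((E1:%g,E2:%g):%g,G:%g):%g);",
                 d, cr, cr, tau - cr, tau, d - tau)
  ape::read.tree(text = txt)
}

shift_oracle <- function(d1, tau1, d2, tau2, cr = 0.05) {
  obs_stem <- function(d, tau) {
    tr <- ghost_pair_tree(d, tau, cr)
    obs <- ape::drop.tip(tr, "G")
    inf <- inferred_donor(as_chronotree(obs), c("E1", "E2"))
    inf$divergence_age - inf$crown_age
  }
  s1 <- obs_stem(d1, tau1)
  s2 <- obs_stem(d2, tau2)
  # true earlier event = larger tau; called earlier = larger stem
  if (tau1 > tau2) s2 > s1 + 1e-12 else s1 > s2 + 1e-12
}

# deterministic little ultrametric tree with a 5-branch cross-section at age 2
five_branch_tree <- function() {
  as_chronotree(ape::read.tree(
    text = "(A:4,(B:3.5,(C:3.2,(D:3.1,E:3.1):0.1):0.3):0.5);"))
}

worked_species <- function() {
  as_chronotree(ape::read.tree(text = "((D1:2,D2:2):1,O:3);"))
}
worked_recipient <- function() {
  as_chronotree(ape::read.tree(text = "(E1:0.5,E2:0.5);"))
}
worked_gene_tree <- function() {
  sp <- worked_species()
  build_gene_tree(sp, worked_recipient(),
                  transfer_event(which(sp$tip.label == "D1"), tau = 1))
}

cophen_extant <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  keep <- extant_tips(tree)
  d[keep, keep, drop = FALSE]
}
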