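#' Apparent divergence age of a grafted recipient, read off the complete tree
#'
#' For a transfer at age `tau` onto the donor branch (child end `donor`), the
#' observed gene tree attaches the recipient clade at the most recent point
#' where the donor lineage's ancestry coalesces with the sampled taxa.  This
#' computes that age directly on the complete species tree, without
#' constructing the gene tree: it is `tau` when any retained tip descends
#' from the donor branch, and otherwise the youngest common-ancestor age
#' between the donor branch and a retained tip.
#'
#' @param tree the complete species chronotree.
#' @param donor donor branch (child-end node id; the root node denotes the
#'   origin stem).
#' @param tau transfer age spanned by the donor branch.
#' @param retained labels of the retained (sampled) non-recipient tips.
#' @param pv,ages optional precomputed parent vector (`parent[node]`, 0 at
#'   the root) and [node_ages()] values.
#' @return the apparent divergence age (>= `tau` always).
#' @export
apparent_divergence_age <- function(tree, donor, tau, retained,
                                    pv = parent_vec(tree),
                                    ages = node_ages(tree)) {
  root <- ape::Ntip(tree) + 1L
  if (donor == root) return(tau) # stem donor: everything descends from it
  markv <- rep(NA_real_, length(ages))
  node <- donor
  markv[node] <- tau
  while (pv[node] != 0L) {
    node <- pv[node]
    markv[node] <- ages[node]
  }
  tip_ids <- match(retained, tree$tip.label)
  if (anyNA(tip_ids)) stop("some retained labels are not tips of the tree")
  best <- Inf
  for (x in tip_ids) {
    cur <- x
    while (is.na(markv[cur])) cur <- pv[cur]
    if (markv[cur] < best) best <- markv[cur]
  }
  best
}

# age of the MRCA of a set of tips, by ancestor-chain walks
mrca_age <- function(pv, ages, tip_ids) {
  cur <- tip_ids[1]
  chain <- cur
  while (pv[cur] != 0L) { cur <- pv[cur]; chain <- c(chain, cur) }
  top <- tip_ids[1]
  for (x in tip_ids[-1]) {
    cur <- x
    while (!(cur %in% chain)) cur <- pv[cur]
    # truncate the chain at the meeting point so later tips meet at or above
    chain <- chain[which(chain == cur):length(chain)]
  }
  ages[chain[1]]
}

#' Evaluate one two-transfer scenario
#'
#' Scores whether the observed relative order of two transfers into a shared
#' recipient clade matches their true order, under a given retained taxon
#' set.  Two routes are provided: `"fast"` reads the apparent divergence
#' ages directly off the complete species tree
#' ([apparent_divergence_age()]); `"genetree"` explicitly builds both
#' complete gene trees ([build_gene_tree()]), prunes them to the retained
#' taxa, and measures the stems with [timing_call()].  The two routes give
#' identical calls and are cross-checked in the test suite.
#'
#' @param species complete species chronotree.
#' @param recipient recipient chronotree (tip labels disjoint from
#'   `species`).
#' @param tau_early,tau_late true transfer ages, `tau_early > tau_late`.
#' @param donor_early,donor_late donor branches (child-end node ids) spanning
#'   the respective ages.
#' @param retained retained (sampled) extant tip labels, spanning >= 2
#'   recipient and >= 1 non-recipient tips.
#' @param method `"fast"` or `"genetree"`.
#' @return list with `d_early`, `d_late` (apparent divergence ages),
#'   `crown_obs` (observed recipient crown age), `s_early`, `s_late`
#'   (observed stems), `called` (`"A_earlier"`/`"B_earlier"`/`"tie"`, with A
#'   the true early event), `result` (`"correct"`/`"incorrect"`) and `tie`.
#' @export
evaluate_event_pair <- function(species, recipient, tau_early, tau_late,
                                donor_early, donor_late, retained,
                                method = c("fast", "genetree")) {
  method <- match.arg(method)
  stopifnot(tau_early > tau_late)
  rec_keep <- intersect(retained, recipient$tip.label)
  don_keep <- intersect(retained, species$tip.label)
  if (length(rec_keep) < 2 || length(don_keep) < 1)
    stop("retained set must keep >= 2 recipient and >= 1 donor-side tips")

  if (method == "fast") {
    pv <- parent_vec(species); ages <- node_ages(species)
    d_e <- apparent_divergence_age(species, donor_early, tau_early, don_keep, pv, ages)
    d_l <- apparent_divergence_age(species, donor_late, tau_late, don_keep, pv, ages)
    rpv <- parent_vec(recipient); rages <- node_ages(recipient)
    crown_obs <- mrca_age(rpv, rages, match(rec_keep, recipient$tip.label))
    s_e <- d_e - crown_obs
    s_l <- d_l - crown_obs
  } else {
    obs_stem <- function(donor, tau) {
      sc <- build_gene_tree(species, recipient, transfer_event(donor, tau))
      obs <- as_chronotree(ape::keep.tip(sc$gene_tree, retained))
      timing_call(obs, rec_keep)
    }
    tc_e <- obs_stem(donor_early, tau_early)
    tc_l <- obs_stem(donor_late, tau_late)
    d_e <- tc_e$divergence_age; d_l <- tc_l$divergence_age
    crown_obs <- tc_e$crown_age
    s_e <- tc_e$s; s_l <- tc_l$s
  }
  # structural ties (both events attaching at the same ancestral node) must
  # score as ties in both routes; summed edge lengths carry ~1e-16 noise
  tol <- 1e-9 * max(1, abs(s_e), abs(s_l))
  called <- if (s_e > s_l + tol) "A_earlier" else if (s_l > s_e + tol) "B_earlier" else "tie"
  list(d_early = d_e, d_late = d_l, crown_obs = crown_obs,
       s_early = s_e, s_late = s_l, called = called,
       result = classify_shift("A_earlier", called), tie = called == "tie")
}

#' Sweep configuration
#'
#' Defaults follow the study regime: 1,000-leaf species trees, extinction
#' fractions 0.0/0.5/0.9, subsampling down to 1% of taxa, 24 runs per cell,
#' 50 trees x 4 event pairs (= 200 pairs) per run.
#'
#' @param epsilon_grid extinction fractions to sweep.
#' @param keep_fraction_grid taxon sampling fractions to sweep.
#' @param n_runs independent runs per cell.
#' @param n_trees species trees per run.
#' @param n_pairs two-transfer scenarios per species tree.
#' @param lambda speciation rate (time scale).
#' @param n_extant extant tips per species tree.
#' @param n_recipient extant tips of the recipient clade.
#' @param recipient_crown_frac recipient crown age (the LECA analog) as a
#'   fraction of the species-tree origin age.
#' @param period_start_frac oldest admissible transfer age (the FECA analog)
#'   as a fraction of the origin age; transfer ages are uniform between the
#'   recipient crown and this bound.
#' @param min_recipient_kept,min_donor_side_kept subsampling constraints, see
#'   [sampling_scheme()].
#' @param sampling_mode see [sampling_scheme()].
#' @param master_seed integer master seed from which per-run seeds are
#'   derived.
#' @return an object of class `sweep_config`.
#' @export
sweep_config <- function(epsilon_grid = c(0.0, 0.5, 0.9),
                         keep_fraction_grid = c(1.0, 0.1, 0.01),
                         n_runs = 24, n_trees = 50, n_pairs = 4,
                         lambda = 1, n_extant = 1000, n_recipient = 10,
                         recipient_crown_frac = 0.25,
                         period_start_frac = 0.75,
                         min_recipient_kept = 2, min_donor_side_kept = 1,
                         sampling_mode = "uniform",
                         master_seed = 1) {
  stopifnot(length(epsilon_grid) >= 1, length(keep_fraction_grid) >= 1,
            n_runs >= 1, n_trees >= 1, n_pairs >= 1,
            recipient_crown_frac > 0, recipient_crown_frac < period_start_frac,
            period_start_frac < 1)
  structure(list(
    epsilon_grid = epsilon_grid, keep_fraction_grid = keep_fraction_grid,
    n_runs = as.integer(n_runs), n_trees = as.integer(n_trees),
    n_pairs = as.integer(n_pairs), lambda = lambda,
    n_extant = as.integer(n_extant), n_recipient = as.integer(n_recipient),
    recipient_crown_frac = recipient_crown_frac,
    period_start_frac = period_start_frac,
    min_recipient_kept = as.integer(min_recipient_kept),
    min_donor_side_kept = as.integer(min_donor_side_kept),
    sampling_mode = sampling_mode,
    master_seed = as.integer(master_seed)
  ), class = "sweep_config")
}

# per-run seed derivation: documented, reproducible, cell-recomputable
derive_run_seed <- function(master_seed, cell_index, run) {
  (master_seed * 1000003 + cell_index * 10007 + run * 101) %% 2147483629L
}

#' Run one sweep cell
#'
#' Simulates `config$n_trees` complete species trees at the given extinction
#' fraction, places `config$n_pairs` two-transfer scenarios per tree into a
#' shared recipient clade, applies extinction pruning and taxon subsampling,
#' scores each pair's relative-timing call against the true transfer order,
#' and pools the percentage of incorrect calls.  Fully determined by
#' `(config, run_seed)`.
#'
#' @param epsilon extinction fraction for this cell.
#' @param keep_fraction taxon sampling fraction for this cell.
#' @param run_seed integer seed for this run.
#' @param config a [sweep_config()].
#' @param detail if `TRUE`, attach a per-pair data.frame (`"pairs"`
#'   attribute) with true ages, donors, apparent ages and outcomes.
#' @return one-row data.frame: `epsilon`, `keep_fraction`, `run_seed`,
#'   `n_pairs`, `n_incorrect`, `pct_incorrect`, `n_ties`, `n_tree_failures`.
#' @export
run_cell <- function(epsilon, keep_fraction, run_seed, config, detail = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  set.seed(run_seed)
  scheme <- sampling_scheme(keep_fraction,
                            min_recipient_kept = config$min_recipient_kept,
                            min_donor_side_kept = config$min_donor_side_kept,
                            mode = config$sampling_mode)
  n_incorrect <- 0L; n_ties <- 0L; n_pairs_done <- 0L
  failures <- 0L; trees_done <- 0L
  pairs <- if (detail) vector("list", config$n_trees * config$n_pairs)

  while (trees_done < config$n_trees) {
    res <- tryCatch({
      sp <- simulate_complete_tree(
        bd_params(config$lambda, epsilon, config$n_extant))
      ages <- node_ages(sp)
      pv <- parent_vec(sp)
      org <- origin_age(sp)
      crown_target <- config$recipient_crown_frac * org
      rec <- simulate_recipient_clade(
        bd_params(config$lambda, epsilon, config$n_recipient),
        crown_age = crown_target)
      sp_ext <- extant_tips(sp)
      rec_ext <- extant_tips(rec)
      rpv <- parent_vec(rec); rages <- node_ages(rec)
      period <- c(config$period_start_frac * org, crown_target)
      out <- vector("list", config$n_pairs)
      for (j in seq_len(config$n_pairs)) {
        pr <- draw_transfer_pair(sp, period, ages = ages)
        retained <- pick_retained_taxa(c(sp_ext, rec_ext), scheme, rec_ext)
        don_keep <- setdiff(retained, rec_ext)
        rec_keep <- intersect(retained, rec_ext)
        d_e <- apparent_divergence_age(sp, pr$donor_early, pr$tau_early,
                                       don_keep, pv, ages)
        d_l <- apparent_divergence_age(sp, pr$donor_late, pr$tau_late,
                                       don_keep, pv, ages)
        crown_obs <- mrca_age(rpv, rages, match(rec_keep, rec$tip.label))
        out[[j]] <- data.frame(
          tree = trees_done + 1L, pair = j,
          tau_early = pr$tau_early, tau_late = pr$tau_late,
          donor_early = pr$donor_early, donor_late = pr$donor_late,
          d_early = d_e, d_late = d_l, crown_obs = crown_obs,
          s_early = d_e - crown_obs, s_late = d_l - crown_obs,
          n_kept = length(retained),
          period_start = period[1], origin = org,
          tie = d_e == d_l, incorrect = d_e <= d_l
        )
      }
      do.call(rbind, out)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      if (failures > config$n_trees)
        stop("cell aborted: more than half the trees failed (last error: ",
             conditionMessage(res), ")")
      next
    }
    trees_done <- trees_done + 1L
    n_pairs_done <- n_pairs_done + nrow(res)
    n_incorrect <- n_incorrect + sum(res$incorrect)
    n_ties <- n_ties + sum(res$tie)
    if (detail) pairs[[trees_done]] <- res
  }
  row <- data.frame(
    epsilon = epsilon, keep_fraction = keep_fraction, run_seed = run_seed,
    n_pairs = n_pairs_done, n_incorrect = n_incorrect,
    pct_incorrect = 100 * n_incorrect / n_pairs_done,
    n_ties = n_ties, n_tree_failures = failures
  )
  if (detail) attr(row, "pairs") <- do.call(rbind, pairs[seq_len(trees_done)])
  row
}

#' Run the full extinction-rate x sampling-fraction sweep
#'
#' Computes every cell of `epsilon_grid x keep_fraction_grid` over
#' `config$n_runs` independent runs each, with per-run seeds derived from the
#' master seed so that any cell can be recomputed in isolation.
#'
#' @param config a [sweep_config()].
#' @param out_dir optional directory; if given, `sweep_long.tsv` is appended
#'   after each cell (partial results survive interruption) and
#'   `sweep_summary.tsv` plus `run.log` are written at the end.
#' @param verbose print per-cell progress.
#' @return an object of class `sweep_result`: list with `long` (one row per
#'   run), `summary` (per-cell mean and sd of the percent-incorrect), and
#'   `config`.
#' @export
run_sweep <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  grid <- expand.grid(epsilon = config$epsilon_grid,
                      keep_fraction = config$keep_fraction_grid,
                      KEEP.OUT.ATTRS = FALSE)
  long <- vector("list", nrow(grid) * config$n_runs)
  k <- 0L
  for (ci in seq_len(nrow(grid))) {
    for (run in seq_len(config$n_runs)) {
      seed <- derive_run_seed(config$master_seed, ci, run)
      row <- run_cell(grid$epsilon[ci], grid$keep_fraction[ci], seed, config)
      row <- cbind(run = run, row)
      k <- k + 1L
      long[[k]] <- row
    }
    if (verbose)
      message(sprintf("cell epsilon=%g f=%g done", grid$epsilon[ci],
                      grid$keep_fraction[ci]))
    if (!is.null(out_dir)) {
      part <- do.call(rbind, long[seq_len(k)])
      write.table(part, file.path(out_dir, "sweep_long.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  long <- do.call(rbind, long)
  summary <- do.call(rbind, lapply(seq_len(nrow(grid)), function(ci) {
    sel <- long$epsilon == grid$epsilon[ci] &
      long$keep_fraction == grid$keep_fraction[ci]
    data.frame(
      epsilon = grid$epsilon[ci], keep_fraction = grid$keep_fraction[ci],
      n_runs = sum(sel),
      mean_pct_incorrect = mean(long$pct_incorrect[sel]),
      sd_pct_incorrect = sd(long$pct_incorrect[sel]),
      mean_pct_ties = mean(100 * long$n_ties[sel] / long$n_pairs[sel])
    )
  }))
  res <- structure(list(long = long, summary = summary, config = config),
                   class = "sweep_result")
  if (!is.null(out_dir)) {
    write.table(summary, file.path(out_dir, "sweep_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c(
      sprintf("ghostshift sweep, master_seed = %d", config$master_seed),
      sprintf("grid: epsilon {%s} x keep_fraction {%s}, %d runs x %d trees x %d pairs",
              paste(config$epsilon_grid, collapse = ", "),
              paste(config$keep_fraction_grid, collapse = ", "),
              config$n_runs, config$n_trees, config$n_pairs),
      sprintf("R %s, ghostshift %s", getRversion(),
              as.character(utils::packageVersion("ghostshift")))
    ), file.path(out_dir, "run.log"))
  }
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Ghost-lineage timing sweep\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
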