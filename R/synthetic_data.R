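#' Simulation scenario for the full pipeline
#'
#' The stated world of the package's validation suite: a birth-death clade
#' with fossil (extinct) and extant tips, a binary thermophysiology character
#' evolving under a known Mk process, state-conditional lognormal canal
#' diameters whose harmonic means straddle the logistic cut-off
#' (HMC ~ 12.6 um at the default calibration), and stratigraphic ranges
#' bracketing each fossil's true age.
#'
#' Defaults: speciation 0.25 and extinction 0.1 per Myr give a clade depth of
#' a few tens of Myr for 16 extant tips, realistic for a genus-to-family
#' level radiation and shallow enough that a true rate of q = 0.05 per Myr
#' leaves recoverable ancestral signal. Endotherm median canal diameter 11 um
#' versus ectotherm 25 um, with lognormal log-sd 0.3 and ~50 canals per thin
#' section, separates the two states strongly at the classifier's operating
#' point. Range widths of 5-15 Myr mimic stage-level stratigraphic
#' resolution.
#'
#' @param n_extant,n_fossil Tip counts of the simulated tree.
#' @param birth,death Speciation/extinction rates per Myr.
#' @param mk_truth True character process, an [mk_params()].
#' @param hmc_median_endo,hmc_median_ecto State-conditional median canal
#'   diameter, micrometres (endotherm < ectotherm).
#' @param hmc_log_sd Lognormal log-scale standard deviation of diameters.
#' @param range_width_min,range_width_max Uniform bounds on FAD-LAD width, Myr.
#' @param canals_mean Mean number of traced canals per thin section.
#' @param max_retries Birth-death restarts allowed before giving up.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_extant = 16L, n_fossil = 12L,
                                birth = 0.25, death = 0.1,
                                mk_truth = mk_params(0.05),
                                hmc_median_endo = 11, hmc_median_ecto = 25,
                                hmc_log_sd = 0.3,
                                range_width_min = 5, range_width_max = 15,
                                canals_mean = 50, max_retries = 100L) {
  stopifnot(n_extant >= 1L, n_fossil >= 0L, birth > 0, death >= 0,
            inherits(mk_truth, "mk_params"),
            hmc_log_sd >= 0, canals_mean >= 1,
            range_width_max >= range_width_min, range_width_min >= 0)
  if (!(hmc_median_endo < hmc_median_ecto)) {
    stop("endotherm median canal diameter must be below the ectotherm median")
  }
  if (death == 0 && n_fossil > 0L) {
    stop("cannot produce fossil tips with extinction rate 0")
  }
  structure(list(n_extant = as.integer(n_extant), n_fossil = as.integer(n_fossil),
                 birth = birth, death = death, mk_truth = mk_truth,
                 hmc_median_endo = hmc_median_endo,
                 hmc_median_ecto = hmc_median_ecto, hmc_log_sd = hmc_log_sd,
                 range_width_min = range_width_min,
                 range_width_max = range_width_max,
                 canals_mean = canals_mean, max_retries = as.integer(max_retries)),
            class = "simulation_scenario")
}

#' Node ages of any tree with branch durations
#'
#' Ages in Ma before present, anchored so that the deepest tip path ends at
#' age 0 (for trees with extant tips, these are the extant tips).
#'
#' @param phy A `phylo` with `edge.length`.
#' @return Ages indexed by ape node number.
#' @export
phylo_node_ages <- function(phy) {
  n <- ape::Ntip(phy)
  depth <- numeric(n + phy$Nnode)
  ed <- ape::reorder.phylo(phy, "cladewise")$edge
  el <- ape::reorder.phylo(phy, "cladewise")$edge.length
  for (k in seq_len(nrow(ed))) depth[ed[k, 2L]] <- depth[ed[k, 1L]] + el[k]
  max(depth[seq_len(n)]) - depth
}

# one forward Gillespie birth-death run; returns NULL on total extinction
bd_run_once <- function(scenario) {
  lam <- scenario$birth; mu <- scenario$death
  # lineage bookkeeping: birth time, end time (NA while alive), spawned kids
  t0 <- c(0); t1 <- c(NA_real_)
  kids <- list(list())  # per lineage: list of (time, child id)
  alive <- 1L
  t <- 0
  n_dead <- 0L
  for (ev in seq_len(200000L)) {
    na <- length(alive)
    if (na == 0L) return(NULL)
    if (na >= scenario$n_extant && n_dead >= scenario$n_fossil) break
    t <- t + stats::rexp(1L, na * (lam + mu))
    who <- alive[sample.int(na, 1L)]
    if (stats::runif(1L) < lam / (lam + mu)) {
      # budding speciation: parent persists, child starts
      t0 <- c(t0, t); t1 <- c(t1, NA_real_)
      id <- length(t0)
      kids[[id]] <- list()
      kids[[who]] <- c(kids[[who]], list(c(t, id)))
      alive <- c(alive, id)
    } else {
      t1[who] <- t
      alive <- setdiff(alive, who)
      n_dead <- n_dead + 1L
    }
  }
  if (length(alive) < scenario$n_extant || n_dead < scenario$n_fossil) return(NULL)
  # observe the clade strictly between the last and the (unrealized) next
  # event, so no terminal branch has zero duration
  t <- t + stats::rexp(1L, length(alive) * (lam + mu))
  t1[is.na(t1)] <- t  # survivors reach the present
  list(t0 = t0, t1 = t1, kids = kids, present = t, alive = alive)
}

bd_to_newick <- function(run) {
  build <- function(lin, from) {
    ev <- run$kids[[lin]]
    ev <- ev[order(vapply(ev, `[`, 0, 1L))]
    if (length(ev) == 0L) {
      sprintf("L%d:%.12g", lin, run$t1[lin] - from)
    } else {
      te <- ev[[1L]][1L]; child <- ev[[1L]][2L]
      run$kids[[lin]] <<- ev[-1L]
      sprintf("(%s,%s):%.12g",
              build(lin, te), build(child, te), te - from)
    }
  }
  paste0(sub(":[-+eE0-9.]+$", "", build(1L, 0)), ";")
}

#' Simulate a birth-death tree with fossil and extant tips
#'
#' Forward Gillespie simulation under constant speciation/extinction,
#' stopped once at least `n_extant` lineages are alive and `n_fossil` have
#' gone extinct; surplus tips of either class are then pruned at random so
#' the requested counts are met exactly. Fossil tips end at their extinction
#' time; extant tips end at the present (age 0). Restarts on total
#' extinction, up to `scenario$max_retries` times.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Optional integer seed.
#' @return A `phylo` with branch durations (Myr); true node ages available
#'   via [phylo_node_ages()]; fossil tip labels carry prefix `"fossil_"`,
#'   extant tips `"extant_"`.
#' @export
simulate_tree <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  run <- NULL
  for (i in seq_len(scenario$max_retries)) {
    run <- bd_run_once(scenario)
    if (!is.null(run)) break
  }
  if (is.null(run)) {
    stop("birth-death simulation went extinct ", scenario$max_retries,
         " times; raise the birth rate or the retry limit")
  }
  phy <- ape::read.tree(text = bd_to_newick(run))
  if (ape::Ntip(phy) == 1L) stop("degenerate single-lineage tree")
  is_ext <- phy$tip.label %in% paste0("L", run$alive)
  phy$tip.label <- ifelse(is_ext,
                          paste0("extant_", sub("^L", "", phy$tip.label)),
                          paste0("fossil_", sub("^L", "", phy$tip.label)))
  extant <- phy$tip.label[startsWith(phy$tip.label, "extant_")]
  fossil <- phy$tip.label[startsWith(phy$tip.label, "fossil_")]
  drop <- character(0)
  if (length(extant) > scenario$n_extant) {
    drop <- c(drop, sample(extant, length(extant) - scenario$n_extant))
  }
  if (length(fossil) > scenario$n_fossil) {
    drop <- c(drop, sample(fossil, length(fossil) - scenario$n_fossil))
  }
  if (length(drop)) phy <- ape::drop.tip(phy, drop)
  phy
}

#' Evolve the binary character along a dated tree
#'
#' The root state is drawn from the model's root prior and states propagate
#' in pre-order with the exact transition probabilities of each branch
#' duration: the generative twin of the inference model.
#'
#' @param phy A `phylo` with branch durations.
#' @param params True process, an [mk_params()].
#' @param seed Optional integer seed.
#' @return List with `tip_states` (named 0/1 over tips) and `node_states`
#'   (0/1 over all nodes in ape order).
#' @export
simulate_states <- function(phy, params, seed = NULL) {
  stopifnot(inherits(params, "mk_params"))
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(phy)
  state <- integer(n + phy$Nnode)
  prior <- root_prior_vec(params)
  state[n + 1L] <- stats::rbinom(1L, 1L, prior[2L])
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1L]; ch <- ord$edge[k, 2L]
    P <- transition_probability(ord$edge.length[k], params)
    state[ch] <- stats::rbinom(1L, 1L, P[state[p] + 1L, 2L])
  }
  list(tip_states = stats::setNames(state[seq_len(n)], phy$tip.label),
       node_states = state)
}

#' Simulate a canal-diameter measurement table from tip states
#'
#' One thin section per fossil tip: a Poisson number of canals (at least 1),
#' per-canal diameters drawn from the state's lognormal distribution
#' (median `hmc_median_*`, log-sd `hmc_log_sd`).
#'
#' @param tip_states Named 0/1 vector (1 = endothermy).
#' @param scenario A [simulation_scenario()].
#' @param fossil_tips Which tips get measurements (default: labels starting
#'   `"fossil_"`).
#' @param seed Optional integer seed.
#' @return A data.frame `specimen_id, taxon, diameter_um`, the histology
#'   module's input format.
#' @export
simulate_measurements <- function(tip_states, scenario,
                                  fossil_tips = grep("^fossil_", names(tip_states),
                                                     value = TRUE),
                                  seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(fossil_tips, function(tx) {
    k <- 1L + stats::rpois(1L, max(scenario$canals_mean - 1, 0))
    med <- if (tip_states[[tx]] == 1L) scenario$hmc_median_endo else scenario$hmc_median_ecto
    d <- stats::rlnorm(k, meanlog = log(med), sdlog = scenario$hmc_log_sd)
    data.frame(specimen_id = paste0(tx, "_s1"), taxon = tx, diameter_um = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Simulate stratigraphic ranges bracketing the true tip ages
#'
#' Each fossil tip of true age `t` gets a range of width `w ~ U(min, max)`
#' split at random around `t` (truncated at 0), so the truth is always inside
#' `[lad, fad]`. Extant tips get the degenerate range (0, 0).
#'
#' @param phy Dated tree (durations in Myr).
#' @param scenario A [simulation_scenario()].
#' @param seed Optional integer seed.
#' @return A `strat_ranges` data.frame covering every tip.
#' @export
simulate_ranges <- function(phy, scenario, seed = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(seed)) set.seed(seed)
  age <- phylo_node_ages(phy)[seq_len(ape::Ntip(phy))]
  names(age) <- phy$tip.label
  # tolerate tiny fp residue from Newick round-tripping of extant depths
  fossil <- age > 1e-6
  w <- stats::runif(sum(fossil), scenario$range_width_min, scenario$range_width_max)
  a <- stats::runif(sum(fossil)) * w
  fad <- age
  lad <- age
  fad[fossil] <- age[fossil] + a
  lad[fossil] <- pmax(0, age[fossil] - (w - a))
  fad[!fossil] <- 0; lad[!fossil] <- 0
  strat_ranges(names(age), fad, lad)
}

#' Simulate one complete pipeline input set
#'
#' Tree, character history, fossil canal measurements, stratigraphic ranges
#' and an extant-state table, plus the retained ground truth. All files
#' emitted by [write_dataset()] are readable by the package's own readers.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed; sub-draws use fixed offsets from it.
#' @return List `tree`, `tip_states`, `node_states`, `measurements`,
#'   `ranges`, `extant_states`, `truth` (root state, true params, seed).
#' @export
simulate_dataset <- function(scenario = simulation_scenario(), seed = 1L) {
  tree <- simulate_tree(scenario, seed = seed)
  sim <- simulate_states(tree, scenario$mk_truth, seed = seed + 500000L)
  meas <- simulate_measurements(sim$tip_states, scenario, seed = seed + 1000000L)
  ranges <- simulate_ranges(tree, scenario, seed = seed + 1500000L)
  extant <- grep("^extant_", names(sim$tip_states), value = TRUE)
  extant_states <- ifelse(sim$tip_states[extant] == 1L, "endothermy", "ectothermy")
  n <- ape::Ntip(tree)
  list(tree = tree, tip_states = sim$tip_states, node_states = sim$node_states,
       measurements = meas, ranges = ranges,
       extant_states = stats::setNames(extant_states, extant),
       truth = list(root_state = sim$node_states[n + 1L],
                    params = scenario$mk_truth, seed = seed))
}

#' Write a simulated dataset to disk in the pipeline's input formats
#' @param ds From [simulate_dataset()]. @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(ds$measurements, file.path(dir, "measurements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(ds$ranges, file.path(dir, "ranges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  utils::write.table(data.frame(taxon = names(ds$extant_states),
                                state = unname(ds$extant_states)),
                     file.path(dir, "extant_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
  jsonlite::write_json(list(root_state = ds$truth$root_state,
                            q01 = ds$truth$params$q01, q10 = ds$truth$params$q10,
                            seed = ds$truth$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
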