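#' Resolve a taxon's binary state from its specimen records
#'
#' Multiple thin sections of one taxon are kept as separate records; the tree
#' needs one state per tip. Default rule: majority vote over specimen
#' statuses; on a tie, endothermy if any specimen's `p_end` reaches the
#' threshold (a tie always implies at least one such specimen, so ties go to
#' endothermy).
#'
#' @param records A `specimen_records` data.frame (see [specimen_records()]).
#' @param model The [logistic_model()] supplying the threshold (tie rule).
#' @return Named character vector taxon -> `"ectothermy"`/`"endothermy"`.
#' @export
taxon_state_from_specimens <- function(records, model = logistic_model()) {
  stopifnot(inherits(records, "data.frame"), nrow(records) >= 1L,
            all(c("taxon", "p_end", "status") %in% names(records)))
  taxa <- unique(records$taxon)
  out <- vapply(taxa, function(tx) {
    r <- records[records$taxon == tx, , drop = FALSE]
    n_endo <- sum(r$status == "endothermy")
    n_ecto <- sum(r$status == "ectothermy")
    if (n_endo > n_ecto) "endothermy"
    else if (n_ecto > n_endo) "ectothermy"
    else if (any(r$p_end >= model$threshold)) "endothermy"
    else "ectothermy"
  }, "")
  stats::setNames(out, taxa)
}

#' Element-wise mean or median across an ensemble of node probabilities
#'
#' @param per_rep List of per-repetition named probability vectors (node
#'   label -> probability of ancestral endothermy), all over the same nodes.
#' @param statistic `"mean"` or `"median"`.
#' @return Named numeric vector, one entry per node.
#' @export
summarize_reps <- function(per_rep, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(per_rep), length(per_rep) >= 1L)
  nms <- names(per_rep[[1L]])
  for (r in seq_along(per_rep)) {
    if (!identical(names(per_rep[[r]]), nms)) {
      stop("mismatched node sets between repetitions (repetition ", r, ")")
    }
  }
  m <- do.call(rbind, per_rep)
  f <- if (statistic == "mean") colMeans else function(x) apply(x, 2L, stats::median)
  stats::setNames(f(m), nms)
}

#' Default pipeline configuration
#'
#' All tunables of the pipeline in one list: the logistic calibration, the
#' dating algorithms' constants, the Mk model form and root prior, and the
#' ensemble size.
#'
#' @param ... Overrides by name, e.g. `pipeline_config(reps = 10)`.
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    logistic.coefficient = -0.45,
    logistic.intercept = 6.04,
    logistic.threshold = 0.59,
    equal.root_buffer = 10,
    mbl.min_len = 1.0,
    mk.model_form = "ER",
    mk.root_prior = "flat",
    reps = 100L,
    seed = 1L
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Unknown keys are an error; values are coerced to the type of the default.
#'
#' @param path Path to the file.
#' @return A config list as from [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- which(vapply(kv, length, 0L) != 3L)
  if (length(bad)) stop("cannot parse config line: '", lines[bad[1L]], "'")
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (i in seq_along(keys)) {
    d <- defaults[[keys[i]]]
    cfg[[keys[i]]] <- if (is.numeric(d)) as.numeric(vals[i]) else vals[i]
  }
  cfg$reps <- as.integer(cfg$reps)
  cfg
}

#' Build the [logistic_model()] named by a configuration list
#' @param cfg A list from [pipeline_config()] or [read_config()].
#' @return A `logistic_model`.
#' @export
logistic_from_config <- function(cfg) {
  logistic_model(coefficient = cfg$logistic.coefficient,
                 intercept = cfg$logistic.intercept,
                 threshold = cfg$logistic.threshold)
}

#' Run the full inference pipeline
#'
#' End to end: classify fossil specimens from canal measurements, merge with
#' known extant states, draw `reps` stochastically dated trees per algorithm
#' ('equal' and 'mbl'), refit the Mk rate and reconstruct marginal ancestral
#' states on each tree, and aggregate the per-node probability of ancestral
#' endothermy by mean and median. Deterministic given `cfg$seed`
#' (repetition `r` uses seed `seed + r`).
#'
#' @param measurements List of [canal_measurements()] (fossil specimens), or
#'   `NULL` if `fossil_states` is supplied directly.
#' @param extant_states Named vector (or data.frame `taxon,state`) of known
#'   states for extant tips.
#' @param topology A `phylo` cladogram covering fossil and extant tips.
#' @param ranges A `strat_ranges` table covering every tip (extant: 0, 0).
#' @param cfg Configuration from [pipeline_config()].
#' @param fossil_states Optional pre-resolved fossil tip states, bypassing
#'   the measurement stage.
#' @param verbose Print one progress line per repetition (seed, fitted rate).
#' @return An `ensemble_summary`: list with `records`, `tip_states`,
#'   `summary` (per algorithm: mean/median/q025/q975 per node as a
#'   data.frame), `rates` (fitted rate per repetition), `reps`, `seed`,
#'   `node_labels`, `config`.
#' @export
run_pipeline <- function(measurements = NULL, extant_states = NULL,
                         topology, ranges, cfg = pipeline_config(),
                         fossil_states = NULL, verbose = FALSE) {
  model <- logistic_from_config(cfg)
  records <- NULL
  if (is.null(fossil_states)) {
    if (is.null(measurements)) stop("need either measurements or fossil_states")
    records <- specimen_records(measurements, model)
    fossil_states <- taxon_state_from_specimens(records, model)
  }
  if (is.data.frame(extant_states)) {
    extant_states <- stats::setNames(extant_states$state, extant_states$taxon)
  }
  tip_states <- c(fossil_states, extant_states)
  miss <- setdiff(topology$tip.label, names(tip_states))
  if (length(miss)) {
    stop("tip(s) without a state (no specimens and not in extant table): ",
         paste(miss, collapse = ", "))
  }
  tip_states <- tip_states[topology$tip.label]
  miss_rng <- setdiff(topology$tip.label, ranges$taxon)
  if (length(miss_rng)) {
    stop("tip(s) without a stratigraphic range: ", paste(miss_rng, collapse = ", "))
  }

  labs <- node_label_vector(topology)
  n <- ape::Ntip(topology)
  internal <- labs[(n + 1L):(n + topology$Nnode)]
  summary <- list()
  rates <- list()
  for (method in c("equal", "mbl")) {
    per_rep <- vector("list", cfg$reps)
    qhat <- numeric(cfg$reps)
    for (r in seq_len(cfg$reps)) {
      ages <- sample_tip_ages(ranges, seed = cfg$seed + r, tips = topology$tip.label)
      tree <- if (method == "equal") {
        timescale_equal(topology, ages, root_buffer = cfg$equal.root_buffer)
      } else {
        timescale_mbl(topology, ages, min_len = cfg$mbl.min_len)
      }
      fit <- fit_rate_ml(tree, tip_states, model_form = cfg$mk.model_form,
                         root_prior = cfg$mk.root_prior)
      asr <- marginal_asr(tree, tip_states, fit)
      per_rep[[r]] <- stats::setNames(asr[internal, "p_endo"], internal)
      qhat[r] <- fit$q01
      if (verbose) {
        message(sprintf("[%s rep %3d] seed %d  q01 = %.5g  q10 = %.5g",
                        method, r, cfg$seed + r, fit$q01, fit$q10))
      }
    }
    m <- do.call(rbind, per_rep)
    summary[[method]] <- data.frame(
      node = internal,
      mean = summarize_reps(per_rep, "mean"),
      median = summarize_reps(per_rep, "median"),
      q025 = apply(m, 2L, stats::quantile, probs = 0.025, names = FALSE),
      q975 = apply(m, 2L, stats::quantile, probs = 0.975, names = FALSE),
      row.names = NULL, stringsAsFactors = FALSE
    )
    rates[[method]] <- qhat
  }
  structure(list(records = records, tip_states = tip_states,
                 summary = summary, rates = rates, reps = cfg$reps,
                 seed = cfg$seed, node_labels = labs, config = cfg),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary> %d repetitions per algorithm, seed %d\n",
              x$reps, x$seed))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-5s: %d internal nodes, mean p_asend range [%.3g, %.3g]\n",
                m, nrow(s), min(s$mean), max(s$mean)))
  }
  invisible(x)
}

#' Look up a node's aggregated probability of ancestral endothermy
#' @param ens An `ensemble_summary`.
#' @param node Internal-node label (e.g. `"Amniota"`).
#' @param method `"equal"` or `"mbl"`. @param statistic `"mean"` or `"median"`.
#' @return A probability.
#' @export
p_asend <- function(ens, node, method = "equal", statistic = "mean") {
  s <- ens$summary[[method]]
  if (is.null(s)) stop("unknown method: ", method)
  i <- match(node, s$node)
  if (is.na(i)) stop("no internal node labelled '", node, "'")
  s[[statistic]][i]
}

#' Write the four analysis tables and a run manifest
#'
#' Emits `summary_<method>_<statistic>.tsv` for the four combinations, plus
#' `manifest.json` (config, seed, repetition count, package version).
#'
#' @param ens An `ensemble_summary`. @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in names(ens$summary)) {
    s <- ens$summary[[m]]
    for (stat in c("mean", "median")) {
      out <- data.frame(node = s$node, p_asend = sprintf("%.17g", s[[stat]]),
                        q025 = sprintf("%.6g", s$q025),
                        q975 = sprintf("%.6g", s$q975))
      utils::write.table(out, file.path(dir, sprintf("summary_%s_%s.tsv", m, stat)),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         fileEncoding = "UTF-8")
    }
  }
  manifest <- list(config = ens$config, seed = ens$seed, reps = ens$reps,
                   package_version = as.character(utils::packageVersion("osteotherm")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
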