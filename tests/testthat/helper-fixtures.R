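# Shared fixtures: the published per-specimen table, the synthetic stand-in
# supertree inputs, and small random-tree generators.

ot_extdata <- function(f) system.file("extdata", f, package = "osteotherm")

# printed results table; the printed probability column stays character so
# its precision (2 or 3 significant figures) is recoverable
ot_table1 <- function() {
  utils::read.table(ot_extdata("table1_specimens.tsv"), header = TRUE,
                    sep = "\t", comment.char = "#", encoding = "UTF-8",
                    colClasses = c(p_end_printed = "character"))
}

printed_sigfigs <- function(s) {
  nchar(gsub("[^0-9]", "", sub("[eE].*$", "", s)))
}

# one single-canal measurement per row: HMC of one diameter is that diameter,
# so these records carry exactly the printed HMC values
ot_table1_measurements <- function() {
  t1 <- ot_table1()
  lapply(seq_len(nrow(t1)), function(i) {
    canal_measurements(t1$specimen_id[i], t1$taxon[i], t1$hmc_um[i])
  })
}

ot_standin_inputs <- function() {
  list(
    topology = read_topology(ot_extdata("synthetic_supertree.nwk")),
    ranges = read_strat_ranges(ot_extdata("synthetic_strat_ranges.tsv")),
    extant = utils::read.table(ot_extdata("synthetic_extant_states.tsv"),
                               header = TRUE, sep = "\t", comment.char = "#",
                               encoding = "UTF-8")
  )
}

# random dated binary tree with strictly positive durations
rand_dated_tree <- function(n) {
  phy <- ape::rtree(n)
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 0.2) + 0.05
  phy
}

rand_tip_states <- function(phy) {
  stats::setNames(sample(0:1, ape::Ntip(phy), replace = TRUE), phy$tip.label)
}
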