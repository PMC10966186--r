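#' Read a cladogram in Newick format
#'
#' Thin wrapper around [ape::read.tree()] that validates the result: unique
#' tip labels are required, internal node labels (clade names such as
#' "Amniota") and non-ASCII characters (the extinct dagger) are preserved.
#' Polytomies are accepted. Branch lengths, if present, are ignored by the
#' time-scaling functions (the topology is the input; ages come from
#' stratigraphy).
#'
#' @param path Path to a Newick file (UTF-8), or use `text =` for a literal
#'   string.
#' @param text Optional Newick string instead of a file.
#' @return An [ape] `phylo` object.
#' @export
read_topology <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("file not found: ", path)
    text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "")
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(phy) || !inherits(phy, "phylo")) {
    # locate the first structural problem for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
    pos <- if (any(bal < 0)) which(bal < 0)[1L] else nchar(text)
    stop("malformed Newick near character ", pos)
  }
  # Newick single-quoted labels: drop the delimiters, unescape doubled quotes
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", substr(x[q], 2L, nchar(x[q]) - 1L))
    x
  }
  phy$tip.label <- unquote(phy$tip.label)
  if (!is.null(phy$node.label)) phy$node.label <- unquote(phy$node.label)
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  phy
}

#' Read a stratigraphic-range table
#'
#' Tab- or comma-separated with columns `taxon`, `fad_ma` (first appearance
#' datum, older bound) and `lad_ma` (last appearance datum, younger bound),
#' ages in Ma before present. Extant taxa carry `fad_ma = lad_ma = 0`.
#'
#' @param path Path to the file.
#' @return A data.frame `taxon`, `fad_ma`, `lad_ma` with class `strat_ranges`.
#' @export
read_strat_ranges <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\t", first_noncomment_line(path))) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          comment.char = "#")
  need <- c("taxon", "fad_ma", "lad_ma")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  strat_ranges(df$taxon, df$fad_ma, df$lad_ma)
}

#' Construct and validate stratigraphic ranges
#' @param taxon Character vector of taxon names (unique).
#' @param fad_ma,lad_ma First/last appearance data in Ma; `fad_ma >= lad_ma >= 0`.
#' @return A `strat_ranges` data.frame.
#' @export
strat_ranges <- function(taxon, fad_ma, lad_ma) {
  stopifnot(is.character(taxon), length(taxon) == length(fad_ma),
            length(fad_ma) == length(lad_ma))
  if (anyDuplicated(taxon)) {
    stop("duplicate taxa in ranges: ",
         paste(unique(taxon[duplicated(taxon)]), collapse = ", "))
  }
  fad_ma <- as.numeric(fad_ma); lad_ma <- as.numeric(lad_ma)
  bad <- which(!is.finite(fad_ma) | !is.finite(lad_ma) |
                 fad_ma < lad_ma | lad_ma < 0)
  if (length(bad)) {
    stop("invalid range for ", taxon[bad[1L]], ": fad=", fad_ma[bad[1L]],
         ", lad=", lad_ma[bad[1L]], " (need fad >= lad >= 0)")
  }
  structure(data.frame(taxon = taxon, fad_ma = fad_ma, lad_ma = lad_ma,
                       stringsAsFactors = FALSE),
            class = c("strat_ranges", "data.frame"))
}

#' Sample one tip age per taxon from its stratigraphic range
#'
#' Ages are drawn independently and uniformly on \[LAD, FAD\]; degenerate
#' ranges (FAD = LAD, in particular extant taxa at 0) return the bound
#' exactly. Deterministic given `seed`.
#'
#' @param ranges A `strat_ranges` data.frame.
#' @param seed Optional integer seed (set before drawing when non-NULL).
#' @param tips Optional character vector of required tips; an error names any
#'   tip without a range.
#' @return Named numeric vector of ages (Ma), names = taxa.
#' @export
sample_tip_ages <- function(ranges, seed = NULL, tips = NULL) {
  stopifnot(inherits(ranges, "strat_ranges"))
  if (!is.null(tips)) {
    miss <- setdiff(tips, ranges$taxon)
    if (length(miss)) {
      stop("no stratigraphic range for tip(s): ", paste(miss, collapse = ", "))
    }
    ranges <- ranges[match(tips, ranges$taxon), ]
  }
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(nrow(ranges))
  age <- ranges$lad_ma + u * (ranges$fad_ma - ranges$lad_ma)
  age[ranges$fad_ma == ranges$lad_ma] <- ranges$lad_ma[ranges$fad_ma == ranges$lad_ma]
  stats::setNames(age, ranges$taxon)
}

# parent lookup: par[child node id] = parent id, NA at root
node_parents <- function(phy) {
  par <- rep(NA_integer_, ape::Ntip(phy) + phy$Nnode)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

#' Initial node ages: oldest descendant tip
#'
#' Assigns every internal node the maximum age over its descendant tips.
#' This is the raw dating both refinement algorithms start from; it always
#' contains zero-duration branches (every internal node touches its oldest
#' descendant through a zero path), which 'equal' and 'mbl' then repair.
#'
#' @param phy A `phylo` topology.
#' @param tip_ages Named ages (Ma) covering every tip label.
#' @return Numeric vector of ages indexed by ape node number
#'   (tips `1..Ntip`, then internal nodes).
#' @export
basic_node_ages <- function(phy, tip_ages) {
  n <- ape::Ntip(phy)
  miss <- setdiff(phy$tip.label, names(tip_ages))
  if (length(miss)) stop("no age for tip(s): ", paste(miss, collapse = ", "))
  age <- c(as.numeric(tip_ages[phy$tip.label]), rep(-Inf, phy$Nnode))
  ed <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    if (age[ch] > age[p]) age[p] <- age[ch]
  }
  age
}

# wrap a dated topology: a phylo whose edge lengths are durations (Myr),
# with the full age vector stored as an attribute
make_timescaled <- function(phy, age, method) {
  phy$edge.length <- age[phy$edge[, 1L]] - age[phy$edge[, 2L]]
  if (any(phy$edge.length <= 0)) {
    stop("internal error: non-positive branch duration after '", method, "'")
  }
  attr(phy, "node_age") <- age
  attr(phy, "dating_method") <- method
  phy
}

#' Node ages of a time-scaled tree
#' @param tree A tree produced by [timescale_equal()] or [timescale_mbl()].
#' @return Ages (Ma) indexed by ape node number.
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "node_age")
  if (is.null(a)) stop("not a time-scaled tree (no node_age attribute)")
  a
}

#' Time-scale a topology with the 'equal' algorithm
#'
#' Starts from [basic_node_ages()] and repairs every maximal run of
#' zero-duration branches by spacing the undatable nodes evenly between the
#' nearest strictly older ancestor and the run's own age (the age of the
#' oldest descendant tip bounding it below). Nodes whose incoming branch
#' already has positive duration are never moved. The root, which under the
#' basic dating always sits at the age of the oldest tip, is pushed older by
#' `root_buffer` to create sharable time; `root_buffer = 0` with an
#' undatable root is an error.
#'
#' @param phy Topology (`phylo`).
#' @param tip_ages Named tip ages (Ma), e.g. from [sample_tip_ages()].
#' @param root_buffer Myr added above the basic root age when the root is
#'   part of a zero-duration run. Default 10.
#' @return A time-scaled `phylo` (edge lengths in Myr, ages via [node_ages()]).
#' @export
timescale_equal <- function(phy, tip_ages, root_buffer = 10) {
  stopifnot(is.numeric(root_buffer), length(root_buffer) == 1L, root_buffer >= 0)
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  root <- n + 1L
  basic <- basic_node_ages(phy, tip_ages)
  par <- node_parents(phy)

  # zero-duration components: maximal sets of nodes connected by branches of
  # zero duration under the basic ages (all members share one age)
  preord <- c(root, ape::reorder.phylo(phy, "cladewise")$edge[, 2L])
  preord <- preord[!duplicated(preord)]
  comp <- integer(nn); ncomp <- 0L
  for (v in preord) {
    if (v == root || basic[par[v]] != basic[v]) {
      ncomp <- ncomp + 1L
      comp[v] <- ncomp
    } else {
      comp[v] <- comp[par[v]]
    }
  }
  final <- basic
  sizes <- tabulate(comp, nbins = ncomp)
  internal <- seq_len(nn) > n

  for (ci in unique(comp[preord])) {
    if (sizes[ci] < 2L) next          # no zero branch here: node stays dated
    members <- which(comp == ci)
    a <- basic[members[1L]]
    top <- members[is.na(par[members]) | comp[par[members]] != ci]
    top <- top[1L]                    # unique by construction
    if (top == root) {
      if (root_buffer <= 0) stop("cannot date root: zero-duration run at the root and root_buffer = 0")
      head_age <- a + root_buffer
      final[root] <- head_age
      fixed_head <- root
    } else {
      head_age <- final[par[top]]     # parent's component resolved earlier
      fixed_head <- par[top]
    }
    # chain depth d (internal members between the fixed head and the node,
    # inclusive) and downward internal chain height h, within the component
    d <- integer(nn); h <- integer(nn)
    ord <- preord[preord %in% members]
    for (v in ord) {
      if (v == fixed_head) next
      up <- par[v]
      d[v] <- (if (up == fixed_head || comp[up] != ci) 0L else d[up]) +
        (if (internal[v]) 1L else 0L)
    }
    for (v in rev(ord)) {
      if (v == fixed_head || !internal[v]) next
      kids <- which(par == v & comp == ci & internal)
      h[v] <- if (length(kids)) 1L + max(h[kids]) else 0L
    }
    for (v in ord) {
      if (v == fixed_head || !internal[v]) next
      final[v] <- head_age - d[v] * (head_age - a) / (d[v] + h[v] + 1L)
    }
  }
  make_timescaled(phy, final, "equal")
}

#' Time-scale a topology with the minimum-branch-length ('mbl') algorithm
#'
#' Starts from [basic_node_ages()] and, in post-order, pushes each internal
#' node old enough that every branch below it lasts at least `min_len` Myr:
#' `age(parent) <- max(age(parent), age(child) + min_len)`. Tip ages are
#' never touched; the root drifts older as needed.
#'
#' @param phy Topology (`phylo`).
#' @param tip_ages Named tip ages (Ma).
#' @param min_len Minimum branch duration in Myr (default 1).
#' @return A time-scaled `phylo`.
#' @export
timescale_mbl <- function(phy, tip_ages, min_len = 1.0) {
  if (!is.numeric(min_len) || length(min_len) != 1L || min_len <= 0) {
    stop("min_len must be a positive duration (Myr)")
  }
  age <- basic_node_ages(phy, tip_ages)
  ed <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    if (age[ch] + min_len > age[p]) age[p] <- age[ch] + min_len
  }
  make_timescaled(phy, age, "mbl")
}

#' Draw an ensemble of stochastically dated trees
#'
#' Repetition `r` samples tip ages with seed `seed + r` and dates the
#' topology with the requested algorithm, so any single repetition is
#' independently reproducible.
#'
#' @param phy Topology.
#' @param ranges A `strat_ranges` table covering every tip.
#' @param method `"equal"` or `"mbl"`.
#' @param reps Number of repetitions (paper setting: 100).
#' @param seed Base integer seed.
#' @param root_buffer,min_len Passed to the respective algorithm.
#' @return List of time-scaled trees, length `reps`.
#' @export
timescale_ensemble <- function(phy, ranges, method = c("equal", "mbl"),
                               reps = 100L, seed = 1L,
                               root_buffer = 10, min_len = 1.0) {
  method <- match.arg(method)
  lapply(seq_len(reps), function(r) {
    ages <- sample_tip_ages(ranges, seed = seed + r, tips = phy$tip.label)
    switch(method,
           equal = timescale_equal(phy, ages, root_buffer = root_buffer),
           mbl = timescale_mbl(phy, ages, min_len = min_len))
  })
}

#' Write a time-scaled tree as Newick (durations as branch lengths)
#' @param tree Time-scaled `phylo`. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timescaled <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
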