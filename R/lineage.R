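# Rice developmental cell-lineage model.
#
# Compartments are unitary cell lineages with a birth time in days after
# pollination (DAP); children split off at fixed times. Sampled terminal
# compartments map to the assayed tissues (endosperm E, radicle R, leaf
# blades L1-L5); the germline (GERM) is a terminal that is never assayed but
# carries transmissible insertions. Double fertilization gives two disjoint
# subtrees below 0 DAP: the embryo (zygote) and the triploid endosperm; the
# four gamete lineages (egg, the two sperm, the polar nuclei of the central
# cell) precede 0 DAP and feed into one of the two products.

#' Sampled tissue labels
#'
#' The tissues assayed in the ontogeny design (endosperm, radicle and leaf
#' blades 1-5). The germline `"GERM"` is a transmission channel, not an
#' assayed sample, and is therefore not included.
#'
#' @return Character vector `c("E","R","L1".."L5")`.
#' @export
sampled_tissues <- function() c("E", "R", "L1", "L2", "L3", "L4", "L5")

all_tissue_labels <- function() c(sampled_tissues(), "GERM")

#' Default lineage configuration
#'
#' Returns the configuration list describing the default rice ontogeny used
#' throughout the package: the SAM and radicle progenitor are regionalized in
#' the proembryo at 3 DAP; the 1st, 2nd and 3rd leaf primordia split from the
#' SAM at 5, 6.5 and 8 DAP; the 4th and 5th leaves split post-germination
#' (defaults 12 and 15 DAP); the germline separates from the SAM at the
#' reproductive stage (default 60 DAP). The endosperm lineage is born at
#' 0 DAP from the central-cell fusion. Four pre-fertilization gamete lineages
#' (egg, sperm-to-egg, sperm-to-central-cell, polar nuclei) start at the
#' onset of gametogenesis (default -10 DAP).
#'
#' The L2 split (6.5 DAP) is the midpoint of the observed 5 and 8 DAP leaf
#' initiations; L4/L5 times only need to preserve leaf order for
#' classification. All times are configurable.
#'
#' @param l2_split,l4_split,l5_split,germline_split Split times (DAP).
#' @param gametogenesis_onset Start of the pre-fertilization lineages (DAP,
#'   negative).
#' @param horizon Sampling horizon for terminal tissues (DAP).
#' @return A nested list suitable for [build_lineage()].
#' @export
lineage_config_default <- function(l2_split = 6.5, l4_split = 12,
                                   l5_split = 15, germline_split = 60,
                                   gametogenesis_onset = -10, horizon = 20) {
  list(
    horizon = horizon,
    compartments = list(
      list(name = "egg",             parents = character(), birth = gametogenesis_onset),
      list(name = "sperm_to_egg",    parents = character(), birth = gametogenesis_onset),
      list(name = "sperm_to_central", parents = character(), birth = gametogenesis_onset),
      list(name = "polar_nuclei",    parents = character(), birth = gametogenesis_onset),
      list(name = "proembryo",       parents = c("egg", "sperm_to_egg"), birth = 0),
      list(name = "endosperm",       parents = c("polar_nuclei", "sperm_to_central"),
           birth = 0, tissue = "E"),
      list(name = "SAM",             parents = "proembryo", birth = 3),
      list(name = "radicle_progenitor", parents = "proembryo", birth = 3, tissue = "R"),
      list(name = "L1", parents = "SAM", birth = 5,        tissue = "L1"),
      list(name = "L2", parents = "SAM", birth = l2_split, tissue = "L2"),
      list(name = "L3", parents = "SAM", birth = 8,        tissue = "L3"),
      list(name = "L4", parents = "SAM", birth = l4_split, tissue = "L4"),
      list(name = "L5", parents = "SAM", birth = l5_split, tissue = "L5"),
      list(name = "germline", parents = "SAM", birth = germline_split,
           tissue = "GERM", end = germline_split + 10)
    )
  )
}

#' Build and validate a lineage tree
#'
#' Turns a lineage configuration (see [lineage_config_default()] and
#' [read_lineage_config()]) into a validated `lineage_tree` object. A
#' compartment may list two parents only at a fertilization join (both
#' gamete lineages feed the same product); everywhere else parentage is a
#' tree. A compartment with a `tissue` entry is a sampled terminal; every
#' tissue label must map to exactly one compartment.
#'
#' @param config A configuration list with elements `horizon` and
#'   `compartments` (each compartment a list with `name`, `parents`, `birth`
#'   and optionally `tissue`).
#' @return An object of class `lineage_tree`.
#' @export
build_lineage <- function(config) {
  comps <- config$compartments
  if (is.null(comps) || !length(comps)) {
    abort("lineage config must define at least one compartment")
  }
  horizon <- config$horizon %||% 20
  nm <- map_chr(comps, "name")
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate compartment name: ", nm[duplicated(nm)][1]))
  }
  tissue <- map(comps, function(x) as.character(unlist(x$tissue %||% character())))
  birth <- map_dbl(comps, "birth")
  all_mapped <- unlist(tissue)
  bad_tissue <- setdiff(all_mapped, all_tissue_labels())
  if (length(bad_tissue)) {
    abort(paste0("unknown tissue label: ", bad_tissue[1]))
  }
  if (anyDuplicated(all_mapped)) {
    abort("each tissue must map to exactly one terminal compartment")
  }

  nodes <- tibble(name = nm, birth = birth, tissue = tissue)

  # children map: a child splits from each of its parents at its own birth
  edges <- list_rbind(map(comps, function(x) {
    ps <- x$parents %||% character()
    if (!length(ps)) return(tibble(parent = character(), child = character(), split = double()))
    tibble(parent = unlist(ps), child = x$name, split = x$birth)
  }))
  unknown <- setdiff(edges$parent, nm)
  if (length(unknown)) abort(paste0("unknown parent compartment: ", unknown[1]))

  # ordering: every child must be born at or after each parent
  pb <- birth[match(edges$parent, nm)]
  if (any(edges$split < pb)) {
    bad <- edges[edges$split < pb, ][1, ]
    abort(sprintf("compartment '%s' splits at %g DAP before its parent '%s' is born",
                  bad$child, bad$split, bad$parent))
  }

  # cycle check by topological elimination
  remaining <- nm
  deps <- setNames(map(comps, function(x) unlist(x$parents %||% character())), nm)
  repeat {
    free <- remaining[map_lgl(deps[remaining], function(p) !any(p %in% remaining))]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining)) abort("cyclic parentage in lineage configuration")

  children <- map(setNames(nm, nm), function(p) {
    e <- edges[edges$parent == p, c("child", "split")]
    e[order(e$split), ]
  })

  # compartment end: last child split for internal nodes, horizon for terminals
  is_terminal <- map_int(tissue, length) > 0
  end <- map_dbl(nm, function(p) {
    ch <- children[[p]]
    if (nrow(ch)) max(ch$split) else max(horizon, nodes$birth[nodes$name == p])
  })
  # a terminal with children (degenerate configs) extends to the horizon too
  end[is_terminal] <- pmax(end[is_terminal], horizon)
  # explicit per-compartment end overrides (e.g. the germline persisting
  # through the reproductive phase)
  explicit <- map_dbl(comps, function(x) x$end %||% NA_real_)
  end <- ifelse(is.na(explicit), end, pmax(explicit, end, birth))
  nodes$end <- end

  structure(
    list(nodes = nodes, children = children, horizon = horizon, config = config),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> ", nrow(x$nodes), " compartments, horizon ",
      x$horizon, " DAP\n", sep = "")
  terms <- x$nodes[map_int(x$nodes$tissue, length) > 0, ]
  cat("  terminals: ",
      paste0(map_chr(terms$tissue, paste, collapse = "+"), "<-", terms$name,
             "@", terms$birth, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Default lineage tree
#'
#' Convenience wrapper equal to `build_lineage(lineage_config_default(...))`.
#'
#' @param ... Passed to [lineage_config_default()].
#' @return A `lineage_tree`.
#' @export
default_lineage <- function(...) build_lineage(lineage_config_default(...))

comp_row <- function(tree, compartment) {
  i <- match(compartment, tree$nodes$name)
  if (is.na(i)) abort(paste0("unknown compartment: ", compartment))
  tree$nodes[i, ]
}

check_placement <- function(tree, compartment, time) {
  row <- comp_row(tree, compartment)
  if (time < row$birth || time > row$end) {
    abort(sprintf("time %g DAP outside compartment '%s' interval [%g, %g]",
                  time, compartment, row$birth, row$end))
  }
  invisible(row)
}

# terminal tissues reached by the lineage of `compartment` from `time` on:
# its own tissue plus every child splitting at or after `time`, recursively.
reachable_tissues <- function(tree, compartment, time) {
  row <- tree$nodes[match(compartment, tree$nodes$name), ]
  out <- row$tissue[[1]]
  ch <- tree$children[[compartment]]
  if (nrow(ch)) {
    keep <- ch$split >= time
    for (i in which(keep)) {
      out <- c(out, reachable_tissues(tree, ch$child[i], ch$split[i]))
    }
  }
  unique(out)
}

#' Tissues carrying an event
#'
#' Given an event placed in a compartment at a time, returns the tissue
#' labels (including `GERM`) whose terminal compartments descend from the
#' event-carrying cell lineage: the compartment's own tissue if it is a
#' sampled terminal, plus everything splitting off at or after the event
#' time.
#'
#' @param tree A `lineage_tree`.
#' @param compartment Compartment name.
#' @param time Event time (DAP); must lie within the compartment's interval.
#' @return Character vector of tissue labels (possibly empty).
#' @export
tissues_containing <- function(tree, compartment, time) {
  check_placement(tree, compartment, time)
  labs <- all_tissue_labels()
  out <- reachable_tissues(tree, compartment, time)
  out[order(match(out, labs))]
}

# piecewise-constant segments of tissues_containing for one compartment:
# the tissue set is constant on (s_{i-1}, s_i] between consecutive child
# splits (and on [birth, s_1]); it is evaluated at each right endpoint.
compartment_segments <- function(tree, compartment) {
  row <- comp_row(tree, compartment)
  ch <- tree$children[[compartment]]
  breaks <- sort(unique(c(row$birth, ch$split[ch$split > row$birth & ch$split <= row$end], row$end)))
  if (length(breaks) == 1) breaks <- c(breaks, breaks)
  segs <- tibble(
    compartment = compartment,
    t_start = head(breaks, -1),
    t_end = tail(breaks, -1)
  )
  segs$tissues <- map(segs$t_end, function(t) tissues_containing(tree, compartment, t))
  segs
}

lineage_segments <- function(tree) {
  list_rbind(map(tree$nodes$name, function(cp) compartment_segments(tree, cp)))
}

#' Candidate timing windows for an observed band pattern
#'
#' Inverts [tissues_containing()]: given the set of sampled tissues in which
#' a band was observed, returns all maximal (compartment, DAP interval)
#' regions whose predicted sampled-tissue set is consistent with the
#' observation. Because a band can drop out of an assayed sample (partial
#' detection) but never appear in a tissue outside the event's lineage, a
#' placement is consistent when its predicted set contains the observed set;
#' among consistent placements only those with a minimal predicted set are
#' kept, i.e. the latest (most specific) cell lineages that still explain
#' every observed tissue. When an exact match exists it is therefore the
#' unique answer.
#'
#' Each returned window carries its full tissue set including `GERM`, so
#' heritability can be read off as `GERM %in% tissues`.
#'
#' @param tree A `lineage_tree`.
#' @param observed Character vector of sampled tissue labels (subset of
#'   [sampled_tissues()]).
#' @return A tibble with columns `compartment`, `t_start`, `t_end`,
#'   `tissues` (list, full label set), `heritable` (logical) and `label`.
#'   Zero rows when no placement explains the pattern.
#' @export
candidate_windows <- function(tree, observed) {
  bad <- setdiff(observed, sampled_tissues())
  if (length(bad)) abort(paste0("observed tissues must be sampled labels; got: ", bad[1]))
  segs <- lineage_segments(tree)
  segs$sampled_set <- map(segs$tissues, intersect, sampled_tissues())
  ok <- map_lgl(segs$sampled_set, function(s) all(observed %in% s))
  segs <- segs[ok, ]
  if (!nrow(segs)) return(empty_windows())
  # minimal predicted sets among consistent placements
  sets <- unique(segs$sampled_set)
  minimal <- keep(sets, function(s) {
    !any(map_lgl(sets, function(o) length(o) < length(s) && all(o %in% s)))
  })
  segs <- segs[map_lgl(segs$sampled_set, function(s) {
    any(map_lgl(minimal, identical, s))
  }), ]
  if (!nrow(segs)) return(empty_windows())
  # merge contiguous segments of the same compartment and tissue set
  segs <- arrange(segs, .data$compartment, .data$t_start)
  merged <- list()
  for (i in seq_len(nrow(segs))) {
    cur <- segs[i, ]
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$compartment == cur$compartment &&
        isTRUE(all.equal(last$t_end, cur$t_start)) &&
        identical(last$tissues[[1]], cur$tissues[[1]])) {
      merged[[length(merged)]]$t_end <- cur$t_end
    } else {
      merged[[length(merged) + 1]] <- cur
    }
  }
  out <- list_rbind(merged)
  out$heritable <- map_lgl(out$tissues, function(ts) "GERM" %in% ts)
  out$label <- sprintf("%g–%g DAP %s", out$t_start, out$t_end, out$compartment)
  select(out, "compartment", "t_start", "t_end", "tissues", "heritable", "label")
}

empty_windows <- function() {
  tibble(
    compartment = character(), t_start = double(), t_end = double(),
    tissues = list(), heritable = logical(), label = character()
  )
}

# does a placement (compartment, time) fall inside a window table?
# segment intervals are (t_start, t_end] except at the compartment birth.
placement_in_windows <- function(tree, windows, compartment, time) {
  if (!nrow(windows)) return(FALSE)
  w <- windows[windows$compartment == compartment, ]
  if (!nrow(w)) return(FALSE)
  birth <- comp_row(tree, compartment)$birth
  any((time > w$t_start | (w$t_start == birth & time >= w$t_start)) & time <= w$t_end)
}
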