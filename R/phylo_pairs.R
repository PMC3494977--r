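# Species tree handling, same-system cluster detection, and construction of
# phylogenetically independent cross-system contrast pairs.
#
# Trees are ape "phylo" objects; branch lengths are optional and never used
# by the analysis (distances are topological node counts). A cluster unit is
# a maximal monophyletic set of tips sharing one multiple sex chromosome
# system; a contrast pair opposes one X1X2Y unit to one XY1Y2 unit, and a
# pair set is phylogenetically independent when the tree paths connecting
# the two units of each pair share no edge.

#' Read a species tree from Newick
#'
#' @param source path to a Newick file, or a Newick string.
#' @param species optional character vector of expected species keys; tips
#'   absent from it and species absent from the tree are reported as
#'   warnings and attached as attributes \code{"unmatched_tips"} and
#'   \code{"missing_species"}.
#' @return an \code{ape::phylo} tree (polytomies permitted).
#' @examples
#' read_species_tree("((A,B,C),D);")
#' @export
read_species_tree <- function(source, species = NULL) {
  is_text <- grepl("[();]", source)
  tree <- tryCatch(
    if (is_text) ape::read.tree(text = source) else ape::read.tree(source),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    kp_stop("Newick parse failure in ",
            if (is_text) "supplied string" else source)
  if (anyDuplicated(tree$tip.label))
    kp_stop("duplicate tip label(s): ",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                  collapse = ", "))
  if (any(!nzchar(tree$tip.label))) kp_stop("empty tip label")
  if (!is.null(species)) {
    unmatched <- setdiff(tree$tip.label, species)
    missing <- setdiff(species, tree$tip.label)
    if (length(unmatched))
      warning("tree tip(s) absent from the species list: ",
              paste(unmatched, collapse = ", "), call. = FALSE)
    if (length(missing))
      warning("species missing from the tree: ",
              paste(missing, collapse = ", "), call. = FALSE)
    attr(tree, "unmatched_tips") <- unmatched
    attr(tree, "missing_species") <- missing
  }
  tree
}

# tips (indices) descending from every node, bottom-up
kp_tips_under <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tips <- vector("list", n_all)
  for (i in seq_len(n_tip)) tips[[i]] <- i
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]
    child <- po$edge[k, 2]
    tips[[parent]] <- c(tips[[parent]], tips[[child]])
  }
  tips
}

# MRCA node index of a set of tip labels (the tip itself for singletons)
kp_unit_node <- function(tree, members) {
  idx <- match(members, tree$tip.label)
  if (anyNA(idx))
    kp_stop("unit member(s) not in tree: ",
            paste(members[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
}

#' Detect maximal monophyletic same-system clusters
#'
#' Bottom-up over the tree: a node is homogeneous when every tip below it
#' carries the same sex chromosome system; units are the homogeneous clades
#' whose parent is not homogeneous (tips under no homogeneous internal node
#' become singleton units). Unit ids are built from the genus prefixes of the
#' member species keys plus the system, e.g. \code{"Gazella_XY1Y2"}.
#'
#' @param tree an \code{ape::phylo} tree whose tips are species keys.
#' @param system_map named character vector mapping every tip label to
#'   \code{"X1X2Y"} or \code{"XY1Y2"}; a tip without a label is an error.
#' @return object of class \code{"cluster_units"}: a named list of units,
#'   each with fields \code{id}, \code{system}, \code{members}; sorted by id.
#' @examples
#' tab <- neosex_karyotypes()
#' tr <- read_species_tree(neosex_fixture_path("tree"))
#' units <- find_system_clusters(tr, stats::setNames(tab$system, tab$species_key))
#' lengths(lapply(units, `[[`, "members"))
#' @export
find_system_clusters <- function(tree, system_map) {
  n_tip <- ape::Ntip(tree)
  lab <- tree$tip.label
  missing <- lab[!lab %in% names(system_map)]
  if (length(missing))
    kp_stop("tip(s) lacking a system label: ", paste(missing, collapse = ", "))
  sys_tip <- unname(system_map[lab])
  if (anyNA(sys_tip) || !all(sys_tip %in% c("X1X2Y", "XY1Y2")))
    kp_stop("system labels must be X1X2Y or XY1Y2 for every tip")

  n_all <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  node_sys <- rep(NA_character_, n_all)
  node_sys[seq_len(n_tip)] <- sys_tip
  seen <- rep(FALSE, n_all)                     # parent already received a child?
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]
    child <- po$edge[k, 2]
    cs <- node_sys[child]
    if (!seen[parent]) {
      node_sys[parent] <- cs
      seen[parent] <- TRUE
    } else if (is.na(cs) || is.na(node_sys[parent]) ||
               cs != node_sys[parent]) {
      node_sys[parent] <- NA_character_
    }
  }
  parent_of <- rep(NA_integer_, n_all)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  homogeneous <- !is.na(node_sys)
  maximal <- homogeneous &
    (is.na(parent_of) | !homogeneous[ifelse(is.na(parent_of), 1L, parent_of)])
  tips_under <- kp_tips_under(tree)

  units <- list()
  for (v in which(maximal)) {
    members <- sort(lab[tips_under[[v]]])
    system <- node_sys[v]
    genera <- sort(unique(sub("_.*$", "", members)))
    id <- paste0(paste(genera, collapse = "-"), "_", system)
    units[[length(units) + 1L]] <- list(id = id, system = system,
                                        members = members)
  }
  ids <- vapply(units, `[[`, "", "id")
  if (anyDuplicated(ids)) {       # same genus split into several units
    for (dup in unique(ids[duplicated(ids)])) {
      at <- which(ids == dup)
      for (j in seq_along(at)) ids[at[j]] <- paste0(dup, ".", j)
    }
    for (j in seq_along(units)) units[[j]]$id <- ids[j]
  }
  units <- units[order(ids)]
  names(units) <- sort(ids)
  class(units) <- "cluster_units"
  units
}

#' @export
print.cluster_units <- function(x, ...) {
  cat(length(x), "cluster unit(s)\n")
  for (u in x)
    cat(sprintf("  %-28s %-6s %d member(s)\n", u$id, u$system,
                length(u$members)))
  invisible(x)
}

#' Representative acrocentric fraction of a cluster unit
#'
#' @param unit one element of a \code{cluster_units} list.
#' @param records a \code{karyotab} data frame covering the unit's members.
#' @param mode \code{"mean"} (arithmetic mean over members) or
#'   \code{"random"} (one member drawn uniformly; seed the RNG upstream).
#' @param sex \code{"female"} (default, the analysis basis) or \code{"male"}.
#' @return a single fraction.
#' @export
cluster_value <- function(unit, records, mode = c("mean", "random"),
                          sex = c("female", "male")) {
  mode <- match.arg(mode)
  sex <- match.arg(sex)
  if (length(unit$members) == 0L) kp_stop("empty cluster unit")
  idx <- match(unit$members, records$species_key)
  if (anyNA(idx))
    kp_stop("unit '", unit$id, "' has member(s) absent from the table: ",
            paste(unit$members[is.na(idx)], collapse = ", "))
  vals <- records[[paste0(sex, "_frac_acro")]][idx]
  if (mode == "mean") mean(vals) else vals[sample.int(length(vals), 1L)]
}

as_pair_df <- function(explicit_pairs) {
  if (is.data.frame(explicit_pairs)) {
    df <- explicit_pairs
  } else {
    df <- data.frame(
      x1x2y = vapply(explicit_pairs, function(p) p[["x1x2y"]], ""),
      xy1y2 = vapply(explicit_pairs, function(p) p[["xy1y2"]], ""),
      stringsAsFactors = FALSE)
  }
  if (!all(c("x1x2y", "xy1y2") %in% names(df)))
    kp_stop("pair configuration needs 'x1x2y' and 'xy1y2' entries")
  df[c("x1x2y", "xy1y2")]
}

#' Build cross-system contrast pairs
#'
#' With \code{explicit_pairs} (a data frame or list of
#' \code{list(x1x2y = id, xy1y2 = id)}), the pairs are validated — existing
#' unit ids, opposite systems in the named slots, no unit used twice — and
#' returned in configuration order. Without it, pairs are constructed
#' automatically: traversing the tree in postorder, whenever the subtree
#' below a node holds unpaired units of both systems, the cross-system unit
#' pair with the smallest topological (node-count) distance is paired (ties
#' broken lexicographically by unit id) and every unit under that node is
#' retired from further pairing, which guarantees edge-disjoint pair paths.
#'
#' @param tree the species tree.
#' @param units output of [find_system_clusters()].
#' @param explicit_pairs optional explicit configuration (see
#'   [read_pair_config()]).
#' @return object of class \code{"contrast_pairs"}: a data frame with columns
#'   \code{pair}, \code{x1x2y}, \code{xy1y2} and the units attached as
#'   attribute \code{"units"}.
#' @export
build_pairs <- function(tree, units, explicit_pairs = NULL) {
  ids <- vapply(units, `[[`, "", "id")
  systems <- vapply(units, `[[`, "", "system")

  if (!is.null(explicit_pairs)) {
    df <- as_pair_df(explicit_pairs)
    unknown <- setdiff(c(df$x1x2y, df$xy1y2), ids)
    if (length(unknown))
      kp_stop("unknown unit id(s) in pair configuration: ",
              paste(unknown, collapse = ", "))
    if (any(systems[match(df$x1x2y, ids)] != "X1X2Y") ||
        any(systems[match(df$xy1y2, ids)] != "XY1Y2"))
      kp_stop("each pair must oppose one X1X2Y unit to one XY1Y2 unit")
    used <- c(df$x1x2y, df$xy1y2)
    if (anyDuplicated(used))
      kp_stop("unit(s) used in more than one pair: ",
              paste(unique(used[duplicated(used)]), collapse = ", "))
    out <- data.frame(pair = seq_len(nrow(df)), df, stringsAsFactors = FALSE)
    attr(out, "units") <- units
    attr(out, "pairing") <- "explicit"
    class(out) <- c("contrast_pairs", "data.frame")
    return(out)
  }

  if (length(unique(systems)) < 2L) {
    warning("all units share one system; no cross-system pairs can be formed",
            call. = FALSE)
    out <- data.frame(pair = integer(0), x1x2y = character(0),
                      xy1y2 = character(0), stringsAsFactors = FALSE)
    attr(out, "units") <- units
    attr(out, "pairing") <- "automatic"
    class(out) <- c("contrast_pairs", "data.frame")
    return(out)
  }

  unit_node <- vapply(units, function(u) kp_unit_node(tree, u$members), 0L)
  topo <- tree
  topo$edge.length <- rep(1, nrow(tree$edge))
  dmat <- ape::dist.nodes(topo)
  tips_under <- kp_tips_under(tree)
  member_idx <- lapply(units, function(u) match(u$members, tree$tip.label))

  active <- rep(TRUE, length(units))
  pairs_x <- character(0)
  pairs_y <- character(0)
  po <- ape::reorder.phylo(tree, "postorder")
  internal_po <- unique(po$edge[, 1])     # postorder over internal nodes
  for (v in internal_po) {
    tipset <- tips_under[[v]]
    inside <- active & vapply(member_idx,
                              function(m) all(m %in% tipset), TRUE)
    in_x <- which(inside & systems == "X1X2Y")
    in_y <- which(inside & systems == "XY1Y2")
    if (length(in_x) && length(in_y)) {
      cand <- expand.grid(ix = in_x, iy = in_y)
      cand$d <- dmat[cbind(unit_node[cand$ix], unit_node[cand$iy])]
      cand <- cand[order(cand$d, ids[cand$ix], ids[cand$iy]), ]
      pairs_x <- c(pairs_x, ids[cand$ix[1]])
      pairs_y <- c(pairs_y, ids[cand$iy[1]])
      active[inside] <- FALSE            # retire the whole spanned subtree
    }
  }
  out <- data.frame(pair = seq_along(pairs_x), x1x2y = pairs_x,
                    xy1y2 = pairs_y, stringsAsFactors = FALSE)
  attr(out, "units") <- units
  attr(out, "pairing") <- "automatic"
  class(out) <- c("contrast_pairs", "data.frame")
  out
}

#' Read a pair configuration file
#'
#' @param path JSON or YAML file holding a list of
#'   \code{\{x1x2y: unit_id, xy1y2: unit_id\}} entries.
#' @return data.frame with columns \code{x1x2y}, \code{xy1y2}.
#' @export
read_pair_config <- function(path) {
  if (!file.exists(path)) kp_stop("pair configuration not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  as_pair_df(raw)
}

# edge key "lo-hi" for each edge on the path between two nodes
kp_path_edges <- function(tree, from, to) {
  if (from == to) return(character(0))
  np <- ape::nodepath(tree, from, to)
  paste(pmin(np[-length(np)], np[-1]), pmax(np[-length(np)], np[-1]), sep = "-")
}

#' Check phylogenetic independence of a pair set
#'
#' Computes the tree path between the two units of every pair (between the
#' clades spanning their members) and reports every edge used by more than
#' one pair. Contrasts are independent evolutionary events exactly when no
#' edge is shared.
#'
#' @param tree the species tree.
#' @param pairs a \code{contrast_pairs} object.
#' @param units cluster units; defaults to those attached to \code{pairs}.
#' @return list with \code{ok} (logical), \code{shared_edges} (character
#'   vector of \code{"node-node"} keys used more than once), and
#'   \code{edge_use} (named usage counts over all pair paths).
#' @export
validate_pair_independence <- function(tree, pairs,
                                       units = attr(pairs, "units")) {
  if (nrow(pairs) == 0L)
    return(list(ok = TRUE, shared_edges = character(0),
                edge_use = integer(0)))
  ids <- vapply(units, `[[`, "", "id")
  path_of <- function(id_x, id_y) {
    ux <- units[[match(id_x, ids)]]
    uy <- units[[match(id_y, ids)]]
    kp_path_edges(tree, kp_unit_node(tree, ux$members),
                  kp_unit_node(tree, uy$members))
  }
  all_edges <- unlist(mapply(path_of, pairs$x1x2y, pairs$xy1y2,
                             SIMPLIFY = FALSE))
  edge_use <- table(all_edges)
  shared <- names(edge_use)[edge_use > 1]
  list(ok = length(shared) == 0L, shared_edges = shared,
       edge_use = c(edge_use))
}
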