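# Synthetic-data generator operationalizing centromere-associated female
# meiotic drive.
#
# Karyotypes are tracked as counts of autosome pairs: A acrocentric and B
# biarmed. A centromeric fusion turns two acrocentric pairs into one biarmed
# pair; a fission is the reverse. Both conserve the autosomal arm count
# (A + 2B); only the chromosome count changes. A per-lineage drive bias d
# enters as a logistic fixation probability: fusions (producing a biarmed
# chromosome) fix with probability 1/(1+exp(-2d)), fissions with
# 1/(1+exp(+2d)), so d > 0 favors biarmed karyotypes, d < 0 acrocentric
# ones, and d = 0 is neutral (1/2). Sex chromosome-autosome fusions arise
# preferentially in acrocentric-rich karyotypes (mutation bias); an X-fusion
# must additionally survive female meiosis (fixation 1/(1+exp(-2d))), while
# a Y-fusion is male-limited and drive-free (fixation 1/2). The first fixed
# event sets the lineage's system permanently: X-fusion -> XY1Y2, Y-fusion
# -> X1X2Y.

#' Simulation parameters
#'
#' @param n_tips number of species (>= 2).
#' @param birth_rate Yule speciation rate per unit time (> 0).
#' @param ancestral_acro_pairs,ancestral_biarm_pairs root karyotype
#'   (acrocentric / biarmed autosome pair counts; their arm total must be at
#'   least 2).
#' @param rearrange_rate expected fusion/fission proposals per unit branch
#'   length.
#' @param drive_values two drive-bias values; each lineage carries one
#'   component of this mixture, switching between components at
#'   \code{drive_switch_rate} per unit branch length. Two well-separated
#'   values of opposite sign reproduce the bimodal acrocentric-fraction
#'   distribution seen in real mammals; \code{c(0, 0)} is the no-drive null.
#' @param drive_weights mixture weights at the root.
#' @param drive_switch_rate component switch rate per unit branch length.
#' @param sex_fusion_rate baseline rate of sex chromosome-autosome fusion
#'   proposals per unit branch length (multiplied by the lineage's current
#'   acrocentric availability A/(A+B)).
#' @param seed RNG seed consumed by [simulate_dataset()].
#' @return validated parameter list of class \code{"sim_params"}.
#' @export
sim_params <- function(n_tips = 48, birth_rate = 1,
                       ancestral_acro_pairs = 10, ancestral_biarm_pairs = 10,
                       rearrange_rate = 1,
                       drive_values = c(0, 0), drive_weights = c(0.5, 0.5),
                       drive_switch_rate = 0.05,
                       sex_fusion_rate = 0.5, seed = NULL) {
  kp_assert_scalar_number(n_tips, "n_tips", lo = 2)
  kp_assert_scalar_number(birth_rate, "birth_rate", lo = 1e-12)
  kp_assert_scalar_number(ancestral_acro_pairs, "ancestral_acro_pairs", lo = 0)
  kp_assert_scalar_number(ancestral_biarm_pairs, "ancestral_biarm_pairs", lo = 0)
  if (ancestral_acro_pairs + 2 * ancestral_biarm_pairs < 2)
    kp_stop("ancestral karyotype must carry at least 2 autosomal arms")
  kp_assert_scalar_number(rearrange_rate, "rearrange_rate", lo = 0)
  kp_assert_scalar_number(sex_fusion_rate, "sex_fusion_rate", lo = 0)
  kp_assert_scalar_number(drive_switch_rate, "drive_switch_rate", lo = 0)
  if (length(drive_values) != 2L || !all(is.finite(drive_values)))
    kp_stop("'drive_values' must be two finite numbers")
  if (length(drive_weights) != 2L || any(drive_weights < 0) ||
      sum(drive_weights) <= 0)
    kp_stop("'drive_weights' must be two non-negative numbers")
  structure(list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
                 ancestral_acro_pairs = as.integer(ancestral_acro_pairs),
                 ancestral_biarm_pairs = as.integer(ancestral_biarm_pairs),
                 rearrange_rate = rearrange_rate,
                 drive_values = as.numeric(drive_values),
                 drive_weights = drive_weights / sum(drive_weights),
                 drive_switch_rate = drive_switch_rate,
                 sex_fusion_rate = sex_fusion_rate,
                 seed = seed),
            class = "sim_params")
}

#' Simulate a pure-birth (Yule) species tree
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed optional seed; when given, the tree is reproducible.
#' @return an \code{ape::phylo} tree with tips labeled
#'   \code{s001_synthetica}, \code{s002_synthetica}, ...
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  kp_assert_scalar_number(n_tips, "n_tips", lo = 2)
  kp_assert_scalar_number(birth_rate, "birth_rate", lo = 1e-12)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(as.integer(n_tips), birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("s%03d_synthetica", seq_len(ape::Ntip(tree)))
  tree
}

kp_preorder_edges <- function(tree) {
  po <- ape::reorder.phylo(tree, "cladewise")
  cbind(po$edge, po$edge.length)
}

#' Evolve autosomal karyotypes along a tree
#'
#' Along each branch of length t, \code{Poisson(rearrange_rate * t)}
#' rearrangement proposals occur. A proposal is a fusion with probability
#' proportional to A(A-1) (pairs of acrocentric pairs available) and a
#' fission proportionally to B; impossible proposals are skipped. Fixation
#' probabilities follow the logistic drive map (see package notes above).
#' The drive component of a lineage switches between the two mixture values
#' at \code{drive_switch_rate}. Uses the current RNG state; seed upstream
#' (or via [simulate_dataset()]) for reproducibility.
#'
#' @param tree species tree with branch lengths.
#' @param params a [sim_params()] object.
#' @return object of class \code{"karyo_evolution"}: list with
#'   \code{tip_states} (data frame label/A/B), per-node \code{node_A},
#'   \code{node_B}, and \code{branch_d} (drive value on the branch above
#'   each node).
#' @export
evolve_karyotypes <- function(tree, params) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(tree$edge.length)) kp_stop("tree must have branch lengths")
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  A <- integer(n_all); B <- integer(n_all)
  comp <- integer(n_all)
  branch_d <- rep(NA_real_, n_all)
  A[root] <- params$ancestral_acro_pairs
  B[root] <- params$ancestral_biarm_pairs
  comp[root] <- sample.int(2L, 1L, prob = params$drive_weights)
  edges <- kp_preorder_edges(tree)
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]; t <- edges[k, 3]
    cc <- comp[parent]
    if (params$drive_switch_rate > 0 &&
        stats::rpois(1L, params$drive_switch_rate * t) %% 2L == 1L)
      cc <- 3L - cc
    d <- params$drive_values[cc]
    a <- A[parent]; b <- B[parent]
    n_ev <- stats::rpois(1L, params$rearrange_rate * t)
    for (ev in seq_len(n_ev)) {
      wf <- a * (a - 1)          # ordered pairs of acrocentric pairs
      wb <- b
      if (wf + wb == 0) next
      if (stats::runif(1) < wf / (wf + wb)) {
        if (stats::runif(1) < stats::plogis(2 * d)) { a <- a - 2L; b <- b + 1L }
      } else {
        if (stats::runif(1) < stats::plogis(-2 * d)) { b <- b - 1L; a <- a + 2L }
      }
    }
    A[child] <- a; B[child] <- b; comp[child] <- cc; branch_d[child] <- d
  }
  structure(list(tip_states = data.frame(label = tree$tip.label,
                                         A = A[seq_len(n_tip)],
                                         B = B[seq_len(n_tip)],
                                         stringsAsFactors = FALSE),
                 node_A = A, node_B = B, branch_d = branch_d),
            class = "karyo_evolution")
}

#' Assign sex chromosome systems along a tree
#'
#' Sex-fusion proposals arise on a branch at rate
#' \code{sex_fusion_rate * A/(A+B)} (per unit length, using the state at the
#' branch's origin), each an X-fusion or Y-fusion with probability 1/2. An
#' X-fusion fixes with probability \code{1/(1+exp(-2d))} (the fused biarmed
#' neo-X must survive female meiotic drive); a Y-fusion fixes with
#' probability 1/2. The first fixed event sets the system permanently
#' (XY1Y2 for X-fusions, X1X2Y for Y-fusions) and, at emission time,
#' consumes one acrocentric autosome pair.
#'
#' @param tree species tree with branch lengths.
#' @param karyo output of [evolve_karyotypes()] on the same tree.
#' @param params a [sim_params()] object.
#' @return named character vector of per-tip systems (\code{"simple"},
#'   \code{"X1X2Y"}, or \code{"XY1Y2"}).
#' @export
assign_sex_systems <- function(tree, karyo, params) {
  stopifnot(inherits(params, "sim_params"), inherits(karyo, "karyo_evolution"))
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  sys <- rep("simple", n_all)
  edges <- kp_preorder_edges(tree)
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]; t <- edges[k, 3]
    if (sys[parent] != "simple") { sys[child] <- sys[parent]; next }
    a <- karyo$node_A[parent]; b <- karyo$node_B[parent]
    rate <- if (a + b > 0) params$sex_fusion_rate * a / (a + b) else 0
    s <- "simple"
    n_ev <- if (rate > 0) stats::rpois(1L, rate * t) else 0L
    d <- karyo$branch_d[child]
    for (ev in seq_len(n_ev)) {
      if (s != "simple") break
      if (stats::runif(1) < 0.5) {          # X-autosome fusion
        if (stats::runif(1) < stats::plogis(2 * d)) s <- "XY1Y2"
      } else {                              # Y-autosome fusion, drive-free
        if (stats::runif(1) < 0.5) s <- "X1X2Y"
      }
    }
    sys[child] <- s
  }
  stats::setNames(sys[seq_len(n_tip)], tree$tip.label)
}

# derive the emitted karyotype record table from simulated states
kp_sim_records <- function(tree, karyo, systems) {
  st <- karyo$tip_states
  sysv <- unname(systems[st$label])
  has_sys <- sysv != "simple"
  A <- ifelse(has_sys, pmax(st$A - 1L, 0L), st$A)  # fused pair consumed
  B <- st$B
  keep <- which(has_sys & (A + B >= 1L))
  df <- data.frame(
    order = rep("synthetic", length(keep)),
    family = rep("synthetic", length(keep)),
    genus = sub("_.*$", "", st$label[keep]),
    species = rep("synthetica", length(keep)),
    female_2n = 2L * (A[keep] + B[keep]) + 2L,
    male_2n = 2L * (A[keep] + B[keep]) + 2L,
    female_nf = 2L * (A[keep] + 2L * B[keep]) + 2L,
    male_nf = 2L * (A[keep] + 2L * B[keep]) + 2L,
    female_frac_acro = acrocentric_fraction_from_counts(A[keep], B[keep]),
    male_frac_acro = acrocentric_fraction_from_counts(A[keep], B[keep]),
    system = sysv[keep],
    source = rep("synthetic", length(keep)),
    stringsAsFactors = FALSE)
  df$species_key <- make_species_key(df$genus, df$species)
  df$valid <- rep(TRUE, nrow(df))
  class(df) <- c("karyotab", "data.frame")
  df
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs tree simulation, karyotype evolution, and system assignment under
#' one seed and assembles the analysis table (species with a multiple
#' system; "simple" tips are excluded from the table but retained in the
#' returned states).
#'
#' @param params a [sim_params()] object; \code{params$seed}, when set,
#'   makes the whole dataset reproducible.
#' @return list with \code{tree}, \code{karyo}, \code{systems},
#'   \code{records} (a \code{karyotab} of multiple-system species), and
#'   \code{params}.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  tree <- simulate_yule_tree(params$n_tips, params$birth_rate)
  karyo <- evolve_karyotypes(tree, params)
  systems <- assign_sex_systems(tree, karyo, params)
  list(tree = tree, karyo = karyo, systems = systems,
       records = kp_sim_records(tree, karyo, systems), params = params)
}

#' Write a simulated dataset to disk
#'
#' Emits \code{karyotypes.tsv} (analysis table in the packaged interchange
#' schema; reloads under strict validation), \code{tree.nwk}, and
#' \code{truth.json} (parameters and per-tip states including "simple"
#' tips).
#'
#' @param tree,karyo,systems components as produced by [simulate_dataset()].
#' @param out_dir output directory (created if absent).
#' @param params optional [sim_params()] recorded in the truth file.
#' @return named character vector of the three file paths, invisibly.
#' @export
emit_dataset <- function(tree, karyo, systems, out_dir, params = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(table = file.path(out_dir, "karyotypes.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             truth = file.path(out_dir, "truth.json"))
  write_karyotype_table(kp_sim_records(tree, karyo, systems), paths["table"])
  ape::write.tree(tree, paths["tree"])
  truth <- list(params = if (!is.null(params)) unclass(params),
                tips = data.frame(karyo$tip_states,
                                  system = unname(systems[karyo$tip_states$label]),
                                  stringsAsFactors = FALSE))
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

# simulate until both systems are present among >= min_tips multiple-system
# tips; returns the dataset plus the pruned analysis tree
kp_sim_until_informative <- function(params, min_tips = 4L,
                                     max_attempts = 200L) {
  for (attempt in seq_len(max_attempts)) {
    ds <- simulate_dataset(params)
    rec <- ds$records
    if (nrow(rec) >= min_tips && length(unique(rec$system)) == 2L) {
      drop <- setdiff(ds$tree$tip.label, rec$species_key)
      ds$analysis_tree <- if (length(drop)) ape::drop.tip(ds$tree, drop)
                          else ds$tree
      return(ds)
    }
  }
  kp_stop("no informative dataset in ", max_attempts,
          " attempts; raise sex_fusion_rate or n_tips")
}

# full paired analysis of one simulated dataset (automatic pairing);
# a degenerate paired test (all differences zero) carries no evidence and
# scores p = 1
kp_sim_paired_p <- function(ds) {
  rec <- ds$records
  units <- find_system_clusters(
    ds$analysis_tree, stats::setNames(rec$system, rec$species_key))
  pairs <- build_pairs(ds$analysis_tree, units)
  if (nrow(pairs) == 0L) return(list(p = 1, n_pairs = 0L))
  p <- tryCatch(
    paired_comparison(rec, ds$analysis_tree, pairs)$test$p_two_sided,
    error = function(e) 1)
  list(p = p, n_pairs = nrow(pairs))
}

#' Type-I error calibration of the paired pipeline
#'
#' Under a no-drive null (\code{drive_values = c(0, 0)}, making fusion and
#' fission fixation, and X- and Y-fusion fixation, all symmetric at 1/2),
#' repeatedly simulates a dataset (re-drawing until both systems are
#' present), runs cluster detection, automatic pairing, and the mean-mode
#' exact paired test, and records rejections at level \code{alpha}.
#' Degenerate replicates (no informative pair differences) carry no
#' evidence and score p = 1.
#'
#' @param null_params [sim_params()] with zero drive; anything else is an
#'   error (the null must not force an association).
#' @param reps number of replicates (>= 200 recommended for calibration).
#' @param alpha nominal level.
#' @param seed RNG seed for the whole experiment.
#' @return list with \code{rate} (rejection fraction), \code{se} (binomial
#'   Monte-Carlo standard error at the nominal level), \code{reps},
#'   \code{alpha}, and \code{mean_pairs}.
#' @export
type_i_error_experiment <- function(null_params, reps = 500, alpha = 0.05,
                                    seed = NULL) {
  stopifnot(inherits(null_params, "sim_params"))
  if (any(null_params$drive_values != 0))
    kp_stop("null_params must have zero drive (association forced otherwise)")
  kp_assert_scalar_number(reps, "reps", lo = 1)
  kp_assert_scalar_number(alpha, "alpha", lo = 0, hi = 1)
  if (!is.null(seed)) set.seed(seed)
  null_params$seed <- NULL
  reject <- logical(reps)
  n_pairs <- integer(reps)
  for (r in seq_len(reps)) {
    ds <- kp_sim_until_informative(null_params)
    res <- kp_sim_paired_p(ds)
    reject[r] <- !is.na(res$p) && res$p <= alpha
    n_pairs[r] <- res$n_pairs
  }
  list(rate = mean(reject),
       se = sqrt(alpha * (1 - alpha) / reps),
       reps = as.integer(reps), alpha = alpha,
       mean_pairs = mean(n_pairs))
}

#' Sign-recovery experiment under drive heterogeneity
#'
#' Simulates datasets under a drive mixture and reports the fraction of
#' replicates in which the X1X2Y group's mean acrocentric fraction exceeds
#' the XY1Y2 group's (exact ties count 1/2, preserving symmetry at zero
#' effect). With a strong, well-separated mixture the fraction approaches 1.
#'
#' @param drive_params a [sim_params()] object (typically
#'   \code{drive_values = c(-d, d)}).
#' @param reps number of replicates.
#' @param seed RNG seed.
#' @return list with \code{recovery} (fraction), \code{reps}.
#' @export
sign_recovery_experiment <- function(drive_params, reps = 100, seed = NULL) {
  stopifnot(inherits(drive_params, "sim_params"))
  kp_assert_scalar_number(reps, "reps", lo = 1)
  if (!is.null(seed)) set.seed(seed)
  drive_params$seed <- NULL
  score <- numeric(reps)
  for (r in seq_len(reps)) {
    ds <- kp_sim_until_informative(drive_params)
    mx <- mean(ds$records$female_frac_acro[ds$records$system == "X1X2Y"])
    my <- mean(ds$records$female_frac_acro[ds$records$system == "XY1Y2"])
    score[r] <- if (mx > my) 1 else if (mx == my) 0.5 else 0
  }
  list(recovery = mean(score), reps = as.integer(reps))
}
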