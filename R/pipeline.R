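# End-to-end orchestration of the three analyses: species-level Mann-Whitney
# comparison, cluster-mean signed-rank test over the phylogenetically
# independent pairs, and the random-member cluster resampling, plus the
# histogram data product and a reproducible JSON report.

kp_frac_col <- function(sex) paste0(match.arg(sex, c("female", "male")),
                                    "_frac_acro")

#' Species-level group comparison of acrocentric fractions
#'
#' Mann-Whitney U test of the per-species acrocentric fractions, X1X2Y group
#' versus XY1Y2 group, ignoring phylogeny (every species counted once).
#'
#' @param records a \code{karyotab} data frame.
#' @param sex which karyotype the fractions come from (default female, the
#'   analysis basis).
#' @return a \code{"mann_whitney"} object; group a is X1X2Y, group b XY1Y2.
#' @examples
#' group_comparison(neosex_karyotypes())
#' @export
group_comparison <- function(records, sex = "female") {
  col <- kp_frac_col(sex)
  a <- records[[col]][records$system == "X1X2Y"]
  b <- records[[col]][records$system == "XY1Y2"]
  if (length(a) == 0L || length(b) == 0L)
    kp_stop("both sex chromosome systems must be present in the table")
  mann_whitney(a, b)
}

kp_pair_table <- function(records, pairs, units, mode, sex) {
  ids <- vapply(units, `[[`, "", "id")
  val <- function(id) cluster_value(units[[match(id, ids)]], records,
                                    mode = mode, sex = sex)
  vx <- vapply(pairs$x1x2y, val, 0)
  vy <- vapply(pairs$xy1y2, val, 0)
  data.frame(pair = pairs$pair, x1x2y = pairs$x1x2y, xy1y2 = pairs$xy1y2,
             value_x1x2y = vx, value_xy1y2 = vy, difference = vx - vy,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Paired comparison over phylogenetically independent pairs
#'
#' For each contrast pair the difference (X1X2Y representative minus XY1Y2
#' representative) is computed from cluster representatives and the exact
#' Wilcoxon signed-rank test is applied to the differences.
#'
#' @param records a \code{karyotab} data frame.
#' @param tree the species tree (used to verify independence on request via
#'   [validate_pair_independence()]; not needed for mean values).
#' @param pairs a \code{contrast_pairs} object with attached units.
#' @param mode representative mode passed to [cluster_value()]
#'   (default \code{"mean"}).
#' @param sex karyotype basis (default female).
#' @return object of class \code{"paired_comparison"}: list with the
#'   \code{"signed_rank"} \code{test} and the per-pair \code{differences}
#'   data frame.
#' @examples
#' tab <- neosex_karyotypes()
#' tr <- read_species_tree(neosex_fixture_path("tree"))
#' units <- find_system_clusters(tr, stats::setNames(tab$system, tab$species_key))
#' prs <- build_pairs(tr, units, read_pair_config(neosex_fixture_path("pairs")))
#' paired_comparison(tab, tr, prs)
#' @export
paired_comparison <- function(records, tree, pairs, mode = "mean",
                              sex = "female") {
  units <- attr(pairs, "units")
  if (is.null(units)) kp_stop("'pairs' carries no cluster units")
  if (nrow(pairs) == 0L) kp_stop("no contrast pairs to test")
  diffs <- kp_pair_table(records, pairs, units, mode, sex)
  res <- structure(list(test = signed_rank_exact(diffs$difference),
                        differences = diffs, mode = mode, sex = sex),
                   class = "paired_comparison")
  res
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat("Paired cross-system comparison (", x$mode, " representatives, ",
      x$sex, " karyotype)\n", sep = "")
  print(x$differences, digits = 4)
  neg <- sum(x$differences$difference < 0)
  if (neg > 0)
    cat("note:", neg, "pair(s) have a negative difference\n")
  print(x$test)
  invisible(x)
}

#' Cluster-resampled paired comparison
#'
#' Repeats the paired signed-rank test \code{k} times, each iteration drawing
#' one member uniformly and independently from every cluster unit instead of
#' averaging. Draws consume the seeded RNG in iteration-major order over
#' units sorted by id, so runs are bit-reproducible.
#'
#' @inheritParams paired_comparison
#' @param k number of iterations (>= 2; default 100).
#' @param seed RNG seed; if \code{NULL} one is generated and reported.
#' @return object of class \code{"resampling_summary"}: list with \code{k},
#'   \code{seed}, \code{p_values}, \code{mean_p}, \code{se_p} (sample
#'   standard deviation of the p-values divided by \code{sqrt(k)}), and
#'   \code{sign_flips} (per-iteration count of negative differences).
#' @export
resampled_paired_comparison <- function(records, tree, pairs, k = 100,
                                        seed = NULL, sex = "female") {
  if (!is.numeric(k) || k < 2) kp_stop("'k' must be at least 2 (SE undefined)")
  units <- attr(pairs, "units")
  if (is.null(units)) kp_stop("'pairs' carries no cluster units")
  if (nrow(pairs) == 0L) kp_stop("no contrast pairs to test")
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    message("resampling seed generated: ", seed)
  }
  set.seed(seed)
  k <- as.integer(k)
  p_values <- numeric(k)
  sign_flips <- integer(k)
  ids <- vapply(units, `[[`, "", "id")
  for (it in seq_len(k)) {
    # one uniform member per cluster unit, consumed in sorted-id order
    drawn <- vapply(units[order(ids)], cluster_value, 0,
                    records = records, mode = "random", sex = sex)
    names(drawn) <- sort(ids)
    vx <- drawn[pairs$x1x2y]
    vy <- drawn[pairs$xy1y2]
    diffs <- data.frame(pair = pairs$pair, difference = vx - vy)
    sr <- signed_rank_exact(diffs$difference)
    p_values[it] <- sr$p_two_sided
    sign_flips[it] <- sum(diffs$difference < 0)
  }
  structure(list(k = k, seed = seed, p_values = p_values,
                 mean_p = mean(p_values),
                 se_p = stats::sd(p_values) / sqrt(k),
                 sign_flips = sign_flips),
            class = "resampling_summary")
}

#' @export
print.resampling_summary <- function(x, ...) {
  cat(sprintf(
    "Cluster resampling: %d iterations (seed %d)\n  mean p = %.4f, SE = %.4f, iterations with sign flips: %d\n",
    x$k, x$seed, x$mean_p, x$se_p, sum(x$sign_flips > 0)))
  invisible(x)
}

#' Histogram counts of acrocentric fractions
#'
#' Bins are half-open \code{[lo, hi)} with the final bin closed at 1, so a
#' fraction of exactly 1 falls in the last bin.
#'
#' @param x a \code{karyotab} data frame or a numeric vector of fractions.
#' @param sex karyotype basis when \code{x} is a table.
#' @param system optional system label to restrict a table to.
#' @param bin_width bin width; must divide 1 evenly (default 0.1).
#' @return data.frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{count}.
#' @examples
#' acro_histogram(neosex_karyotypes(), system = "X1X2Y")
#' @export
acro_histogram <- function(x, sex = "female", system = NULL, bin_width = 0.1) {
  n_bins <- 1 / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-8)
    kp_stop("bin_width must divide 1 evenly")
  n_bins <- as.integer(round(n_bins))
  if (is.data.frame(x)) {
    if (!is.null(system)) x <- x[x$system == system, , drop = FALSE]
    vals <- x[[kp_frac_col(sex)]]
  } else {
    vals <- x
  }
  if (any(vals < 0 | vals > 1)) kp_stop("fractions must lie in [0, 1]")
  idx <- pmin(floor(vals / bin_width), n_bins - 1)   # 1.0 -> final bin
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(bin_lo = bin_width * (seq_len(n_bins) - 1),
             bin_hi = bin_width * seq_len(n_bins),
             count = counts)
}

#' Run the full analysis and write a report
#'
#' \code{config} is a list (or a path to a YAML/JSON file holding one) with
#' fields \code{table} (karyotype TSV), \code{tree} (Newick), and optionally
#' \code{pairs} (explicit pair configuration; omitted = automatic pairing),
#' \code{seed} (resampling seed, default 1), \code{k} (iterations, default
#' 100), \code{sex} (\code{"female"}/\code{"male"}), \code{strict}
#' (loader strictness), \code{bin_width}, \code{out_dir} (when given, a JSON
#' report and TSV histogram tables are written there). With all inputs and
#' the seed fixed the report is byte-identical across runs.
#'
#' @param config list or path, as above.
#' @return the report (a nested list), invisibly when written to disk.
#' @export
run_report <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config) else jsonlite::fromJSON(config,
                                                      simplifyDataFrame = FALSE)
  }
  for (field in c("table", "tree"))
    if (is.null(config[[field]]))
      kp_stop("config is missing required field '", field, "'")
  sex <- if (is.null(config$sex)) "female" else config$sex
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  k <- if (is.null(config$k)) 100L else as.integer(config$k)
  strict <- if (is.null(config$strict)) TRUE else isTRUE(config$strict)
  bin_width <- if (is.null(config$bin_width)) 0.1 else config$bin_width

  records <- load_karyotype_table(config$table, strict = strict, quiet = TRUE)
  analysis <- records[records$system %in% c("X1X2Y", "XY1Y2"), , drop = FALSE]
  tree <- read_species_tree(config$tree, species = analysis$species_key)
  audit <- audit_table(analysis, quiet = TRUE)
  units <- find_system_clusters(
    tree, stats::setNames(analysis$system, analysis$species_key))
  explicit <- if (!is.null(config$pairs)) read_pair_config(config$pairs)
  pairs <- build_pairs(tree, units, explicit)
  independence <- validate_pair_independence(tree, pairs)
  group <- group_comparison(analysis, sex = sex)
  paired <- paired_comparison(analysis, tree, pairs, mode = "mean", sex = sex)
  resampled <- resampled_paired_comparison(analysis, tree, pairs,
                                           k = k, seed = seed, sex = sex)
  hists <- list(
    X1X2Y = acro_histogram(analysis, sex = sex, system = "X1X2Y",
                           bin_width = bin_width),
    XY1Y2 = acro_histogram(analysis, sex = sex, system = "XY1Y2",
                           bin_width = bin_width))
  if (!is.null(config$background_table)) {
    bg <- load_karyotype_table(config$background_table, strict = FALSE,
                               quiet = TRUE)
    hists$background <- acro_histogram(bg, sex = sex, bin_width = bin_width)
  }

  report <- list(
    software = list(package = "karyopairs",
                    version = as.character(utils::packageVersion("karyopairs"))),
    inputs = list(table = config$table, tree = config$tree,
                  pairs = config$pairs, sex = sex, seed = seed, k = k),
    data = list(n_records = nrow(records),
                n_by_system = as.list(table(analysis$system)),
                n_audit_flagged = sum(audit$flagged)),
    clusters = lapply(unname(units), function(u)
      list(id = u$id, system = u$system, n = length(u$members))),
    pairing = list(mode = attr(pairs, "pairing"),
                   n_pairs = nrow(pairs),
                   independent = independence$ok,
                   shared_edges = independence$shared_edges),
    group_test = list(u1 = group$u1, u2 = group$u2, u_min = group$u_min,
                      z = group$z, p_two_sided = group$p_two_sided,
                      median_x1x2y = group$median_a,
                      median_xy1y2 = group$median_b),
    paired_test = list(differences = paired$differences,
                       w_plus = paired$test$w_plus,
                       w_minus = paired$test$w_minus,
                       s = paired$test$s,
                       n_used = paired$test$n_used,
                       n_zero_dropped = paired$test$n_zero,
                       method = paired$test$method,
                       p_two_sided = paired$test$p_two_sided,
                       n_negative_differences =
                         sum(paired$differences$difference < 0)),
    resampling = list(k = resampled$k, seed = resampled$seed,
                      mean_p = resampled$mean_p, se_p = resampled$se_p,
                      iterations_with_sign_flips =
                        sum(resampled$sign_flips > 0),
                      p_values = resampled$p_values),
    histograms = hists)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(hists))
      utils::write.table(hists[[nm]],
                         file.path(config$out_dir,
                                   paste0("histogram_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}
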