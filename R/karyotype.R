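# Karyotype records: loading, validation, and arm arithmetic.
#
# A record summarizes one species' female and male karyotype by the diploid
# number 2n (chromosome count), the fundamental number NF (chromosome-arm
# count), the fraction of acrocentric chromosomes, and the sex chromosome
# system (X1X2Y = Y-autosome fusion, XY1Y2 = X-autosome fusion, or "simple").
# Every chromosome contributes one arm (acrocentric) or two (biarmed), hence
# the structural bound 2n <= NF <= 2 * 2n.

#' @keywords internal
karyotype_columns <- c("order", "family", "genus", "species",
                       "female_2n", "male_2n", "female_nf", "male_nf",
                       "female_frac_acro", "male_frac_acro",
                       "system", "source")

kp_systems <- c("X1X2Y", "XY1Y2", "simple")

#' Load and validate a karyotype table
#'
#' Reads a UTF-8 tab-separated table with the exact header
#' \code{order, family, genus, species, female_2n, male_2n, female_nf,
#' male_nf, female_frac_acro, male_frac_acro, system, source} and validates
#' every row: positive integer counts, the arm-count bound
#' \code{2n <= NF <= 2*2n} for each sex, fractions in [0, 1], a recognized
#' system label, and uniqueness of (genus, species, system). A
#' \code{species_key} column (see [make_species_key()]) is appended.
#'
#' @param path path to a TSV file.
#' @param strict logical; if \code{TRUE} (default) any invariant violation is
#'   an error listing the offending rows. If \code{FALSE} the table is
#'   returned with a logical \code{valid} column and violations are reported
#'   as a warning.
#' @param quiet logical; suppress the per-system count message.
#' @return a \code{data.frame} of class \code{"karyotab"}, one row per data
#'   row in file order.
#' @examples
#' tab <- load_karyotype_table(neosex_fixture_path("table"))
#' table(tab$system)
#' @export
load_karyotype_table <- function(path, strict = TRUE, quiet = FALSE) {
  if (!file.exists(path)) kp_stop("file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(karyotype_columns, names(raw))
  if (length(missing))
    kp_stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  raw <- raw[karyotype_columns]
  if (nrow(raw) == 0L) {
    warning("karyotype table is empty (header only)", call. = FALSE)
    out <- raw
    for (col in c("female_2n", "male_2n", "female_nf", "male_nf"))
      out[[col]] <- integer(0)
    for (col in c("female_frac_acro", "male_frac_acro"))
      out[[col]] <- numeric(0)
    out$species_key <- character(0)
    out$valid <- logical(0)
    class(out) <- c("karyotab", "data.frame")
    return(out)
  }

  num_cols <- c("female_2n", "male_2n", "female_nf", "male_nf",
                "female_frac_acro", "male_frac_acro")
  for (col in num_cols) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val))
    if (length(bad))
      kp_stop(sprintf("parse error: non-numeric value in column '%s' at row(s) %s",
                      col, paste(bad, collapse = ", ")))
    raw[[col]] <- val
  }
  for (col in c("female_2n", "male_2n", "female_nf", "male_nf"))
    raw[[col]] <- as.integer(raw[[col]])

  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems, sprintf("%s (row %s)", what,
                                       paste(rows, collapse = ", ")))
    rows
  }
  bad <- list(
    note(which(raw$female_2n < 1 | raw$male_2n < 1 |
               raw$female_nf < 1 | raw$male_nf < 1), "non-positive count"),
    note(which(raw$female_nf < raw$female_2n |
               raw$female_nf > 2L * raw$female_2n),
         "female NF outside [2n, 2*2n]"),
    note(which(raw$male_nf < raw$male_2n | raw$male_nf > 2L * raw$male_2n),
         "male NF outside [2n, 2*2n]"),
    note(which(raw$female_frac_acro < 0 | raw$female_frac_acro > 1 |
               raw$male_frac_acro < 0 | raw$male_frac_acro > 1),
         "fraction outside [0, 1]"),
    note(which(!raw$system %in% kp_systems),
         sprintf("system not in {%s}", paste(kp_systems, collapse = ", "))),
    note(which(duplicated(paste(raw$genus, raw$species, raw$system))),
         "duplicate (genus, species, system)")
  )
  bad_rows <- sort(unique(unlist(bad)))
  if (length(problems)) {
    msg <- paste0("validation: ", paste(problems, collapse = "; "))
    if (strict) kp_stop(msg) else warning(msg, call. = FALSE)
  }
  raw$species_key <- make_species_key(raw$genus, raw$species)
  raw$valid <- !seq_len(nrow(raw)) %in% bad_rows
  if (!quiet) {
    counts <- table(factor(raw$system, levels = kp_systems))
    message("loaded ", nrow(raw), " karyotype records (",
            paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), ")")
  }
  class(raw) <- c("karyotab", "data.frame")
  raw
}

#' Write a karyotype table
#'
#' Writes records back to the tab-separated interchange format, dropping the
#' derived \code{species_key}/\code{valid} columns so that a written table
#' reloads to identical records.
#'
#' @param records a \code{karyotab} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_karyotype_table <- function(records, path) {
  utils::write.table(as.data.frame(records)[karyotype_columns], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a chromosome shape class to an arm class
#'
#' Chromosome shapes follow Levan's nomenclature; for arm counting,
#' subtelocentric and telocentric chromosomes are pooled with acrocentrics
#' (one arm), metacentric and submetacentric chromosomes are biarmed (two
#' arms).
#'
#' @param category character vector of shape names (case-insensitive), each
#'   one of \code{"metacentric"}, \code{"submetacentric"},
#'   \code{"subtelocentric"}, \code{"telocentric"}, \code{"acrocentric"}.
#' @return character vector, \code{"biarmed"} or \code{"acrocentric"}.
#' @examples
#' classify_shape(c("submetacentric", "telocentric"))
#' @export
classify_shape <- function(category) {
  map <- c(metacentric = "biarmed", submetacentric = "biarmed",
           subtelocentric = "acrocentric", telocentric = "acrocentric",
           acrocentric = "acrocentric")
  cat_lc <- tolower(trimws(as.character(category)))
  unknown <- unique(cat_lc[!cat_lc %in% names(map)])
  if (length(unknown))
    kp_stop("unrecognized shape category '", paste(unknown, collapse = "', '"),
            "'; accepted values: ", paste(names(map), collapse = ", "))
  unname(map[cat_lc])
}

#' Acrocentric fraction from arm-class counts
#'
#' @param n_acro number of acrocentric chromosomes (>= 0).
#' @param n_biarmed number of biarmed chromosomes (>= 0).
#' @return \code{n_acro / (n_acro + n_biarmed)} at full precision
#'   (vectorized).
#' @examples
#' acrocentric_fraction_from_counts(26, 24)  # 0.52
#' @export
acrocentric_fraction_from_counts <- function(n_acro, n_biarmed) {
  if (any(n_acro < 0) || any(n_biarmed < 0))
    kp_stop("counts must be non-negative")
  tot <- n_acro + n_biarmed
  if (any(tot < 1)) kp_stop("at least one chromosome is required (both counts zero)")
  n_acro / tot
}

#' Estimate the acrocentric fraction from 2n and NF
#'
#' Standard cytogenetic arm accounting: with \code{b} biarmed and \code{a}
#' acrocentric chromosomes, \code{2n = a + b} and \code{NF = a + 2b}, so
#' \code{a = 2*2n - NF} and the acrocentric fraction is
#' \code{(2*2n - NF) / 2n}.
#'
#' @param two_n diploid chromosome number(s).
#' @param nf fundamental (arm) number(s).
#' @return estimated acrocentric fraction(s) in [0, 1], full precision.
#' @examples
#' estimate_acrocentric_fraction(50, 74)  # 0.52
#' estimate_acrocentric_fraction(6, 10)   # 1/3
#' @export
estimate_acrocentric_fraction <- function(two_n, nf) {
  if (any(two_n < 1)) kp_stop("2n must be positive")
  if (any(nf < two_n | nf > 2 * two_n))
    kp_stop("arm-count bound violated: need 2n <= NF <= 2*2n")
  (2 * two_n - nf) / two_n
}

#' Audit printed fractions against the 2n/NF estimate
#'
#' Cross-checks each record's printed female acrocentric fraction against the
#' value implied by its female 2n and NF ([estimate_acrocentric_fraction()]).
#' Disagreement beyond \code{threshold} usually signals differing
#' fundamental-number conventions between source papers, not a data error;
#' the printed fraction remains the authoritative analysis input.
#'
#' @param records a \code{karyotab} data frame.
#' @param threshold flag records whose absolute deviation exceeds this
#'   (default 0.02).
#' @param quiet suppress the summary message.
#' @return data.frame with columns \code{species_key}, \code{printed_fraction},
#'   \code{estimated_fraction}, \code{deviation}, \code{flagged}.
#' @examples
#' aud <- audit_table(neosex_karyotypes(), quiet = TRUE)
#' subset(aud, flagged)
#' @export
audit_table <- function(records, threshold = 0.02, quiet = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    kp_stop("'records' must be a non-empty karyotype table")
  if (threshold <= 0 || threshold > 1) kp_stop("threshold must be in (0, 1]")
  est <- estimate_acrocentric_fraction(records$female_2n, records$female_nf)
  dev <- abs(records$female_frac_acro - est)
  out <- data.frame(species_key = records$species_key,
                    printed_fraction = records$female_frac_acro,
                    estimated_fraction = est,
                    deviation = dev,
                    flagged = dev > threshold,
                    stringsAsFactors = FALSE)
  if (!quiet)
    message(sum(out$flagged), " of ", nrow(out),
            " records deviate from the 2n/NF estimate by more than ", threshold)
  out
}

#' Path to a packaged reference file
#'
#' @param which one of \code{"table"}, \code{"tree"}, \code{"pairs"}.
#' @return file path inside the installed package.
#' @export
neosex_fixture_path <- function(which = c("table", "tree", "pairs")) {
  which <- match.arg(which)
  fname <- switch(which,
                  table = "neosex_karyotypes.tsv",
                  tree  = "neosex_tree.nwk",
                  pairs = "neosex_pairs.json")
  system.file("extdata", fname, package = "karyopairs", mustWork = TRUE)
}

#' Packaged mammalian reference dataset
#'
#' The 41-species compilation of mammals with multiple sex chromosome
#' systems (18 X1X2Y, 23 XY1Y2), as a validated karyotype table. Note the
#' accompanying literature reports 19 X1X2Y species while the printed
#' compilation contains 18; the table is shipped as printed.
#'
#' @param quiet suppress the loader's count message (default TRUE).
#' @return a \code{karyotab} data frame with 41 rows.
#' @export
neosex_karyotypes <- function(quiet = TRUE) {
  load_karyotype_table(neosex_fixture_path("table"), quiet = quiet)
}
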