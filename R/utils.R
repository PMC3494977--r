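#' Build a species key from genus and epithet
#'
#' Keys identify species across the karyotype table, the tree tip labels and
#' the pair configuration. Any run of non-alphanumeric characters (spaces,
#' dots) collapses to a single underscore, so \code{"Taterillus" + "sp.1"}
#' becomes \code{"Taterillus_sp_1"}.
#'
#' @param genus character vector of genus names.
#' @param species character vector of species epithets.
#' @return character vector of keys, one per input pair.
#' @examples
#' make_species_key("Sorex", "araneus Race A")
#' @export
make_species_key <- function(genus, species) {
  stopifnot(length(genus) == length(species))
  sub("_+$", "", gsub("[^A-Za-z0-9]+", "_", paste(genus, species)))
}

# internal: fail with a consistent prefix
kp_stop <- function(...) stop(..., call. = FALSE)

kp_assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    kp_stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                    name, format(lo), format(hi)))
  invisible(x)
}
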