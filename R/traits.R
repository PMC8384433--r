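# Species trait tables: one row per tip with the observed species mean,
# the sample size it was estimated from, and its squared standard error.

#' Construct a species trait table
#'
#' @param species Character vector of species names (must match tip labels
#'   when used with a tree).
#' @param mean Observed mean trait values.
#' @param n Per-species sample sizes (`>= 1`).
#' @param se2 Squared standard errors of the species means (`>= 0`), the
#'   "known" half of observational error.
#' @return A `data.frame` of class `trait_data` with columns
#'   `species`, `mean`, `n`, `se2`.
#' @export
trait_data <- function(species, mean, n = 1, se2 = 0) {
  n <- rep_len(n, length(species))
  se2 <- rep_len(se2, length(species))
  if (anyDuplicated(species)) stop_("duplicate species in trait table")
  if (any(!is.finite(mean))) stop_("non-finite trait means")
  if (any(se2 < 0)) stop_("squared standard errors must be >= 0")
  if (any(n < 1)) stop_("sample sizes must be >= 1")
  structure(data.frame(species = as.character(species), mean = mean,
                       n = n, se2 = se2, stringsAsFactors = FALSE),
            class = c("trait_data", "data.frame"))
}

#' Read a trait table from CSV/TSV
#'
#' Expects columns `species`, `mean`, `n`, `se2`; tolerates quoted labels
#' and scientific notation.
#'
#' @param file Path to a CSV or TSV file.
#' @param sep Field separator; guessed from the extension by default.
#' @return A [trait_data()] table.
#' @export
read_trait_data <- function(file, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("species", "mean", "n", "se2")
  if (!all(need %in% names(df))) {
    stop_(sprintf("trait table must have columns %s", paste(need, collapse = ", ")))
  }
  trait_data(df$species, df$mean, df$n, df$se2)
}

#' Write a trait table to CSV
#' @param traits A [trait_data()] table.
#' @param file Output path.
#' @export
write_trait_data <- function(traits, file) {
  utils::write.csv(as.data.frame(traits), file, row.names = FALSE)
}

# Align a trait table with a tree's tips. Missing species are an error by
# default; tips absent from the table can be dropped with a warning.
align_traits <- function(traits, tree, drop_missing = FALSE) {
  idx <- match(tree$tip.label, traits$species)
  if (any(is.na(idx))) {
    missing <- tree$tip.label[is.na(idx)]
    stop_(sprintf("no trait data for tip(s): %s", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(traits$species, tree$tip.label)
  if (length(extra)) {
    if (!drop_missing) stop_(sprintf("trait table has species not in the tree: %s",
                                     paste(extra, collapse = ", ")))
    warning(sprintf("dropping %d species not in the tree", length(extra)), call. = FALSE)
  }
  traits[idx, , drop = FALSE]
}
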