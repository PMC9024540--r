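#' Bundled worked-example tables
#'
#' Three small tables from a published Himalayan medicinal-herb SDM study
#' ship with the package as plain CSV so that the arithmetic stages can be
#' exercised on real printed numbers:
#' \itemize{
#'   \item `example_correlation_matrix()`: the 19 x 19 pairwise Pearson
#'     correlation matrix among the candidate bioclimatic predictors
#'     bio_1..bio_19.
#'   \item `example_importance_scores()`: per-algorithm permutation
#'     importance scores for the 8 retained predictors (rows = variables,
#'     columns = the nine algorithms; the Mean column is recomputed, not
#'     stored).
#'   \item `example_range_change_counts()`: loss/absent/stable/gain pixel
#'     counts for four future scenarios x two ensemble methods.
#' }
#'
#' @return see each function: a matrix, a data.frame with `variable`
#'   rownames, or a data.frame of counts.
#' @name example_tables
NULL

example_path <- function(file)
  system.file("extdata", file, package = "ensdm", mustWork = TRUE)

#' @rdname example_tables
#' @export
example_correlation_matrix <- function() {
  m <- as.matrix(utils::read.csv(example_path("bioclim_correlation_matrix.csv"),
                                 row.names = 1, check.names = FALSE))
  stopifnot(identical(rownames(m), colnames(m)))
  m
}

#' @rdname example_tables
#' @export
example_importance_scores <- function() {
  d <- utils::read.csv(example_path("importance_scores.csv"),
                       check.names = FALSE)
  rownames(d) <- d$variable
  d$variable <- NULL
  d
}

#' @rdname example_tables
#' @export
example_range_change_counts <- function() {
  utils::read.csv(example_path("range_change_counts.csv"),
                  check.names = FALSE)
}
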