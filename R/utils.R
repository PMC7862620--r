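## Small internal helpers.

#' @useDynLib plscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

## Strict numeric matrix coercion for feature tables.
as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    drop <- intersect(c("complex_id", "dG_exp"), names(features))
    features <- features[setdiff(names(features), drop)]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  if (any(!is.finite(features))) stop("non-finite feature values")
  features
}
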