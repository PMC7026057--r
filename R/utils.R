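## Internal helpers shared across modules.

#' Geometric mean
#' @param x positive numeric vector.
#' @param na.rm drop NAs first.
#' @return the geometric mean; NaN on any non-positive value.
#' @keywords internal
geoMean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) return(NaN)
  exp(mean(log(x)))
}

## Sample SD (n-1 denominator) -- the geNorm convention used throughout.
sampleSD <- function(x) stats::sd(x)

## Run an expression under a fixed RNG seed and restore the caller's
## generator state afterwards (used for the quasi-randomized multivariate-t
## integration inside the Dunnett adjustment, so identical inputs give
## identical reports without disturbing user-level reproducibility).
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Write a data.frame as TSV with full numeric precision (round-trips to
## better than 1e-9).
writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Average-rank helper: ascending scores -> ranks 1..k, ties averaged.
avgRank <- function(scores) {
  r <- rank(scores, ties.method = "average")
  names(r) <- names(scores)
  r
}

stopif <- function(cond, ...) if (cond) stop(..., call. = FALSE)
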