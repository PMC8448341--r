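## Internal helpers shared across the package.

#' @importFrom methods is new validObject as
#' @importFrom stats median rmultinom rlnorm rbinom rnbinom var cor mad
#'   quantile setNames
#' @importFrom utils read.delim write.csv packageVersion head
NULL

## Mitochondrial contig dialects normalised to a single token. Datasets span
## ENSEMBL ("MT") and UCSC/Cell Ranger ("chrM"/"chrMT") conventions.
.MITO_CHROMS <- c("MT", "chrM", "chrMT", "M", "chrMt", "mt")

.isMitoChrom <- function(chrom) {
  chrom %in% .MITO_CHROMS
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Check a numeric vector/matrix holds non-negative integral counts.
.checkCountValues <- function(x, what = "counts") {
  v <- if (is(x, "sparseMatrix")) x@x else as.numeric(x)
  if (any(is.na(v))) return(sprintf("%s contain missing values", what))
  if (any(v < 0)) return(sprintf("%s contain negative values", what))
  bad <- which(v != round(v))
  if (length(bad)) {
    return(sprintf("%s contain non-integer values (first offending value: %s)",
                   what, format(v[bad[1]])))
  }
  NULL
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

## Subsample an integer count vector to exactly `target` total counts without
## replacement (multivariate hypergeometric): emulates discarding reads from
## the observed library.
.subsampleCounts <- function(x, target) {
  total <- sum(x)
  if (target > total) .stopf("subsample target %d exceeds depth %d", target, total)
  if (target == total) return(x)
  reads <- rep.int(seq_along(x), x)
  kept <- sample(reads, target, replace = FALSE)
  tabulate(kept, nbins = length(x))
}

## Population variance (divides by n); the convention used for the
## normalized-variance calibration statistic.
.popVar <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}
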