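`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a temporarily seeded RNG, restoring the caller's stream so
# seeded calls do not perturb global reproducibility. seed = NULL means
# "use the ambient RNG" (needed so experiment drivers can thread one master
# seed through many inner calls).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("'seed' must be a single integer or NULL")
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

.as_feature_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (samples x features)", arg))
  }
  if (anyNA(x)) stop(sprintf("'%s' contains missing values", arg))
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x
}

.check_square_symmetric <- function(w, arg = "weights") {
  if (!is.matrix(w) || nrow(w) != ncol(w)) {
    stop(sprintf("'%s' must be a square matrix", arg))
  }
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-8, check.attributes = FALSE))) {
    stop(sprintf("'%s' must be symmetric", arg))
  }
  invisible(w)
}
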