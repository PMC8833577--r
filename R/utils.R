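# Internal helpers shared across modules.

.epihfo_env <- new.env(parent = emptyenv())

stop_epihfo <- function(msg, class) {
  stop(structure(class = c(class, "epihfo_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "epihfo_invalid_input") {
  if (!isTRUE(ok)) stop_epihfo(msg, class)
  invisible(TRUE)
}

#' @keywords internal
is_count <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x == as.integer(x)

# Area-averaging resampling weights mapping n source bins onto m destination
# bins (rows of the returned m x n matrix sum to 1).  Each destination bin
# covers the source interval [j*n/m, (j+1)*n/m) and weights source bins by
# fractional overlap, i.e. exact box averaging with no interpolation ringing.
resample_weights <- function(n, m) {
  key <- paste0("rw_", n, "_", m)
  w <- .epihfo_env[[key]]
  if (!is.null(w)) return(w)
  w <- matrix(0, m, n)
  step <- n / m
  for (j in seq_len(m)) {
    lo <- (j - 1) * step
    hi <- j * step
    i0 <- floor(lo) + 1
    i1 <- min(n, ceiling(hi))
    idx <- i0:i1
    ov <- pmin(idx, hi) - pmax(idx - 1, lo)
    ov[ov < 0] <- 0
    w[j, idx] <- ov / step
  }
  .epihfo_env[[key]] <- w
  w
}

# md5 of an arbitrary R object (used for config hashes in manifests).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# Derive a bounded child seed from a base seed and a stream index, keeping the
# result well inside 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 100003L) * 20011 + (as.numeric(stream) %% 99991L) * 17 + 1)
}

# Evaluate an expression under a local RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
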