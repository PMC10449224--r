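# internal interval helpers (0-based, half-open throughout)

# merge possibly overlapping/adjacent intervals; `x` is a 2-column matrix
merge_intervals <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  ir <- IRanges::reduce(IRanges::IRanges(as.integer(x[, 1]) + 1L, as.integer(x[, 2])))
  cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

# check that intervals are sorted, disjoint and merged (no shared endpoints)
is_merged <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) return(TRUE)
  if (any(x[, 2] <= x[, 1])) return(FALSE)
  if (nrow(x) == 1) return(TRUE)
  all(x[-1, 1] > x[-nrow(x), 2])
}

interval_lengths <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) return(numeric(0))
  x[, 2] - x[, 1]
}

# evaluate an expression with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
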