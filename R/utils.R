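#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois runif rexp sd cor shapiro.test kruskal.test
#'   ks.test hclust cutree as.dist quantile predict
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's global RNG state afterwards. All stochastic entry points route
# their randomness through this so a single integer seed fixes an entire run
# without clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying well inside
# the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 1009) %% 2147483587L) + 1L
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("retinamech_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_invalid(name, " must be a positive number")
  }
  invisible(x)
}
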