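# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily seeded RNG
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' package functions do not perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# locale-independent lexicographic order (C collation)
c_order <- function(x) order(x, method = "radix")

c_sort <- function(x) sort(x, method = "radix")

stop_fmt <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "emtmap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
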