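#' @keywords internal
"_PACKAGE"

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("cannabismr_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_input <- function(...) {
  stop(structure(class = c("cannabismr_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Weighted simple linear regression y ~ x (optionally without intercept),
# closed form; returns c(intercept, slope). Used in hot loops where lm()
# overhead matters (bootstrap, SIMEX).
wls_line <- function(x, y, w, intercept = TRUE) {
  sw <- sum(w)
  if (!intercept) {
    return(c(0, sum(w * x * y) / sum(w * x^2)))
  }
  sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  c((sy - slope * sx) / sw, slope)
}
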