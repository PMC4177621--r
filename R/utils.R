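#' @keywords internal
"_PACKAGE"

# Scoped RNG: run `expr` under `seed` without disturbing the caller's
# random-number state. All stochastic functions in the package route
# their randomness through this helper.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Lightweight leveled logging; level controlled by option admixlat.log_level
# in c("debug","info","warn","quiet").
admix_log <- function(msg, ..., level = "info") {
  lv <- getOption("admixlat.log_level", "warn")
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (ranks[[level]] >= ranks[[lv]])
    message(sprintf("[admixlat] %s", sprintf(msg, ...)))
  invisible(NULL)
}

#' Set package logging verbosity
#'
#' @param level one of "debug", "info", "warn", "quiet"
#' @return previous level, invisibly
#' @export
admixlat_log_level <- function(level = c("warn", "info", "debug", "quiet")) {
  level <- match.arg(level)
  old <- getOption("admixlat.log_level", "warn")
  options(admixlat.log_level = level)
  invisible(old)
}

stop_config <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

# draw one Dirichlet row per row of the alpha matrix
rdirichlet_mat <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow = nrow(alpha))
  g / rowSums(g)
}
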