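# Internal helpers shared across modules.

ISLANDS <- c("Cuba", "Hispaniola", "Jamaica", "PuertoRico")
ECOMORPHS <- c("trunk-ground", "trunk-crown", "crown-giant", "twig",
               "grass-bush", "trunk")
SEXES <- c("male", "female", "unknown")
SOURCES <- c("museum", "experiment")
TREATMENTS <- c("broad", "narrow")
META_COLS <- c("specimen_id", "species", "island", "ecomorph", "sex",
               "source", "treatment")

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Stable polynomial hash of the labels mixed with the master seed, kept
#' below 2^31 so the result is a valid R integer seed. Used by the pipeline
#' to give every quartet (and every stochastic stage) its own deterministic
#' seed while a single master seed controls the whole run.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the consumer (e.g. quartet labels).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  s <- paste(vapply(list(...), as.character, character(1L)), collapse = "|")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483647)
}

# Column-wise means/variances for a numeric matrix (sample variance, n-1).
.col_stats <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  v <- colSums((x - rep(m, each = n))^2) / (n - 1L)
  list(n = n, mean = m, var = v)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
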