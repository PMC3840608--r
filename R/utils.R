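#' @import data.table
#' @importFrom stats rbinom rgeom rnorm rpois runif median quantile uniroot
#'   plogis glm glm.fit binomial poisson coef vcov setNames
#' @importFrom utils head read.csv write.csv
NULL

# claims dimensions recognised throughout the package
CLAIMS_DIMENSIONS <- c("pharmacy", "dx_inpatient", "dx_outpatient",
                       "px_inpatient", "px_outpatient")

# evaluate expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards so library code never perturbs user-level randomness
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Derive a deterministic child seed
#'
#' Splits one root seed into per-(condition, replicate) substreams so that
#' adding scenarios or replicates never perturbs the draws of earlier ones.
#' The result is always a valid 32-bit integer seed.
#'
#' @param root integer root seed.
#' @param condition_id integer condition index (0 when unused).
#' @param replicate integer replicate index (0 when unused).
#' @return An integer seed.
#' @export
child_seed <- function(root, condition_id = 0L, replicate = 0L) {
  s <- (as.double(root) %% 2147483647) + condition_id * 1000003 + replicate * 97
  as.integer(s %% 2147483647)
}

# zero-truncated geometric draw on {1, 2, ...} with success probability p
rztgeom <- function(n, prob) {
  rgeom(n, prob) + 1L
}

# nearest-rank (ceiling) sample quantile of a numeric vector
nearest_rank_quantile <- function(x, q) {
  stopifnot(length(x) > 0, q > 0, q <= 1)
  xs <- sort(x)
  xs[max(1L, ceiling(q * length(xs)))]
}

# strip decimal points / whitespace from ICD-9 style codes ("530.11" -> "53011")
normalize_icd9 <- function(code) {
  toupper(gsub("[. ]", "", code))
}

# render a normalized ICD-9 code with its decimal point ("5301" -> "530.1")
format_icd9 <- function(code) {
  ifelse(nchar(code) > 3L,
         paste0(substr(code, 1L, 3L), ".", substring(code, 4L)),
         code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
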