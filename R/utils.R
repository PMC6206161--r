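
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stable per-subject seed from a master seed
#'
#' Polynomial rolling hash of the subject identifier, folded into the master
#' seed modulo 2^31 - 1. Adding subjects to a cohort never reshuffles the
#' trials of existing subjects, because each subject's stream depends only on
#' the master seed and their own identifier.
#'
#' @param master integer master seed.
#' @param id character scalar (e.g. a subject id).
#' @param salt optional integer mixed in, to derive several independent
#'   streams per subject.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
stable_seed <- function(master, id, salt = 0L) {
  stopifnot(length(id) == 1L, is.character(id))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% m
  s <- (h + (as.numeric(master) %% m) * 69069 + as.numeric(salt) * 40503) %% m
  as.integer(s %% (m - 2) + 1)
}
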