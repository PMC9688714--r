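## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' Complement of DNA bases
#'
#' Vectorized single-base complement (A<->T, C<->G).
#'
#' @param base character vector of bases in `A/C/G/T`.
#' @return character vector of complements.
#' @examples
#' complement_base(c("A", "G"))
#' @export
complement_base <- function(base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- comp[toupper(base)]
  if (anyNA(out)) stop("bases must be one of A/C/G/T")
  unname(out)
}

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the simulator route through this so that a
## SimConfig (including its seed) maps to byte-identical outputs.
with_rng <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

## stopifnot with a readable message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Coerce a reference argument (FASTA path or DNAStringSet) to a DNAStringSet.
as_reference <- function(reference) {
  if (is.character(reference)) {
    check_that(file.exists(reference),
               paste0("reference FASTA not found: ", reference))
    reference <- Biostrings::readDNAStringSet(reference)
  }
  check_that(methods::is(reference, "DNAStringSet"),
             "reference must be a DNAStringSet or a FASTA path")
  reference
}
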