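# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. `seed = NULL` uses the ambient stream.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed that stays inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  if (is.null(seed) || is.na(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# Genus displayed in tables: label minus a trailing ".NN" suffix.
#' Strip a trailing numeric OTU suffix from taxon labels for display
#'
#' Labels like `"Ralstonia.01"` name the genus plus an OTU counter; the genus
#' is the substring before the final `".<digits>"` suffix. Labels without such
#' a suffix are returned unchanged.
#'
#' @param taxa character vector of taxon labels.
#' @return character vector of display (genus) names.
#' @examples
#' genusOf(c("Ralstonia.01", "Prevotella.18", "K.Bacteria.01", "unnamed"))
#' @export
genusOf <- function(taxa) sub("\\.[0-9]+$", "", taxa)
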